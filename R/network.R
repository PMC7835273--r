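#' Network configuration
#'
#' Architecture of the three-class 3D residual attention classifier. The
#' trunk is a stem convolution plus 2x2x2 average pooling followed by
#' `n_residual_units` residual units at constant width. Two attention
#' branches hang off the trunk midpoint and endpoint: each projects the
#' features to a single-channel sigmoid attention map, gates the features it
#' feeds to its auxiliary two-class head, and multiplicatively re-weights the
#' trunk (`f * (1 + a)`). The branch tasks are `cancer_vs_normal` (classes
#' no-cancer vs cancer-without-nodal-spread) and `lnm_vs_cancer` (cancer
#' without vs with nodal spread). The two maps are summed and the combined
#' map re-weights the features entering the final three-class head.
#'
#' @param n_residual_units even integer (default 4); the attention branches
#'   attach after units n/2 and n.
#' @param channel_width trunk width in channels (default 8).
#' @param attention_feedback scalar in [0, 1] scaling the gradient that the
#'   gated (downstream) losses send back into the attention maps. At 0 (the
#'   default) the maps are pure class-activation maps of their auxiliary
#'   task (stop-gradient at the gates), which keeps their localization
#'   meaning intact; values above 0 let the main task co-shape the maps,
#'   which in our experiments traded localization for little else.
#' @param n_classes fixed at 3.
#' @return object of class `network_config`.
#' @export
network_config <- function(n_residual_units = 4L, channel_width = 8L,
                           attention_feedback = 0, n_classes = 3L) {
  n_residual_units <- as.integer(n_residual_units)
  if (n_residual_units < 2L || n_residual_units %% 2L != 0L) {
    stop("n_residual_units must be an even integer >= 2", call. = FALSE)
  }
  if (n_classes != 3L) stop("the classifier is three-class", call. = FALSE)
  stopifnot(channel_width >= 1, attention_feedback >= 0,
            attention_feedback <= 1)
  structure(list(n_residual_units = n_residual_units,
                 channel_width = as.integer(channel_width),
                 attention_branches = c("cancer_vs_normal", "lnm_vs_cancer"),
                 attention_feedback = attention_feedback,
                 n_classes = 3L),
            class = "network_config")
}

#' Training configuration
#'
#' Plain stochastic gradient descent on the equal-weighted sum of the main
#' three-class cross-entropy and the two masked auxiliary cross-entropies.
#'
#' @param learning_rate positive step size (default 0.001).
#' @param loss_weights nonnegative length-3 vector (main, aux1, aux2);
#'   default equal.
#' @param epochs number of passes over the data.
#' @param batch_size minibatch size; `NULL` (default) = full batch.
#' @param momentum SGD momentum in [0, 1) (default 0, plain SGD).
#' @param clip_norm global gradient-norm ceiling (default 1); `Inf` disables
#'   clipping.
#' @param lr_decay multiplicative per-epoch learning-rate decay in (0, 1]
#'   (default 1, constant rate).
#' @param warmup_epochs linear learning-rate warmup over this many initial
#'   epochs (default 0, none); tames the first momentum-amplified steps.
#' @param early_stop_loss optional scalar: stop when the mean epoch training
#'   loss falls below it (default `NULL`, run all epochs).
#' @param seed integer seed for shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, loss_weights = c(1, 1, 1),
                         epochs = 30L, batch_size = NULL, momentum = 0,
                         clip_norm = 1, lr_decay = 1, warmup_epochs = 0L,
                         early_stop_loss = NULL, seed = 1L) {
  stopifnot(learning_rate > 0, length(loss_weights) == 3,
            all(loss_weights >= 0), epochs >= 1,
            momentum >= 0, momentum < 1, clip_norm > 0,
            lr_decay > 0, lr_decay <= 1, warmup_epochs >= 0,
            is.null(early_stop_loss) || early_stop_loss > 0)
  structure(list(learning_rate = learning_rate, loss_weights = loss_weights,
                 epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 momentum = momentum, clip_norm = clip_norm,
                 lr_decay = lr_decay, warmup_epochs = as.integer(warmup_epochs),
                 early_stop_loss = early_stop_loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Auxiliary-task targets for a sample label
#'
#' Task 1 (cancer presence) is defined on no-cancer vs cancer-without-LNM;
#' task 2 (nodal spread) on cancer-without-LNM vs cancer-with-LNM. The class
#' outside each task is masked (NA) and contributes neither loss nor
#' gradient.
#'
#' @param label `"no_cancer"`/`"normal"`, `"cancer_no_LNM"` or `"cancer_LNM"`.
#' @return list with `task1` and `task2`, each `"positive"`, `"negative"` or
#'   `NA`.
#' @export
aux_targets <- function(label) {
  if (label %in% c("no_cancer", "normal")) {
    list(task1 = "negative", task2 = NA_character_)
  } else if (label == "cancer_no_LNM") {
    list(task1 = "positive", task2 = "negative")
  } else if (label == "cancer_LNM") {
    list(task1 = NA_character_, task2 = "positive")
  } else {
    stop("unknown label: ", label, call. = FALSE)
  }
}

# ---- convolution plumbing -------------------------------------------------
# Feature maps live in matrices of shape (V * n, C): voxels of sample 1 in
# array order, then sample 2, ... Convolution is shift-and-add over the 27
# kernel offsets using precomputed index maps; out-of-volume taps hit an
# all-zero guard row (zero padding).

conv_offsets <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)

conv_geometry <- function(dims, n) {
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  V <- d1 * d2 * d3
  v0 <- 0:(V - 1)
  z <- v0 %% d1 + 1L
  y <- (v0 %/% d1) %% d2 + 1L
  x <- v0 %/% (d1 * d2) + 1L
  zero_row <- V * n + 1L
  sample_shift <- rep((0:(n - 1)) * V, each = V)
  idx <- vector("list", 27L)
  for (o in seq_len(27L)) {
    sz <- z + conv_offsets$dz[o]
    sy <- y + conv_offsets$dy[o]
    sx <- x + conv_offsets$dx[o]
    ok <- sz >= 1L & sz <= d1 & sy >= 1L & sy <= d2 & sx >= 1L & sx <= d3
    lin <- (sx - 1L) * d1 * d2 + (sy - 1L) * d1 + sz
    full <- rep(lin, n) + sample_shift
    full[!rep(ok, n)] <- zero_row
    idx[[o]] <- full
  }
  list(idx = idx, V = V, n = n, dims = dims)
}

conv_fwd <- function(X, W, b, geom) {
  Xa <- rbind(X, 0)
  Y <- matrix(0, nrow(X), ncol(W[[1]]))
  for (o in seq_len(27L)) {
    Y <- Y + Xa[geom$idx[[o]], , drop = FALSE] %*% W[[o]]
  }
  Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
}

conv_bwd_data <- function(dY, W, geom) {
  dYa <- rbind(dY, 0)
  dX <- matrix(0, nrow(dY), nrow(W[[1]]))
  for (o in seq_len(27L)) {
    # the adjoint of offset o is offset 28 - o (the negated displacement)
    dX <- dX + dYa[geom$idx[[28L - o]], , drop = FALSE] %*% t(W[[o]])
  }
  dX
}

conv_bwd_w <- function(X, dY, geom) {
  Xa <- rbind(X, 0)
  lapply(seq_len(27L), function(o) {
    crossprod(Xa[geom$idx[[o]], , drop = FALSE], dY)
  })
}

pool_geometry <- function(dims, n) {
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  stopifnot(all(c(d1, d2, d3) %% 2L == 0L))
  dp <- c(d1, d2, d3) %/% 2L
  V <- prod(dims); Vp <- prod(dp)
  v0 <- 0:(V - 1)
  z <- v0 %% d1 + 1L
  y <- (v0 %/% d1) %% d2 + 1L
  x <- v0 %/% (d1 * d2) + 1L
  pz <- (z + 1L) %/% 2L; py <- (y + 1L) %/% 2L; px <- (x + 1L) %/% 2L
  plin <- (px - 1L) * dp[1] * dp[2] + (py - 1L) * dp[1] + pz
  unpool <- rep(plin, n) + rep((0:(n - 1)) * Vp, each = V)
  list(unpool = unpool, dims_pooled = dp, Vp = Vp, n = n)
}

conv_init <- function(cin, cout, sd = sqrt(2 / (27 * cin))) {
  lapply(seq_len(27L), function(o) matrix(stats::rnorm(cin * cout, sd = sd),
                                          cin, cout))
}

#' Build the three-class 3D residual attention network
#'
#' Initializes all parameters (He-scaled Gaussian convolution kernels, small
#' Gaussian dense heads, zero biases) for a given half-chest input shape.
#' Each residual unit obeys the additive skip contract
#' `out = relu(input + conv(relu(conv(input))))` at constant width, so a unit
#' with zero transform weights is the identity on nonnegative features.
#'
#' @param config a [network_config()].
#' @param input_shape integer length-3 half-chest shape (z, y, x); every
#'   dimension must be even (one 2x2x2 pooling stage).
#' @param seed integer seed for the initialization.
#' @return object of class `ax_network` holding the parameters, config and
#'   input geometry.
#' @export
build_network <- function(config = network_config(),
                          input_shape = c(32L, 48L, 24L), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape < 2) ||
      any(input_shape %% 2L != 0L)) {
    stop("input_shape must be three even positive integers", call. = FALSE)
  }
  C <- config$channel_width
  params <- with_seed(seed, {
    p <- list(stem = list(W = conv_init(2L, C), b = numeric(C)))
    p$res <- lapply(seq_len(config$n_residual_units), function(u) {
      list(W1 = conv_init(C, C), b1 = numeric(C),
           W2 = conv_init(C, C), b2 = numeric(C))
    })
    # Each attention branch produces a two-class evidence map by 1x1x1
    # convolution. The auxiliary classifier pools the evidence maps
    # (mean + max over voxels) into the two-class logits, and the attention
    # map is the sigmoid of the positive-minus-negative evidence, so
    # attention concentrates where the branch sees evidence for its positive
    # class. Keeping the maps translation-invariant (no positional
    # parameters) is what lets a branch trained on one lesion configuration
    # generalize to lesions elsewhere.
    p$attn1 <- list(W = matrix(stats::rnorm(C * 2, sd = 0.1), C, 2),
                    b = numeric(2))
    p$attn2 <- list(W = matrix(stats::rnorm(C * 2, sd = 0.1), C, 2),
                    b = numeric(2))
    # The main head reads the mean of the attention-modulated features
    # alongside the per-channel peaks of the raw trunk (2C inputs). The max
    # path carries small-lesion evidence undiluted and trains the trunk
    # without touching attention; the mean path reads the attention-
    # amplified average, so the only gradient the main loss sends into the
    # attention maps is the aligned one — amplify the voxels whose features
    # support the true class.
    p$main <- list(W = matrix(stats::rnorm(2 * C * 3, sd = 0.01), 2 * C, 3),
                   b = numeric(3))
    p
  })
  structure(list(config = config, input_shape = input_shape, params = params,
                 classes = c("no_cancer", "cancer_no_LNM", "cancer_LNM")),
            class = "ax_network")
}

# Stack a list of preprocessed 4D arrays (z, y, x, 2) into the (V*n, 2)
# matrix layout; validates shapes against the model. Channels are centered
# (x - 0.5) at the network boundary: zero-mean-ish inputs condition the
# first-layer SGD far better than the all-positive [0, 1] range.
stack_inputs <- function(model, xs) {
  shp <- model$input_shape
  V <- prod(shp)
  X <- matrix(0, V * length(xs), 2L)
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    if (!identical(as.integer(dim(x)), as.integer(c(shp, 2L)))) {
      stop("input shape mismatch: expected (",
           paste(c(shp, 2L), collapse = ", "), ")", call. = FALSE)
    }
    X[(i - 1L) * V + seq_len(V), ] <- matrix(x, V, 2L)
  }
  X - 0.5
}

make_geometry <- function(model, n) {
  shp <- model$input_shape
  pool <- pool_geometry(shp, n)
  list(full = conv_geometry(shp, n),
       pooled = conv_geometry(pool$dims_pooled, n),
       pool = pool,
       gap_group = rep(seq_len(n), each = pool$Vp))
}

# Leaky rectifier (slope 0.05 below zero): keeps every unit trainable in a
# narrow trunk, where hard-zero units are easily lost for good. Identity on
# nonnegative inputs, so the residual skip contract is unchanged there.
relu <- function(x) x * (x > 0) + 0.05 * x * (x <= 0)
relu_grad <- function(pre) (pre > 0) + 0.05 * (pre <= 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Global mean + max pooling over voxels per sample: (n, 2C) features, means
# first. Returns the argmax rows needed for the backward scatter.
head_pool_fwd <- function(F, gap_group, Vp, n) {
  C <- ncol(F)
  gap <- rowsum(F, gap_group, reorder = TRUE) / Vp
  gmp <- matrix(0, n, C)
  amax <- matrix(0L, n, C)
  for (ch in seq_len(C)) {
    M <- matrix(F[, ch], Vp, n)
    a <- max.col(t(M), ties.method = "first")
    amax[, ch] <- a
    gmp[, ch] <- M[cbind(a, seq_len(n))]
  }
  list(feat = cbind(gap, gmp), amax = amax)
}

head_pool_bwd <- function(dfeat, amax, Vp, n, gap_group) {
  C <- ncol(dfeat) %/% 2L
  dF <- dfeat[gap_group, seq_len(C), drop = FALSE] / Vp
  for (ch in seq_len(C)) {
    rows <- (seq_len(n) - 1L) * Vp + amax[, ch]
    dF[rows, ch] <- dF[rows, ch] + dfeat[, C + ch]
  }
  dF
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass; returns scores, attention maps and (optionally) every
# intermediate needed by the backward pass.
forward_net <- function(model, X, geom, zero_combined = FALSE,
                        keep_cache = FALSE) {
  p <- model$params
  nres <- model$config$n_residual_units
  mid <- nres %/% 2L
  gp <- geom$pool
  Vp <- gp$Vp

  S0 <- conv_fwd(X, p$stem$W, p$stem$b, geom$full)
  Z <- relu(S0)
  F0 <- rowsum(Z, gp$unpool, reorder = TRUE) / 8

  ru_cache <- vector("list", nres)
  Fcur <- F0
  run_unit <- function(Fin, pu) {
    H1pre <- conv_fwd(Fin, pu$W1, pu$b1, geom$pooled)
    H1 <- relu(H1pre)
    H2 <- conv_fwd(H1, pu$W2, pu$b2, geom$pooled)
    out_pre <- Fin + H2
    list(out = relu(out_pre), H1pre = H1pre, H1 = H1, out_pre = out_pre,
         Fin = Fin)
  }
  for (u in seq_len(mid)) {
    ru_cache[[u]] <- run_unit(Fcur, p$res[[u]])
    Fcur <- ru_cache[[u]]$out
  }
  F2 <- Fcur
  n <- gp$n
  # Branch: two-class evidence maps -> pooled aux logits + attention map.
  # The evidence difference is centered per sample before the sigmoid
  # (instance normalization): attention encodes where evidence is relative
  # to the rest of the volume, immune to a shared constant that would
  # saturate the map uniformly.
  run_branch <- function(F, pb) {
    s <- F %*% pb$W + matrix(pb$b, nrow(F), 2, byrow = TRUE)
    hp <- head_pool_fwd(s, geom$gap_group, Vp, n)
    d <- s[, 2] - s[, 1]
    dc <- d - (rowsum(d, geom$gap_group, reorder = TRUE) / Vp)[geom$gap_group]
    list(s = s, hp = hp,
         logits = hp$feat[, 1:2, drop = FALSE] + hp$feat[, 3:4, drop = FALSE],
         A = sigmoid(dc))
  }
  br1 <- run_branch(F2, p$attn1)
  A1 <- br1$A
  Fcur <- F2 * (1 + A1)
  F2g <- Fcur
  for (u in seq(mid + 1L, nres)) {
    ru_cache[[u]] <- run_unit(Fcur, p$res[[u]])
    Fcur <- ru_cache[[u]]$out
  }
  F4 <- Fcur
  br2 <- run_branch(F4, p$attn2)
  A2 <- br2$A
  Acomb <- if (zero_combined) rep(0, length(A1)) else A1 + A2
  F5 <- F4 * (1 + Acomb)
  hp4 <- head_pool_fwd(F4, geom$gap_group, Vp, n)
  main_feat <- cbind(rowsum(F5, geom$gap_group, reorder = TRUE) / Vp,
                     hp4$feat[, -seq_len(ncol(F4)), drop = FALSE])
  main_logits <- main_feat %*% p$main$W +
    matrix(p$main$b, n, 3, byrow = TRUE)

  out <- list(main_logits = main_logits, aux1_logits = br1$logits,
              aux2_logits = br2$logits, A1 = A1, A2 = A2, Acomb = Acomb)
  if (keep_cache) {
    out$cache <- list(X = X, S0 = S0, Z = Z, F0 = F0, ru = ru_cache, F2 = F2,
                      br1 = br1, F2g = F2g, F4 = F4, br2 = br2, F5 = F5,
                      main_feat = main_feat, amax4 = hp4$amax, mid = mid)
  }
  out
}

# Cross-entropy on logits with optional masked targets (NA = no loss).
# Returns mean loss over unmasked rows and the gradient wrt logits (already
# scaled by 1/n_unmasked; zero rows where masked).
softmax_ce <- function(logits, target_idx) {
  n <- nrow(logits)
  P <- softmax_rows(logits)
  keep <- !is.na(target_idx)
  m <- sum(keep)
  if (m == 0) return(list(loss = 0, dlogits = matrix(0, n, ncol(logits))))
  picked <- P[cbind(which(keep), target_idx[keep])]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- matrix(0, n, ncol(logits))
  dl[keep, ] <- P[keep, , drop = FALSE] / m
  dl[cbind(which(keep), target_idx[keep])] <-
    dl[cbind(which(keep), target_idx[keep])] - 1 / m
  list(loss = loss, dlogits = dl)
}

# One full forward + backward pass; returns loss components and gradients in
# the same nested structure as model$params.
backward_net <- function(model, X, geom, y_main, y_aux1, y_aux2, loss_w) {
  p <- model$params
  fw <- forward_net(model, X, geom, keep_cache = TRUE)
  cc <- fw$cache
  gp <- geom$pool
  Vp <- gp$Vp
  nres <- model$config$n_residual_units
  mid <- cc$mid

  ce_main <- softmax_ce(fw$main_logits, y_main)
  ce_a1 <- softmax_ce(fw$aux1_logits, y_aux1)
  ce_a2 <- softmax_ce(fw$aux2_logits, y_aux2)
  loss <- loss_w[1] * ce_main$loss + loss_w[2] * ce_a1$loss +
    loss_w[3] * ce_a2$loss

  g <- list(stem = list(W = NULL, b = NULL), res = vector("list", nres),
            attn1 = list(), attn2 = list(), main = list())

  n <- gp$n
  gamma <- model$config$attention_feedback
  # Adjoint of run_branch: the branch's own cross-entropy plus the
  # gating-path gradient dA, the latter attenuated by `attention_feedback`
  # so the auxiliary loss stays in control of the evidence maps' sign while
  # the multiplicative shortcut still trains the trunk.
  branch_backward <- function(br, pb, F, daux, dA) {
    ds <- head_pool_bwd(cbind(daux, daux), br$hp$amax, Vp, n, geom$gap_group)
    if (gamma > 0) {
      dd <- gamma * dA * br$A * (1 - br$A)
      # adjoint of the per-sample centering of the evidence difference
      dd <- dd - (rowsum(dd, geom$gap_group, reorder = TRUE) /
                    Vp)[geom$gap_group]
      ds[, 2] <- ds[, 2] + dd
      ds[, 1] <- ds[, 1] - dd
    }
    list(gW = crossprod(F, ds), gb = colSums(ds),
         dF = ds %*% t(pb$W))
  }

  dml <- loss_w[1] * ce_main$dlogits
  g$main$W <- crossprod(cc$main_feat, dml)
  g$main$b <- colSums(dml)
  dmain_feat <- dml %*% t(p$main$W)
  C <- ncol(cc$F4)
  dF5 <- dmain_feat[geom$gap_group, seq_len(C), drop = FALSE] / Vp
  dF4 <- dF5 * (1 + fw$Acomb)
  # max path reads the raw trunk: scatter to the argmax voxels of F4
  for (ch in seq_len(C)) {
    rows <- (seq_len(n) - 1L) * Vp + cc$amax4[, ch]
    dF4[rows, ch] <- dF4[rows, ch] + dmain_feat[, C + ch]
  }
  dAcomb <- rowSums(dF5 * cc$F4)

  bb2 <- branch_backward(cc$br2, p$attn2, cc$F4, loss_w[3] * ce_a2$dlogits,
                         dAcomb)
  g$attn2 <- list(W = bb2$gW, b = bb2$gb)
  dF4 <- dF4 + bb2$dF

  ru_backward <- function(u, dOut) {
    ru <- cc$ru[[u]]
    pu <- p$res[[u]]
    dpre <- dOut * relu_grad(ru$out_pre)
    dH2 <- dpre
    g$res[[u]] <<- list()
    g$res[[u]]$W2 <<- conv_bwd_w(ru$H1, dH2, geom$pooled)
    g$res[[u]]$b2 <<- colSums(dH2)
    dH1 <- conv_bwd_data(dH2, pu$W2, geom$pooled)
    dH1pre <- dH1 * relu_grad(ru$H1pre)
    g$res[[u]]$W1 <<- conv_bwd_w(ru$Fin, dH1pre, geom$pooled)
    g$res[[u]]$b1 <<- colSums(dH1pre)
    dpre + conv_bwd_data(dH1pre, pu$W1, geom$pooled)
  }

  dcur <- dF4
  for (u in rev(seq(mid + 1L, nres))) dcur <- ru_backward(u, dcur)
  dF2g <- dcur
  dF2 <- dF2g * (1 + fw$A1)
  dA1 <- dAcomb + rowSums(dF2g * cc$F2)

  bb1 <- branch_backward(cc$br1, p$attn1, cc$F2, loss_w[2] * ce_a1$dlogits,
                         dA1)
  g$attn1 <- list(W = bb1$gW, b = bb1$gb)
  dF2 <- dF2 + bb1$dF

  dcur <- dF2
  for (u in rev(seq_len(mid))) dcur <- ru_backward(u, dcur)
  dF0 <- dcur
  dZ <- dF0[gp$unpool, , drop = FALSE] / 8
  dS0 <- dZ * relu_grad(cc$S0)
  g$stem$W <- conv_bwd_w(cc$X, dS0, geom$full)
  g$stem$b <- colSums(dS0)

  list(loss = loss, loss_main = ce_main$loss, loss_aux1 = ce_a1$loss,
       loss_aux2 = ce_a2$loss, grads = g)
}

# Elementwise update over the nested parameter/gradient structures.
sgd_step <- function(params, grads, vel, lr, momentum) {
  upd <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in seq_along(p)) {
        r <- upd(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      v_new <- momentum * v - lr * g
      list(p = p + v_new, v = v_new)
    }
  }
  upd(params, grads, vel)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

grad_sq_norm <- function(g) {
  if (is.list(g)) sum(vapply(g, grad_sq_norm, numeric(1))) else sum(g^2)
}

scale_grads <- function(g, s) {
  if (is.list(g)) lapply(g, scale_grads, s = s) else g * s
}

#' Train the network on preprocessed half-chest samples
#'
#' Minimizes the equal-weighted (configurable) sum of the main three-class
#' cross-entropy and the two masked auxiliary cross-entropies by stochastic
#' gradient descent. Deterministic given the configuration seed and sample
#' order (up to floating-point reduction order).
#'
#' @param model an [build_network()] model.
#' @param samples list of `list(x = <4D array (z,y,x,2) in [0,1]>, label = )`
#'   with labels among no_cancer/normal, cancer_no_LNM, cancer_LNM.
#' @param config a [train_config()].
#' @return list with the trained `model` and `loss_trace` (per-epoch data
#'   frame of total/main/aux losses).
#' @export
train_network <- function(model, samples, config = train_config()) {
  stopifnot(inherits(model, "ax_network"), inherits(config, "train_config"))
  if (length(samples) == 0) stop("empty training set", call. = FALSE)
  labels <- vapply(samples, function(s) s$label, character(1))
  labels[labels == "normal"] <- "no_cancer"
  if (length(unique(labels)) < 2) {
    stop("training requires at least two classes", call. = FALSE)
  }
  y_main <- match(labels, model$classes)
  if (anyNA(y_main)) stop("unknown sample label", call. = FALSE)
  aux <- lapply(labels, aux_targets)
  to_idx <- function(t) ifelse(is.na(t), NA_integer_,
                               ifelse(t == "positive", 2L, 1L))
  y_aux1 <- to_idx(vapply(aux, `[[`, character(1), "task1"))
  y_aux2 <- to_idx(vapply(aux, `[[`, character(1), "task2"))

  X_all <- stack_inputs(model, lapply(samples, `[[`, "x"))
  n <- length(samples)
  V <- prod(model$input_shape)
  geoms <- new.env(parent = emptyenv())
  get_geom <- function(m) {
    key <- as.character(m)
    if (is.null(geoms[[key]])) geoms[[key]] <- make_geometry(model, m)
    geoms[[key]]
  }

  vel <- zero_like(model$params)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      loss_main = numeric(0), loss_aux1 = numeric(0),
                      loss_aux2 = numeric(0))
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      warm <- if (config$warmup_epochs > 0) min(1, ep / config$warmup_epochs)
              else 1
      lr_ep <- config$learning_rate * warm * config$lr_decay^(ep - 1L)
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      ep_loss <- c(0, 0, 0, 0)
      nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        take <- ord[start:min(start + bs - 1L, n)]
        rows <- as.vector(outer(seq_len(V), (take - 1L) * V, `+`))
        bres <- backward_net(model, X_all[rows, , drop = FALSE],
                             get_geom(length(take)),
                             y_main[take], y_aux1[take], y_aux2[take],
                             config$loss_weights)
        if (!is.finite(bres$loss)) {
          stop("training diverged (non-finite loss); lower the learning rate",
               call. = FALSE)
        }
        gnorm <- sqrt(grad_sq_norm(bres$grads))
        if (is.finite(config$clip_norm) && gnorm > config$clip_norm) {
          bres$grads <- scale_grads(bres$grads, config$clip_norm / gnorm)
        }
        st <- sgd_step(model$params, bres$grads, vel, lr_ep, config$momentum)
        model$params <- st$p
        vel <- st$v
        ep_loss <- ep_loss + c(bres$loss, bres$loss_main, bres$loss_aux1,
                               bres$loss_aux2)
        nb <- nb + 1L
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss[1] / nb,
                                       loss_main = ep_loss[2] / nb,
                                       loss_aux1 = ep_loss[3] / nb,
                                       loss_aux2 = ep_loss[4] / nb))
      if (!is.null(config$early_stop_loss) &&
          ep_loss[1] / nb < config$early_stop_loss) break
    }
  })
  list(model = model, loss_trace = trace)
}

#' Forward pass returning scores and attention maps
#'
#' @param model an `ax_network`.
#' @param x preprocessed 4D input array (z, y, x, 2).
#' @param zero_combined if TRUE, ablates the combined attention map (sets it
#'   to zero on the forward path) — for attention-pathway diagnostics.
#' @return list with `main_scores` (named 3-vector of class probabilities),
#'   `aux1_scores`, `aux2_scores` (named 2-vectors), `attention_map_1`,
#'   `attention_map_2`, `combined_attention` (3D arrays at the pooled
#'   resolution; combined = map1 + map2).
#' @export
predict_network <- function(model, x, zero_combined = FALSE) {
  stopifnot(inherits(model, "ax_network"))
  X <- stack_inputs(model, list(x))
  geom <- make_geometry(model, 1L)
  fw <- forward_net(model, X, geom, zero_combined = zero_combined)
  dp <- geom$pool$dims_pooled
  main <- drop(softmax_rows(fw$main_logits))
  names(main) <- model$classes
  a1 <- drop(softmax_rows(fw$aux1_logits))
  names(a1) <- c("negative", "positive")
  a2 <- drop(softmax_rows(fw$aux2_logits))
  names(a2) <- c("negative", "positive")
  list(main_scores = main, aux1_scores = a1, aux2_scores = a2,
       attention_map_1 = array(fw$A1, dim = dp),
       attention_map_2 = array(fw$A2, dim = dp),
       combined_attention = array(fw$Acomb, dim = dp))
}

#' AI metastasis probability from the three-class head
#'
#' The bridge from the classifier to the fusion stage: the posterior of nodal
#' metastasis given cancer presence, `p3 / (p2 + p3)` from the main softmax.
#'
#' @param model an `ax_network`.
#' @param x preprocessed 4D input array.
#' @return probability in [0, 1].
#' @export
predict_lnm_probability <- function(model, x) {
  p <- predict_network(model, x)$main_scores
  denom <- p[["cancer_no_LNM"]] + p[["cancer_LNM"]]
  if (denom < 1e-12) {
    stop("cancer-class posterior mass is numerically zero; the LNM ",
         "probability is undefined", call. = FALSE)
  }
  unname(p[["cancer_LNM"]] / denom)
}

#' Downsample a lesion mask to the attention-map resolution
#'
#' Pools a voxel mask by 2x2x2 blocks (a pooled voxel is inside if any of its
#' 8 source voxels is), matching the resolution of the network's attention
#' maps.
#'
#' @param mask 3D logical array with even dimensions.
#' @return 3D logical array of halved dimensions.
#' @export
pool_mask <- function(mask) {
  gp <- pool_geometry(dim(mask), 1L)
  array(rowsum(as.numeric(mask), gp$unpool, reorder = TRUE) > 0,
        dim = gp$dims_pooled)
}
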