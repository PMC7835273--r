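test_that("auxiliary targets mask the out-of-task class", {
  expect_equal(aux_targets("no_cancer"),
               list(task1 = "negative", task2 = NA_character_))
  expect_equal(aux_targets("normal"),
               list(task1 = "negative", task2 = NA_character_))
  expect_equal(aux_targets("cancer_no_LNM"),
               list(task1 = "positive", task2 = "negative"))
  expect_equal(aux_targets("cancer_LNM"),
               list(task1 = NA_character_, task2 = "positive"))
  expect_error(aux_targets("lung"), "unknown")
})

test_that("network configuration enforces the two-branch three-class shape", {
  cfg <- network_config()
  expect_identical(cfg$n_residual_units, 4L)
  expect_identical(cfg$attention_branches,
                   c("cancer_vs_normal", "lnm_vs_cancer"))
  expect_error(network_config(n_residual_units = 3), "even")
  expect_error(network_config(n_classes = 2), "three-class")
  expect_error(build_network(input_shape = c(7, 8, 8)), "even")
})

test_that("the forward pass satisfies the shape and probability contracts", {
  model <- build_network(network_config(channel_width = 4L),
                         input_shape = c(6L, 8L, 4L), seed = 3)
  x <- with_seed(1, array(runif(6 * 8 * 4 * 2), dim = c(6, 8, 4, 2)))
  out <- predict_network(model, x)
  expect_equal(sum(out$main_scores), 1)
  expect_equal(sum(out$aux1_scores), 1)
  expect_equal(sum(out$aux2_scores), 1)
  expect_true(all(is.finite(out$main_scores)))
  expect_identical(dim(out$attention_map_1), c(3L, 4L, 2L))
  expect_identical(dim(out$combined_attention), c(3L, 4L, 2L))
  expect_true(all(out$attention_map_1 >= 0 & out$attention_map_1 <= 1))
  expect_equal(out$combined_attention,
               out$attention_map_1 + out$attention_map_2)
})

test_that("attention sits on the forward path of the main classifier", {
  model <- build_network(network_config(channel_width = 4L),
                         input_shape = c(6L, 8L, 4L), seed = 3)
  x <- with_seed(2, array(runif(6 * 8 * 4 * 2), dim = c(6, 8, 4, 2)))
  with_att <- predict_network(model, x)
  ablated <- predict_network(model, x, zero_combined = TRUE)
  expect_false(isTRUE(all.equal(with_att$main_scores, ablated$main_scores)))
  expect_true(all(ablated$combined_attention == 0))
})

test_that("identical seeds build identical networks", {
  x <- with_seed(4, array(runif(6 * 8 * 4 * 2), dim = c(6, 8, 4, 2)))
  m1 <- build_network(network_config(), input_shape = c(6L, 8L, 4L), seed = 11)
  m2 <- build_network(network_config(), input_shape = c(6L, 8L, 4L), seed = 11)
  expect_identical(m1$params, m2$params)
  expect_equal(predict_network(m1, x), predict_network(m2, x))
  m3 <- build_network(network_config(), input_shape = c(6L, 8L, 4L), seed = 12)
  expect_false(identical(m1$params, m3$params))
})

test_that("residual units reduce to the identity at zero transform weights", {
  geom <- axfuse:::conv_geometry(c(4L, 4L, 2L), 2L)
  C <- 3L
  zero_W <- lapply(1:27, function(o) matrix(0, C, C))
  Fin <- with_seed(5, matrix(runif(4 * 4 * 2 * 2 * C), ncol = C))  # nonneg
  H1 <- axfuse:::relu(axfuse:::conv_fwd(Fin, zero_W, numeric(C), geom))
  H2 <- axfuse:::conv_fwd(H1, zero_W, numeric(C), geom)
  out <- axfuse:::relu(Fin + H2)
  expect_equal(out, Fin)
})

test_that("convolution adjoints match the forward operator", {
  # <conv(x), y> == <x, conv_transpose(y)> on random tensors
  geom <- axfuse:::conv_geometry(c(4L, 3L, 2L), 2L)
  with_seed(6, {
    W <- lapply(1:27, function(o) matrix(rnorm(6), 2, 3))
    X <- matrix(rnorm(4 * 3 * 2 * 2 * 2), ncol = 2)
    Y <- matrix(rnorm(4 * 3 * 2 * 2 * 3), ncol = 3)
  })
  lhs <- sum(axfuse:::conv_fwd(X, W, numeric(3), geom) * Y)
  rhs <- sum(X * axfuse:::conv_bwd_data(Y, W, geom))
  expect_equal(lhs, rhs)
})

test_that("untrained balanced loss sits at the uniform-prediction value", {
  # ln 3 for the 3-class head plus ln 2 for each two-class auxiliary head
  model <- build_network(network_config(channel_width = 4L),
                         input_shape = c(6L, 8L, 4L), seed = 7)
  xs <- with_seed(8, lapply(1:6, function(i)
    array(runif(6 * 8 * 4 * 2), dim = c(6, 8, 4, 2))))
  labels <- rep(c("no_cancer", "cancer_no_LNM", "cancer_LNM"), 2)
  samples <- Map(function(x, l) list(x = x, label = l), xs, labels)
  fit <- train_network(model, samples,
                       train_config(learning_rate = 1e-9, epochs = 1L))
  expect_lt(abs(fit$loss_trace$loss[1] - (log(3) + 2 * log(2))), 0.1)
})

test_that("zero-weighted auxiliary losses leave gradients untouched", {
  model <- build_network(network_config(channel_width = 4L),
                         input_shape = c(6L, 8L, 4L), seed = 9)
  xs <- with_seed(10, lapply(1:4, function(i)
    array(runif(6 * 8 * 4 * 2), dim = c(6, 8, 4, 2))))
  X <- axfuse:::stack_inputs(model, xs)
  geom <- axfuse:::make_geometry(model, 4L)
  y_main <- c(1L, 2L, 3L, 2L)
  b1 <- axfuse:::backward_net(model, X, geom, y_main,
                              c(1L, 2L, NA, 2L), c(NA, 1L, 2L, 1L),
                              loss_w = c(1, 0, 0))
  # permuting the auxiliary targets must not change any gradient
  b2 <- axfuse:::backward_net(model, X, geom, y_main,
                              c(2L, 1L, NA, 1L), c(NA, 2L, 1L, 2L),
                              loss_w = c(1, 0, 0))
  expect_equal(b1$grads, b2$grads)
  expect_equal(b1$loss, b2$loss)
})

test_that("LNM probability is the renormalized cancer-class posterior", {
  model <- build_network(network_config(channel_width = 4L),
                         input_shape = c(6L, 8L, 4L), seed = 13)
  x <- with_seed(14, array(runif(6 * 8 * 4 * 2), dim = c(6, 8, 4, 2)))
  scores <- predict_network(model, x)$main_scores
  expect_equal(predict_lnm_probability(model, x),
               unname(scores[["cancer_LNM"]] /
                        (scores[["cancer_no_LNM"]] + scores[["cancer_LNM"]])))

  # a head collapsed onto the no-cancer class makes the posterior undefined
  degenerate <- model
  degenerate$params$main$W[] <- 0
  degenerate$params$main$b <- c(800, -800, -800)
  expect_error(predict_lnm_probability(degenerate, x), "undefined")
})

test_that("training rejects degenerate datasets and reduces the loss", {
  model <- build_network(network_config(channel_width = 4L),
                         input_shape = c(6L, 8L, 4L), seed = 15)
  expect_error(train_network(model, list()), "empty")
  one_class <- list(list(x = array(0.5, c(6, 8, 4, 2)), label = "cancer_LNM"),
                    list(x = array(0.4, c(6, 8, 4, 2)), label = "cancer_LNM"))
  expect_error(train_network(model, one_class), "two classes")

  xs <- with_seed(16, lapply(1:8, function(i) {
    base <- array(0.1 * (i %% 2), dim = c(6, 8, 4, 2))
    base + array(runif(length(base), 0, 0.05), dim = dim(base))
  }))
  labels <- rep(c("no_cancer", "cancer_LNM"), 4)
  samples <- Map(function(x, l) list(x = x, label = l), xs, labels)
  fit <- train_network(model, samples,
                       train_config(learning_rate = 0.05, momentum = 0.9,
                                    epochs = 15L, seed = 1))
  expect_lt(fit$loss_trace$loss[15], fit$loss_trace$loss[1])
  # same seed and data reproduce the trace
  fit2 <- train_network(build_network(network_config(channel_width = 4L),
                                      input_shape = c(6L, 8L, 4L), seed = 15),
                        samples,
                        train_config(learning_rate = 0.05, momentum = 0.9,
                                     epochs = 15L, seed = 1))
  expect_equal(fit$loss_trace, fit2$loss_trace)
})

test_that("lesion masks pool to the attention-map resolution", {
  mask <- array(FALSE, dim = c(4, 4, 2))
  mask[3, 3, 1] <- TRUE
  pm <- pool_mask(mask)
  expect_identical(dim(pm), c(2L, 2L, 1L))
  expect_identical(which(pm), 4L)  # block (2,2,1)
  expect_identical(sum(pm), 1L)
})
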