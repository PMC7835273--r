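#' Phantom specification
#'
#' Parameters of the synthetic paired PET/CT chest volume: a uniform
#' soft-tissue background with Gaussian hot spots standing in for the breast
#' tumor and the axillary node, plus additive Gaussian noise. Volumes are
#' indexed (axial z: superior -> inferior, anterior-posterior y, lateral x);
#' the lateral axis is split at the midline into left/right half-chests.
#'
#' @param volume_shape integer length-3 (z, y, x); x must be even so the
#'   midline split is exact. Default 32 x 48 x 48.
#' @param background_suv background PET intensity in SUV (default 0.8).
#' @param tumor_suv,node_suv peak lesion SUVs (defaults 8 and 3.5; axillary
#'   nodes are typically fainter than the primary).
#' @param tumor_sigma,node_sigma isotropic Gaussian widths in voxels.
#' @param ct_background_hu CT background in Hounsfield units (default 0,
#'   water-like soft tissue).
#' @param ct_tumor_hu,ct_node_hu peak CT intensities of the two lesion types
#'   (defaults 80 and -60): the primary is rendered as an enhancing mass, the
#'   metastatic node with a hypodense (necrotic) core. The opposite CT
#'   contrast makes node voxels linearly separable from every point of the
#'   tumor's intensity profile in joint (PET, CT) space, so the classes are
#'   separable by construction.
#' @param noise_sd additive Gaussian noise SD, applied to PET in SUV and
#'   (scaled by 20) to CT in HU.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(32L, 48L, 48L),
                         background_suv = 0.8, tumor_suv = 8, node_suv = 3.5,
                         tumor_sigma = 2.5, node_sigma = 1.5,
                         ct_background_hu = 0, ct_tumor_hu = 80,
                         ct_node_hu = -60, noise_sd = 0.1, seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 4))
  if (volume_shape[3] %% 2L != 0L) {
    stop("the lateral dimension must be even (midline split)", call. = FALSE)
  }
  if (tumor_suv <= background_suv || node_suv <= background_suv) {
    stop("lesion peak SUVs must exceed the background", call. = FALSE)
  }
  stopifnot(tumor_sigma > 0, node_sigma > 0, noise_sd >= 0)
  structure(list(volume_shape = volume_shape, background_suv = background_suv,
                 tumor_suv = tumor_suv, node_suv = node_suv,
                 tumor_sigma = tumor_sigma, node_sigma = node_sigma,
                 ct_background_hu = ct_background_hu,
                 ct_tumor_hu = ct_tumor_hu, ct_node_hu = ct_node_hu,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Preprocessing configuration
#'
#' Intensity clipping/normalization applied before the network: PET voxels
#' above `suv_cutoff` are assigned the cutoff and the channel is scaled to
#' [0, 1]; CT voxels are clipped to [`hu_low`, `hu_high`] and mapped affinely
#' (increasing) onto [0, 1].
#'
#' @param suv_cutoff positive SUV ceiling (default 6).
#' @param hu_low,hu_high HU window (defaults -100 and 200).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(suv_cutoff = 6, hu_low = -100, hu_high = 200) {
  stopifnot(suv_cutoff > 0, hu_low < hu_high)
  structure(list(suv_cutoff = suv_cutoff, hu_low = hu_low, hu_high = hu_high),
            class = "preprocess_config")
}

# Anatomical sub-boxes in normalized (z, y, x-within-half) coordinates.
# Breast tumor: mid-inferior, anterior; axillary node: superior, lateral.
# The z and y ranges of the two boxes are disjoint with a margin so that the
# half-maximum masks of default-width lesions can never touch.
.tumor_box <- list(z = c(0.55, 0.85), y = c(0.65, 0.90), x = c(0.25, 0.70))
.node_box  <- list(z = c(0.05, 0.25), y = c(0.20, 0.45), x = c(0.55, 0.90))

# Draw a lesion center uniformly inside a normalized sub-box on one side.
# Half x in [0,1] maps to the lateral voxel range of that side; for the left
# side (x indices 1..nx/2) lateral means small x, mirrored for the right.
lesion_center <- function(box, shape, side) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  u <- stats::runif(3)
  cz <- box$z[1] + u[1] * diff(box$z)
  cy <- box$y[1] + u[2] * diff(box$y)
  cxh <- box$x[1] + u[3] * diff(box$x)  # 0 = midline, 1 = lateral edge
  half <- nx / 2
  cx <- if (side == "left") half - cxh * (half - 1)
        else half + 1 + cxh * (half - 1)
  c(cz * (nz - 1) + 1, cy * (ny - 1) + 1, cx)
}

# Gaussian bump of unit peak at `center` with width `sigma` over the volume.
gaussian_bump <- function(shape, center, sigma) {
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  gz <- exp(-(z - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(y - center[2])^2 / (2 * sigma^2))
  gx <- exp(-(x - center[3])^2 / (2 * sigma^2))
  outer(outer(gz, gy), gx)
}

#' Generate a whole-chest PET/CT phantom
#'
#' Builds paired PET (SUV) and CT (HU) volumes for one simulated subject:
#' background plus a breast-region tumor hot spot when `label != "normal"` and
#' an axillary-region node hot spot when `label == "cancer_LNM"`, with
#' additive Gaussian noise. Lesion centers are drawn uniformly within fixed
#' anatomical sub-boxes on a randomly chosen side. Lesion masks are the
#' full-width-half-maximum regions of each Gaussian, disjoint by construction
#' of the sub-boxes. Uses the current RNG state (seed upstream for
#' reproducibility).
#'
#' @param label `"normal"`, `"cancer_no_LNM"` or `"cancer_LNM"`.
#' @param spec a [phantom_spec()].
#' @param side lesion side, `"left"`, `"right"`, or `"random"` (default).
#' @return list with 3D arrays `pet`, `ct`, logical `tumor_mask`,
#'   `node_mask`, and the lesion `side` (NA for normal phantoms).
#' @export
generate_phantom <- function(label, spec = phantom_spec(), side = "random") {
  stopifnot(label %in% c("normal", "cancer_no_LNM", "cancer_LNM"),
            inherits(spec, "phantom_spec"))
  shape <- spec$volume_shape
  half_extent <- c(shape[1], shape[2], shape[3] / 2)
  box_extent <- function(box) {
    c(diff(box$z) * shape[1], diff(box$y) * shape[2], diff(box$x) * half_extent[3])
  }
  if (label != "normal" && any(box_extent(.tumor_box) < spec$tumor_sigma)) {
    stop("tumor_sigma exceeds the breast sub-box extent", call. = FALSE)
  }
  if (label == "cancer_LNM" && any(box_extent(.node_box) < spec$node_sigma)) {
    stop("node_sigma exceeds the axillary sub-box extent", call. = FALSE)
  }
  if (side == "random") side <- sample(c("left", "right"), 1L)

  pet <- array(spec$background_suv, dim = shape)
  ct <- array(spec$ct_background_hu, dim = shape)
  tumor_mask <- array(FALSE, dim = shape)
  node_mask <- array(FALSE, dim = shape)
  lesion_side <- NA_character_

  if (label != "normal") {
    lesion_side <- side
    ctr <- lesion_center(.tumor_box, shape, side)
    bump <- gaussian_bump(shape, ctr, spec$tumor_sigma)
    pet <- pet + (spec$tumor_suv - spec$background_suv) * bump
    ct <- ct + (spec$ct_tumor_hu - spec$ct_background_hu) * bump
    tumor_mask <- bump > 0.5
  }
  if (label == "cancer_LNM") {
    ctr <- lesion_center(.node_box, shape, side)
    bump <- gaussian_bump(shape, ctr, spec$node_sigma)
    pet <- pet + (spec$node_suv - spec$background_suv) * bump
    ct <- ct + (spec$ct_node_hu - spec$ct_background_hu) * bump
    node_mask <- bump > 0.5
  }
  nvox <- prod(shape)
  pet <- pet + stats::rnorm(nvox, sd = spec$noise_sd)
  ct <- ct + stats::rnorm(nvox, sd = 20 * spec$noise_sd)
  list(pet = pet, ct = ct, tumor_mask = tumor_mask, node_mask = node_mask,
       side = lesion_side, label = label)
}

#' Split a whole-chest phantom at the midline
#'
#' Separates the paired volumes into left and right half-chest samples along
#' the lateral axis (left = lateral indices 1..nx/2). Each half is labeled by
#' the lesions whose mask centroid falls inside it; a half with no lesion is a
#' normal sample. Concatenating the halves along x reconstructs the input
#' exactly.
#'
#' @param phantom output of [generate_phantom()] (fields `pet`, `ct`,
#'   `tumor_mask`, `node_mask`).
#' @return list of two `half_chest_sample` objects (`left`, `right`), each
#'   with `pet`, `ct`, `side`, `label`, `tumor_mask`, `node_mask`.
#' @export
split_sides <- function(phantom) {
  shape <- dim(phantom$pet)
  stopifnot(length(shape) == 3, identical(dim(phantom$ct), shape))
  nx <- shape[3]
  if (nx %% 2L != 0L) {
    stop("the lateral dimension must be even to split at the midline",
         call. = FALSE)
  }
  half <- nx / 2
  idx <- list(left = seq_len(half), right = seq(half + 1L, nx))
  centroid_x <- function(mask) {
    if (!any(mask)) return(NA_real_)
    mean(arrayInd(which(mask), dim(mask))[, 3])
  }
  tx <- centroid_x(phantom$tumor_mask)
  nxc <- centroid_x(phantom$node_mask)
  out <- lapply(names(idx), function(s) {
    cols <- idx[[s]]
    in_half <- function(cx) !is.na(cx) && (cx <= half + 0.5) == (s == "left")
    label <- if (in_half(nxc)) "cancer_LNM"
             else if (in_half(tx)) "cancer_no_LNM"
             else "normal"
    structure(list(
      pet = phantom$pet[, , cols, drop = FALSE],
      ct = phantom$ct[, , cols, drop = FALSE],
      tumor_mask = if (in_half(tx)) phantom$tumor_mask[, , cols, drop = FALSE]
                   else array(FALSE, dim = c(shape[1:2], half)),
      node_mask = if (in_half(nxc)) phantom$node_mask[, , cols, drop = FALSE]
                  else array(FALSE, dim = c(shape[1:2], half)),
      side = s, label = label), class = "half_chest_sample")
  })
  names(out) <- names(idx)
  out
}

#' Preprocess a half-chest sample for the network
#'
#' PET is clipped to [0, `suv_cutoff`] and divided by the cutoff; CT is
#' clipped to the HU window and mapped affinely onto [0, 1]
#' (hu_low -> 0, hu_high -> 1). The two channels are stacked PET-first into a
#' 4D array (z, y, x, channel), all values in [0, 1].
#'
#' @param sample a `half_chest_sample` (or any list with `pet` and `ct`
#'   arrays of equal shape).
#' @param config a [preprocess_config()].
#' @return 4D numeric array (z, y, x, 2) with values in [0, 1].
#' @export
preprocess <- function(sample, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  pet <- sample$pet; ct <- sample$ct
  stopifnot(identical(dim(pet), dim(ct)))
  if (!all(is.finite(pet)) || !all(is.finite(ct))) {
    stop("volumes contain non-finite voxels", call. = FALSE)
  }
  petn <- pmin(pmax(pet, 0), config$suv_cutoff) / config$suv_cutoff
  ctn <- (pmin(pmax(ct, config$hu_low), config$hu_high) - config$hu_low) /
    (config$hu_high - config$hu_low)
  out <- array(0, dim = c(dim(pet), 2L))
  out[, , , 1L] <- petn
  out[, , , 2L] <- ctn
  out
}
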