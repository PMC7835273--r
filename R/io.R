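#' Read a diagnosis records CSV
#'
#' Canonical record schema: columns `sample_id`, `patient_id`, `side`,
#' `grade`, `p_ai`, and optionally `pathology` (0/1). Grades are validated as
#' integers in 1..5 and probabilities as [0, 1]; violations are reported with
#' the offending row number.
#'
#' @param path path to a CSV file.
#' @param require_pathology error if the pathology column is absent.
#' @return validated data frame of diagnosis records.
#' @export
read_records <- function(path, require_pathology = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "patient_id", "side", "grade", "p_ai")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("records file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (require_pathology && is.null(df$pathology)) {
    stop("records file has no `pathology` column", call. = FALSE)
  }
  # ungraded (normal) sides may carry NA for both grade and p_ai
  ungraded <- is.na(df$grade) & is.na(df$p_ai)
  grade <- suppressWarnings(as.numeric(df$grade))
  bad <- which(!ungraded &
                 (is.na(grade) | grade != round(grade) | grade < 1 | grade > 5))
  if (length(bad)) {
    stop("invalid grade in row ", bad[1], ": ", df$grade[bad[1]],
         call. = FALSE)
  }
  df$grade <- as.integer(grade)
  p_ai <- suppressWarnings(as.numeric(df$p_ai))
  bad <- which(!ungraded & (is.na(p_ai) | p_ai < 0 | p_ai > 1))
  if (length(bad)) {
    stop("invalid p_ai in row ", bad[1], ": ", df$p_ai[bad[1]],
         call. = FALSE)
  }
  df$p_ai <- p_ai
  if (!is.null(df$pathology)) {
    bad <- which(!df$pathology %in% c(0, 1))
    if (length(bad)) {
      stop("invalid pathology in row ", bad[1], ": ", df$pathology[bad[1]],
           call. = FALSE)
    }
    df$pathology <- as.integer(df$pathology)
  }
  df
}

#' Write diagnosis or fused records to CSV
#'
#' @param records data frame of (possibly fused) records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate fused records into a report object
#'
#' Bundles the study's evaluation outputs for one set of fused records:
#' dichotomized metrics at each grade cutoff before and after AI assistance,
#' the regrade transition table, the confidence-retention curve, and (when
#' scores are available) the ROC/AUC with its Youden-optimal point.
#'
#' @param fused data frame from [fuse_records()] including `pathology`.
#' @param cutoffs list of positive-grade sets (default the nested
#'   \{5\}, \{4,5\}, \{3,4,5\}).
#' @return object of class `ax_report` (a nested list, JSON-serializable via
#'   [write_report()]).
#' @export
evaluate_records <- function(fused,
                             cutoffs = list(`5` = 5L, `45` = 4:5,
                                            `345` = 3:5)) {
  stopifnot(is.data.frame(fused))
  if (is.null(fused$pathology)) {
    stop("evaluation requires pathology truth", call. = FALSE)
  }
  counts_in <- tally_grades(data.frame(grade = fused$grade,
                                       pathology = fused$pathology))
  has_fusion <- !is.null(fused$grade_out)
  counts_out <- if (has_fusion) {
    tally_grades(data.frame(grade = fused$grade_out,
                            pathology = fused$pathology))
  } else NULL

  metrics <- lapply(cutoffs, function(cut) {
    m <- list(without_ai = unclass(dichotomize(counts_in, cut)))
    if (has_fusion) m$with_ai <- unclass(dichotomize(counts_out, cut))
    m$positive_grades <- as.integer(cut)
    m
  })

  report <- list(
    n_records = nrow(fused),
    grade_counts = list(positives = counts_in$positives,
                        negatives = counts_in$negatives),
    metrics = metrics
  )
  if (has_fusion) {
    tt <- transition_table(fused)
    report$transition_table <- list(counts = tt$counts, effects = tt$effects)
    report$effect_summary <- as.list(table(fused$effect))
  }
  if (!is.null(fused$p_ai) && !anyNA(fused$p_ai)) {
    roc <- roc_curve(fused$p_ai, fused$pathology)
    yj <- youden_optimal(roc)
    report$roc <- list(auc = roc$auc, points = roc$points,
                       youden = list(threshold = yj$threshold,
                                     youden_j = yj$youden_j,
                                     metrics = unclass(yj$metrics)))
    report$retention <- retention_curve(fused$p_ai)$curve
  }
  structure(report, class = "ax_report")
}

#' Write an evaluation report as JSON
#'
#' @param report an [evaluate_records()] report (or any JSON-serializable
#'   list).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass_recursive(report), digits = NA,
                           auto_unbox = TRUE, pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read an evaluation report back from JSON
#'
#' @param path path to a JSON report written by [write_report()].
#' @return nested list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

unclass_recursive <- function(x) {
  if (is.array(x) && length(dim(x)) > 2) {
    # JSON has no native >2-d arrays; flatten with an explicit dim record
    return(list(dim = dim(x), dimnames = dimnames(x), values = as.vector(x)))
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}

#' Read fusion settings from a YAML/JSON config file
#'
#' The file may hold `grade_scale` (fields `grade_to_prob`,
#' `bin_upper_percents`) and `fusion_config` (fields `confidence_threshold`,
#' `gate_comparison`) blocks; omitted blocks fall back to defaults. The
#' mapping is lossless: writing with [write_fusion_settings()] and reading
#' back reproduces the configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `scale` ([grade_scale()]) and `config`
#'   ([fusion_config()]).
#' @export
read_fusion_settings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  gs <- raw$grade_scale
  fc <- raw$fusion_config
  scale <- if (is.null(gs)) grade_scale() else {
    do.call(grade_scale, gs[intersect(names(gs),
                                      c("grade_to_prob", "bin_upper_percents"))])
  }
  config <- if (is.null(fc)) fusion_config() else {
    do.call(fusion_config,
            fc[intersect(names(fc),
                         c("confidence_threshold", "gate_comparison"))])
  }
  list(scale = scale, config = config)
}

#' Write fusion settings to a YAML config file
#'
#' @param scale a [grade_scale()].
#' @param config a [fusion_config()].
#' @param path output path (`.yaml`).
#' @return the path, invisibly.
#' @export
write_fusion_settings <- function(scale, config, path) {
  yaml::write_yaml(list(
    grade_scale = list(grade_to_prob = scale$grade_to_prob,
                       bin_upper_percents = scale$bin_upper_percents),
    fusion_config = list(confidence_threshold = config$confidence_threshold,
                         gate_comparison = config$gate_comparison)
  ), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what a command-line (or scripted) run did: the command, its
#' parameters, the seeds in play, input/output paths, package version and a
#' timestamp. Deterministic stages rerun with an identical manifest (modulo
#' timestamp) reproduce identical outputs.
#'
#' @param command the subcommand or function name.
#' @param params named list of parameters/configuration.
#' @param seeds named list or vector of seeds.
#' @param inputs,outputs character vectors of paths.
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(command, params = list(), seeds = list(),
                           inputs = character(0), outputs = character(0),
                           path) {
  manifest <- list(
    command = command,
    params = params,
    config_hash = digest_params(params),
    seeds = seeds,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("axfuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(manifest)
}

# Stable content hash of a parameter list (sum-based rolling hash over the
# serialized bytes; identification only, not cryptographic).
digest_params <- function(params) {
  bytes <- serialize(params, NULL, version = 2)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write half-chest volumes as NIfTI files
#'
#' One NIfTI file per channel (`<id>_pet.nii.gz`, `<id>_ct.nii.gz`) plus a
#' sidecar JSON with label, side and lesion-mask voxel indices. Requires the
#' RNifti package.
#'
#' @param sample a `half_chest_sample` from [split_sides()].
#' @param id file stem.
#' @param dir output directory.
#' @return character vector of paths written, invisibly.
#' @export
write_half_chest <- function(sample, id, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI volumes requires the RNifti package", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pet_path <- file.path(dir, paste0(id, "_pet.nii.gz"))
  ct_path <- file.path(dir, paste0(id, "_ct.nii.gz"))
  meta_path <- file.path(dir, paste0(id, ".json"))
  RNifti::writeNifti(RNifti::asNifti(sample$pet), pet_path)
  RNifti::writeNifti(RNifti::asNifti(sample$ct), ct_path)
  writeLines(jsonlite::toJSON(list(
    id = id, side = sample$side, label = sample$label,
    dim = dim(sample$pet),
    tumor_mask_voxels = which(sample$tumor_mask),
    node_mask_voxels = which(sample$node_mask)
  ), auto_unbox = TRUE, digits = NA), meta_path)
  invisible(c(pet_path, ct_path, meta_path))
}

#' Read a half-chest sample written by [write_half_chest()]
#'
#' @param id file stem.
#' @param dir directory holding the files.
#' @return a `half_chest_sample` list.
#' @export
read_half_chest <- function(id, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(file.path(dir, paste0(id, ".json")))
  pet <- array(as.numeric(RNifti::readNifti(
    file.path(dir, paste0(id, "_pet.nii.gz")))), dim = meta$dim)
  ct <- array(as.numeric(RNifti::readNifti(
    file.path(dir, paste0(id, "_ct.nii.gz")))), dim = meta$dim)
  tm <- array(FALSE, dim = meta$dim)
  tm[as.integer(unlist(meta$tumor_mask_voxels))] <- TRUE
  nm <- array(FALSE, dim = meta$dim)
  nm[as.integer(unlist(meta$node_mask_voxels))] <- TRUE
  structure(list(pet = pet, ct = ct, tumor_mask = tm, node_mask = nm,
                 side = meta$side, label = meta$label),
            class = "half_chest_sample")
}
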