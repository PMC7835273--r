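#' Cohort specification
#'
#' Defines the size and composition of a synthetic study cohort of breast
#' cancer patients imaged by FDG-PET/CT. Defaults mirror the study structure:
#' 407 patients of whom 7 have bilateral cancer (414 cancer sides), 204 sides
#' with pathology-proven axillary lymph node metastasis; each patient
#' contributes both half-chests, so cancer-free sides serve as normal samples.
#'
#' @param n_patients number of patients (default 407).
#' @param n_bilateral number of patients with bilateral cancer (default 7).
#' @param n_metastatic_sides number of cancer sides with nodal metastasis
#'   (default 204).
#' @param seed integer seed controlling every random draw.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 407L, n_bilateral = 7L,
                        n_metastatic_sides = 204L, seed = 1L) {
  n_patients <- as.integer(n_patients)
  n_bilateral <- as.integer(n_bilateral)
  n_metastatic_sides <- as.integer(n_metastatic_sides)
  if (n_patients < 1 || n_bilateral < 0 || n_bilateral > n_patients) {
    stop("need 0 <= n_bilateral <= n_patients and n_patients >= 1",
         call. = FALSE)
  }
  n_sides <- n_patients + n_bilateral
  if (n_metastatic_sides < 0 || n_metastatic_sides > n_sides) {
    stop("n_metastatic_sides must not exceed the number of cancer sides",
         call. = FALSE)
  }
  structure(list(n_patients = n_patients, n_bilateral = n_bilateral,
                 n_metastatic_sides = n_metastatic_sides,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Reader (clinician) error profile
#'
#' Generative model of a clinician's 5-grade reading conditioned on pathology
#' truth, with an optional latent-difficulty tilt: as a sample's difficulty
#' rises, probability mass is pulled toward the indeterminate grade 3 by the
#' factor `exp(-difficulty_coupling * difficulty * |grade - 3|)`. With
#' coupling 0 the profile reduces to its marginal distributions. Defaults are
#' the senior reader's empirical distributions reconstructed from the study's
#' per-grade counts.
#'
#' @param grade_given_positive,grade_given_negative length-5 probability
#'   vectors (sum to 1) for metastatic and non-metastatic cancer sides.
#' @param difficulty_coupling nonnegative scalar.
#' @return object of class `reader_profile`.
#' @export
reader_profile <- function(grade_given_positive = c(19, 34, 29, 46, 76) / 204,
                           grade_given_negative = c(110, 93, 5, 2, 0) / 210,
                           difficulty_coupling = 0) {
  stopifnot(length(grade_given_positive) == 5,
            length(grade_given_negative) == 5,
            difficulty_coupling >= 0)
  if (any(grade_given_positive < 0) || any(grade_given_negative < 0) ||
      abs(sum(grade_given_positive) - 1) > 1e-8 ||
      abs(sum(grade_given_negative) - 1) > 1e-8) {
    stop("grade distributions must be probability vectors summing to 1",
         call. = FALSE)
  }
  structure(list(grade_given_positive = grade_given_positive,
                 grade_given_negative = grade_given_negative,
                 difficulty_coupling = difficulty_coupling),
            class = "reader_profile")
}

#' Junior reader profile
#'
#' The second reader's reconstructed empirical grade distributions, for use as
#' an alternative [reader_profile()].
#' @param difficulty_coupling nonnegative scalar, as in [reader_profile()].
#' @return object of class `reader_profile`.
#' @export
reader_profile_b <- function(difficulty_coupling = 0) {
  reader_profile(grade_given_positive = c(56, 8, 23, 48, 69) / 204,
                 grade_given_negative = c(204, 4, 1, 1, 0) / 210,
                 difficulty_coupling = difficulty_coupling)
}

#' AI error profile
#'
#' Generative model of the AI metastasis probability conditioned on truth:
#' a Beta draw per class, optionally degraded on difficult samples by
#' shrinking toward 0.5 with factor `1 - difficulty_coupling * difficulty`
#' (floored at -1, so couplings above 1/difficulty push the probability past
#' 0.5 onto the wrong side). With coupling 0 the AI output is independent of
#' the reader's given the truth; a positive coupling makes clinician and AI
#' errors co-occur on the same latent-difficulty tail.
#'
#' @param beta_params_positive,beta_params_negative length-2 positive shape
#'   pairs for metastatic / non-metastatic sides.
#' @param difficulty_coupling nonnegative scalar.
#' @return object of class `ai_profile`.
#' @export
ai_profile <- function(beta_params_positive = c(2.5, 1),
                       beta_params_negative = c(1, 2.5),
                       difficulty_coupling = 0) {
  stopifnot(length(beta_params_positive) == 2,
            length(beta_params_negative) == 2,
            difficulty_coupling >= 0)
  if (any(beta_params_positive <= 0) || any(beta_params_negative <= 0)) {
    stop("beta shape parameters must be positive", call. = FALSE)
  }
  structure(list(beta_params_positive = beta_params_positive,
                 beta_params_negative = beta_params_negative,
                 difficulty_coupling = difficulty_coupling),
            class = "ai_profile")
}

#' Simulate one clinician grade
#'
#' @param label `"cancer_no_LNM"` or `"cancer_LNM"` (normal sides are not
#'   graded).
#' @param difficulty latent difficulty in [0, 1].
#' @param profile a [reader_profile()].
#' @return integer grade in 1..5, drawn from the tilted profile using the
#'   current RNG state.
#' @export
simulate_reader <- function(label, difficulty, profile = reader_profile()) {
  if (!label %in% c("cancer_no_LNM", "cancer_LNM")) {
    stop("readers grade cancer sides only", call. = FALSE)
  }
  assert_probability(difficulty, "difficulty")
  base <- if (label == "cancer_LNM") profile$grade_given_positive
          else profile$grade_given_negative
  w <- base * exp(-profile$difficulty_coupling * difficulty * abs(1:5 - 3))
  sample.int(5L, 1L, prob = w)
}

#' Simulate one AI probability
#'
#' @param label `"cancer_no_LNM"` or `"cancer_LNM"`.
#' @param difficulty latent difficulty in [0, 1].
#' @param profile an [ai_profile()].
#' @return AI metastasis probability in [0, 1], drawn with the current RNG.
#' @export
simulate_ai <- function(label, difficulty, profile = ai_profile()) {
  if (!label %in% c("cancer_no_LNM", "cancer_LNM")) {
    stop("the AI bridge probability is defined for cancer sides only",
         call. = FALSE)
  }
  assert_probability(difficulty, "difficulty")
  shp <- if (label == "cancer_LNM") profile$beta_params_positive
         else profile$beta_params_negative
  b <- stats::rbeta(1L, shp[1], shp[2])
  shrink <- pmax(-1, 1 - profile$difficulty_coupling * difficulty)
  p <- 0.5 + (b - 0.5) * shrink
  min(max(p, 0), 1)
}

#' Build a synthetic cohort of half-chest diagnosis records
#'
#' Generates `2 * n_patients` half-chest samples: each patient contributes a
#' left and right side; unilateral patients get a random cancer side,
#' bilateral ones two. `n_metastatic_sides` cancer sides (chosen at random)
#' are labeled `cancer_LNM` (pathology positive), the rest `cancer_no_LNM`.
#' Every sample receives a latent difficulty ~ Beta(2, 5); cancer sides
#' additionally receive a clinician grade and an AI probability drawn from the
#' profiles, both tied to the shared difficulty so that reader and AI errors
#' can be made to co-occur. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param reader a [reader_profile()].
#' @param ai an [ai_profile()].
#' @return data frame with columns `sample_id`, `patient_id`, `side`,
#'   `label`, `difficulty`, `grade` (NA on normal sides), `p_ai` (NA on
#'   normal sides), `pathology` (1 = nodal metastasis, 0 otherwise).
#' @examples
#' records <- build_cohort(cohort_spec(n_patients = 10, n_bilateral = 1,
#'                                     n_metastatic_sides = 5, seed = 7))
#' table(records$label)
#' @export
build_cohort <- function(spec = cohort_spec(), reader = reader_profile(),
                         ai = ai_profile()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(reader, "reader_profile"),
            inherits(ai, "ai_profile"))
  with_seed(spec$seed, {
    np <- spec$n_patients
    n_sides_cancer <- np + spec$n_bilateral
    patient_id <- rep(sprintf("P%04d", seq_len(np)), each = 2L)
    side <- rep(c("left", "right"), times = np)

    bilateral <- sample.int(np, spec$n_bilateral)
    unilateral <- setdiff(seq_len(np), bilateral)
    cancer_side <- ifelse(sample(c(TRUE, FALSE), np, replace = TRUE),
                          "left", "right")
    is_cancer <- logical(2L * np)
    for_left <- seq(1L, 2L * np, by = 2L)
    for_right <- for_left + 1L
    is_cancer[for_left[bilateral]] <- TRUE
    is_cancer[for_right[bilateral]] <- TRUE
    left_cancer <- unilateral[cancer_side[unilateral] == "left"]
    right_cancer <- unilateral[cancer_side[unilateral] == "right"]
    is_cancer[for_left[left_cancer]] <- TRUE
    is_cancer[for_right[right_cancer]] <- TRUE

    label <- rep("normal", 2L * np)
    cancer_idx <- which(is_cancer)
    lnm_idx <- cancer_idx[sample.int(n_sides_cancer, spec$n_metastatic_sides)]
    label[cancer_idx] <- "cancer_no_LNM"
    label[lnm_idx] <- "cancer_LNM"

    difficulty <- stats::rbeta(2L * np, 2, 5)
    grade <- rep(NA_integer_, 2L * np)
    p_ai <- rep(NA_real_, 2L * np)
    for (i in cancer_idx) {
      grade[i] <- simulate_reader(label[i], difficulty[i], reader)
      p_ai[i] <- simulate_ai(label[i], difficulty[i], ai)
    }
    data.frame(
      sample_id = sprintf("%s_%s", patient_id, substr(side, 1, 1)),
      patient_id = patient_id,
      side = side,
      label = label,
      difficulty = difficulty,
      grade = grade,
      p_ai = p_ai,
      pathology = as.integer(label == "cancer_LNM"),
      stringsAsFactors = FALSE
    )
  })
}
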