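#' Reference global-measure table for the SAH study conditions
#'
#' Per-group, per-assessment means and standard deviations of the five
#' global MRI measures (SIENAX-normalised total brain, grey-matter,
#' white-matter and ventricular CSF volumes in mL-equivalent units, and mean
#' grey-matter ADC in 1e-6 mm^2/s) for good-grade SAH patients and paired
#' healthy controls at the three assessments: A1 (< 72 h post-rupture),
#' A2 (5-10 days) and A3 (3 months). These are the default study conditions
#' for [generate_cohort_table()].
#'
#' @return A tibble with columns `timepoint`, `measure`, `patient_mean`,
#'   `patient_sd`, `control_mean`, `control_sd`.
#' @export
sah_reference_measures <- function() {
  tibble::tribble(
    ~timepoint, ~measure,             ~patient_mean, ~patient_sd, ~control_mean, ~control_sd,
    "A1", "total_brain_volume", 1521, 66, 1461, 90,
    "A1", "gm_volume",           790, 44,  746, 50,
    "A1", "wm_volume",           731, 28,  706, 54,
    "A1", "csf_volume",           45, 20,   37,  8,
    "A1", "gm_adc",             1004, 35, 1054, 40,
    "A2", "total_brain_volume", 1502, 68, 1455, 99,
    "A2", "gm_volume",           773, 54,  748, 48,
    "A2", "wm_volume",           729, 29,  707, 54,
    "A2", "csf_volume",           46, 20,   37,  8,
    "A2", "gm_adc",             1010, 33, 1054, 40,
    "A3", "total_brain_volume", 1480, 61, 1461, 90,
    "A3", "gm_volume",           765, 45,  748, 50,
    "A3", "wm_volume",           718, 23,  708, 55,
    "A3", "csf_volume",           55, 26,   37,  8,
    "A3", "gm_adc",             1025, 26, 1053, 41
  )
}

#' Specification of a synthetic two-group cohort
#'
#' Defines the sampling distributions for a patient/control cohort with
#' repeated assessments. Defaults reproduce the study conditions: 27
#' patients, 27 age/sex-paired controls, global measures drawn from
#' independent per-group normals at each of three assessments.
#'
#' @param n_patients,n_controls Group sizes (each >= 2).
#' @param measures Tibble in the format of [sah_reference_measures()].
#' @param age_mean,age_sd,age_range Patient age distribution: ages are drawn
#'   from Normal(`age_mean`, `age_sd`), rounded, and truncated to
#'   `age_range`. Controls copy their paired patient's age with a uniform
#'   jitter of at most 2 years (the pairing criterion).
#' @param sex_ratio Proportion of male patients (default 11/27).
#' @param seed Integer seed; all generation is reproducible given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 27, n_controls = 27,
                        measures = sah_reference_measures(),
                        age_mean = 55, age_sd = 11, age_range = c(31, 77),
                        sex_ratio = 11 / 27,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  n_controls <- as.integer(n_controls)
  if (is.na(n_patients) || is.na(n_controls) || n_patients < 2 || n_controls < 2) {
    stop("group sizes must be integers >= 2", call. = FALSE)
  }
  measures <- tibble::as_tibble(measures)
  needed <- c("timepoint", "measure", "patient_mean", "patient_sd",
              "control_mean", "control_sd")
  if (!all(needed %in% names(measures))) {
    stop("`measures` must have columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!all(measures$timepoint %in% c("A1", "A2", "A3"))) {
    stop("timepoints must be labelled from {A1, A2, A3}", call. = FALSE)
  }
  if (any(measures$patient_sd <= 0) || any(measures$control_sd <= 0)) {
    stop("all standard deviations must be > 0", call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, n_controls = n_controls, measures = measures,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         sex_ratio = sex_ratio, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort table of global MRI measures
#'
#' Draws one row per subject x assessment; each global measure is sampled
#' independently from the per-group normal distribution given in the spec.
#' Controls are age (+/- 2 years) and sex matched to patients by copying the
#' paired patient's demographics with jitter, emulating the recruitment
#' pairing. When group sizes differ, pairing recycles over the smaller group.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group` ("patient"/"control"),
#'   `age`, `sex`, `timepoint`, and one column per measure in the spec.
#' @examples
#' tab <- generate_cohort_table(cohort_spec(seed = 42))
#' dplyr::count(tab, group, timepoint)
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  p_age <- pmin(pmax(round(stats::rnorm(spec$n_patients, spec$age_mean, spec$age_sd)),
                     spec$age_range[1]), spec$age_range[2])
  p_sex <- ifelse(seq_len(spec$n_patients) <= round(spec$sex_ratio * spec$n_patients),
                  "M", "F")
  pair_idx <- rep_len(seq_len(spec$n_patients), spec$n_controls)
  c_age <- pmin(pmax(round(p_age[pair_idx] + stats::runif(spec$n_controls, -2, 2)),
                     spec$age_range[1] - 2L), spec$age_range[2] + 2L)
  c_sex <- p_sex[pair_idx]

  demo <- tibble::tibble(
    subject_id = c(sprintf("P%02d", seq_len(spec$n_patients)),
                   sprintf("C%02d", seq_len(spec$n_controls))),
    group = rep(c("patient", "control"), c(spec$n_patients, spec$n_controls)),
    age = c(p_age, c_age),
    sex = c(p_sex, c_sex)
  )

  timepoints <- unique(spec$measures$timepoint)
  grid <- tidyr::expand_grid(demo, timepoint = timepoints)

  wide <- tidyr::pivot_longer(
    spec$measures,
    cols = c("patient_mean", "patient_sd", "control_mean", "control_sd"),
    names_to = c("group", ".value"), names_sep = "_"
  )
  out <- dplyr::left_join(grid, wide, by = c("group", "timepoint"),
                          relationship = "many-to-many")
  out <- dplyr::mutate(out, value = stats::rnorm(dplyr::n(), .data$mean, .data$sd))
  out <- tidyr::pivot_wider(
    dplyr::select(out, -"mean", -"sd"),
    names_from = "measure", values_from = "value"
  )
  dplyr::arrange(out, .data$group == "control", .data$subject_id, .data$timepoint)
}

#' Specification of a phantom image cohort
#'
#' Describes a pair of image groups on a common grid: group A images are
#' uniform background plus Gaussian noise; group B images additionally carry
#' a spherical "lesion" of the given amplitude, standing in for a localized
#' group difference (such as the posterior-cerebellar abnormality the real
#' analysis detects). Voxel values are clipped at zero so maps remain valid
#' nonnegative GM-volume maps.
#'
#' @param shape Grid shape, default `c(32, 32, 32)`.
#' @param voxel_size Voxel edge lengths in mm, default 2 mm isotropic.
#' @param background Background intensity (default 0.5, a typical modulated
#'   GM-fraction level).
#' @param blob_centre Sphere centre in voxel coordinates.
#' @param blob_radius Sphere radius in voxels; must fit inside the grid.
#' @param amplitude Intensity added inside the sphere for group B (any sign).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), voxel_size = c(2, 2, 2),
                         background = 0.5,
                         blob_centre = (shape + 1) / 2, blob_radius = 5,
                         amplitude = 0.1, noise_sd = 0.05, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (blob_radius < 0) stop("blob radius must be >= 0", call. = FALSE)
  if (any(blob_centre - blob_radius < 1) || any(blob_centre + blob_radius > shape)) {
    stop("blob must lie fully inside the grid", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size = as.numeric(voxel_size),
         background = background, blob_centre = blob_centre,
         blob_radius = blob_radius, amplitude = amplitude,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a two-group phantom image cohort
#'
#' @param spec A [phantom_spec()].
#' @param n_a,n_b Number of images in group A (background only) and group B
#'   (background + blob).
#' @return An [image_stack] of `n_a + n_b` images with group labels
#'   `"A"`/`"B"` and subject ids `A01..`, `B01..`.
#' @examples
#' st <- generate_phantom_cohort(phantom_spec(noise_sd = 0, seed = 1), 3, 3)
#' @export
generate_phantom_cohort <- function(spec, n_a, n_b) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  stopifnot(n_a >= 1, n_b >= 1)
  set.seed(spec$seed)
  nvox <- prod(spec$shape)
  blob <- as.vector(sphere_mask(spec$shape, spec$blob_centre, spec$blob_radius))

  one_image <- function(with_blob) {
    v <- spec$background + stats::rnorm(nvox, 0, spec$noise_sd)
    if (with_blob) v <- v + spec$amplitude * blob
    pmax(v, 0)
  }
  mat <- vapply(c(rep(FALSE, n_a), rep(TRUE, n_b)), one_image, numeric(nvox))
  image_stack(
    data = mat, shape = spec$shape, voxel_size = spec$voxel_size,
    subject_id = c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b))),
    group = rep(c("A", "B"), c(n_a, n_b))
  )
}

#' Specification of synthetic cognitive-domain scores
#'
#' @param n_subjects Number of subjects.
#' @param n_domains Number of cognitive domains (default 5).
#' @param norm_mean,norm_sd Normative mean and sd per domain; scalars are
#'   recycled across domains. Defaults 100 and 15 (Wechsler-style scaling).
#' @param effect Standardised downward shift (in normative sds) applied to
#'   the affected domains of designated impaired subjects. Default 2.5 sd,
#'   which puts affected domains well past the 5th-percentile deficit cut.
#' @param n_affected Number of domains shifted for impaired subjects
#'   (default 2, the minimum that triggers the impairment rule).
#' @param seed Integer seed.
#' @return An object of class `cognitive_spec`.
#' @export
cognitive_spec <- function(n_subjects = 25, n_domains = 5,
                           norm_mean = 100, norm_sd = 15,
                           effect = 2.5, n_affected = 2, seed = 1L) {
  n_subjects <- as.integer(n_subjects); n_domains <- as.integer(n_domains)
  if (n_domains < 1) stop("need at least one domain", call. = FALSE)
  norm_mean <- rep_len(norm_mean, n_domains)
  norm_sd <- rep_len(norm_sd, n_domains)
  if (any(norm_sd <= 0)) stop("normative sds must be > 0", call. = FALSE)
  if (n_affected > n_domains) stop("n_affected cannot exceed n_domains", call. = FALSE)
  structure(
    list(n_subjects = n_subjects, n_domains = n_domains,
         norm_mean = norm_mean, norm_sd = norm_sd,
         effect = effect, n_affected = as.integer(n_affected),
         seed = as.integer(seed)),
    class = "cognitive_spec"
  )
}

#' Generate synthetic per-domain cognitive scores
#'
#' Non-impaired subjects score at the normative distribution in every
#' domain; subjects listed in `impaired_ids` have their first `n_affected`
#' domains shifted downward by `effect` normative sds.
#'
#' @param spec A [cognitive_spec()].
#' @param impaired_ids Character vector of subject ids (subset of the
#'   generated `S01..` ids) to receive the impairment shift. May be empty.
#' @return A tibble in long format: `subject_id`, `domain` (`D1..`), `score`.
#' @export
generate_cognitive_scores <- function(spec, impaired_ids = character()) {
  stopifnot(inherits(spec, "cognitive_spec"))
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  impaired_ids <- as.character(impaired_ids)
  if (!all(impaired_ids %in% ids)) {
    stop("unknown subject id in `impaired_ids`", call. = FALSE)
  }
  set.seed(spec$seed)
  domains <- sprintf("D%d", seq_len(spec$n_domains))
  out <- tidyr::expand_grid(subject_id = ids, domain = domains)
  dom_i <- match(out$domain, domains)
  shift <- ifelse(out$subject_id %in% impaired_ids & dom_i <= spec$n_affected,
                  spec$effect * spec$norm_sd[dom_i], 0)
  out$score <- stats::rnorm(nrow(out), spec$norm_mean[dom_i], spec$norm_sd[dom_i]) - shift
  out
}
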