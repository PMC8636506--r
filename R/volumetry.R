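#' SIENAX-style global tissue volumes from segmented fraction maps
#'
#' Integrates grey-matter, white-matter and ventricular-CSF partial-volume
#' fraction maps into normalised global volumes: each tissue volume is the
#' sum of its fraction map times the voxel volume times the skull-derived
#' normalisation scaling factor. Total brain volume is GM + WM; ventricular
#' CSF is reported separately.
#'
#' @param gm,wm,csf [volume_image] fraction maps with values in \[0, 1\],
#'   sharing one grid.
#' @param scaling Dimensionless normalisation scaling factor (> 0); the
#'   skull-based estimation of this factor is preprocessing and is taken as
#'   input.
#' @param unit Output unit divisor: volumes are reported as
#'   (sum x voxel mm^3 x scaling) / `unit`. The default `1` reports mm^3;
#'   use `1000` for mL.
#' @return A one-row tibble: `total_brain_volume`, `gm_volume`, `wm_volume`,
#'   `csf_volume`, `scaling`.
#' @examples
#' half <- volume_image(array(0.5, c(10, 10, 10)), voxel_size = c(1, 1, 1))
#' zero <- volume_image(array(0, c(10, 10, 10)), voxel_size = c(1, 1, 1))
#' compute_global_volumes(half, zero, zero, scaling = 1.2)
#' @export
compute_global_volumes <- function(gm, wm, csf, scaling = 1, unit = 1) {
  for (m in list(gm, wm, csf)) {
    stopifnot(is_volume_image(m))
    rng <- range(m$data)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("fraction maps must have values in [0, 1]", call. = FALSE)
    }
  }
  check_same_grid(gm, wm, "tissue maps")
  check_same_grid(gm, csf, "tissue maps")
  if (!is.numeric(scaling) || scaling <= 0) stop("scaling must be > 0", call. = FALSE)

  vv <- voxel_volume(gm)
  vol <- function(m) sum(m$data) * vv * scaling / unit
  g <- vol(gm); w <- vol(wm); v <- vol(csf)
  tibble::tibble(
    total_brain_volume = g + w,
    gm_volume = g,
    wm_volume = w,
    csf_volume = v,
    scaling = scaling
  )
}

#' Welch's unequal-variance t test from summary statistics
#'
#' Two-sided Welch test computed from group means, standard deviations and
#' sizes (Satterthwaite degrees of freedom). Used to reproduce group
#' comparisons reported only as mean +/- sd per group.
#'
#' @param mean_a,sd_a,n_a First group summary (n >= 2, sd > 0).
#' @param mean_b,sd_b,n_b Second group summary.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' welch_from_summary(45, 20, 27, 37, 8, 27)  # p ~ 0.06
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd_a <= 0 || sd_b <= 0) stop("sds must be > 0", call. = FALSE)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  statistic <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(statistic), df)
  tibble::tibble(statistic = statistic, df = df, p_value = p)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank tie handling. The U
#' statistic counts pairs where a first-sample value exceeds a
#' second-sample value, with half-credit for ties. The two-sided p-value is
#' computed by full enumeration of label assignments when the combined
#' sample size is at most `exact_limit`, and by the tie-corrected normal
#' approximation (no continuity correction) otherwise.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_limit Combined-size cutoff for exact enumeration
#'   (default 12).
#' @return A one-row tibble: `u`, `p_value`, `method`.
#' @examples
#' mann_whitney_test(c(1, 2), c(3, 4))  # U = 0, exact p = 2/6
#' @export
mann_whitney_test <- function(a, b, exact_limit = 12) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  u_of <- function(idx_a) {
    r <- rank(pooled)  # midranks
    sum(r[idx_a]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))

  if (n <= exact_limit) {
    # enumerate all C(n, na) assignments of the pooled values to group a
    r <- rank(pooled)
    cmb <- utils::combn(n, na)
    us <- colSums(matrix(r[cmb], nrow = na)) - na * (na + 1) / 2
    # two-sided: as-or-more extreme distance from the null mean U
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  tibble::tibble(u = u_obs, p_value = p, method = method)
}

#' Group comparison summaries for cohort measures
#'
#' Reproduces a per-assessment group-comparison table: for each requested
#' measure and timepoint, per-group mean, sd and n plus the two-sided
#' Welch-from-summary p-value. The choice of an unpaired Welch test is an
#' approximation documented in the methods vignette (the pairing keys of
#' the matched design are not part of the summary data).
#'
#' @param data Cohort tibble as produced by [generate_cohort_table()]:
#'   columns `group`, `timepoint`, plus one numeric column per measure.
#' @param measures Character vector of measure column names (default: all
#'   numeric columns except `age`).
#' @param groups Length-2 character vector naming the comparison groups
#'   (first minus second); default `c("patient", "control")`.
#' @return A tibble with one row per timepoint x measure:
#'   group means/sds/ns, `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(data, measures = NULL,
                           groups = c("patient", "control")) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("group", "timepoint") %in% names(data)))
  if (is.null(measures)) {
    num <- vapply(data, is.numeric, logical(1))
    measures <- setdiff(names(data)[num], c("age"))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(data, "group", "timepoint", dplyr::all_of(measures)),
    cols = dplyr::all_of(measures), names_to = "measure", values_to = "value"
  )
  long <- dplyr::filter(long, .data$group %in% groups, !is.na(.data$value))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$timepoint, .data$measure),
    mean_a = mean(.data$value[.data$group == groups[1]]),
    sd_a = stats::sd(.data$value[.data$group == groups[1]]),
    n_a = sum(.data$group == groups[1]),
    mean_b = mean(.data$value[.data$group == groups[2]]),
    sd_b = stats::sd(.data$value[.data$group == groups[2]]),
    n_b = sum(.data$group == groups[2]),
    .groups = "drop"
  )
  tests <- purrr::pmap_dfr(
    dplyr::select(out, "mean_a", "sd_a", "n_a", "mean_b", "sd_b", "n_b"),
    welch_from_summary
  )
  dplyr::bind_cols(out, tests)
}
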