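#' Normative table for cognitive domains
#'
#' One row per domain with the normative mean and sd used for z-scoring,
#' and the score orientation (`higher_better = TRUE` when a larger raw
#' score means better performance). Which tests feed which domain is user
#' configuration, not code; scores entering here are already aggregated to
#' one value per domain.
#'
#' @param domain Character vector of domain names (unique).
#' @param mean,sd Normative mean and sd per domain (sd > 0).
#' @param higher_better Logical per domain; default `TRUE`.
#' @return A tibble of class usable by [domain_z_scores()].
#' @export
normative_table <- function(domain, mean, sd, higher_better = TRUE) {
  if (anyDuplicated(domain)) stop("duplicate domain in norms", call. = FALSE)
  if (any(sd <= 0)) stop("normative sds must be > 0", call. = FALSE)
  tibble::tibble(
    domain = as.character(domain),
    mean = as.numeric(mean),
    sd = as.numeric(sd),
    higher_better = rep_len(as.logical(higher_better), length(domain))
  )
}

#' Convert raw domain scores to signed z-scores
#'
#' z = (raw - normative mean) / normative sd, sign-flipped for
#' lower-is-better domains so that more negative always means worse.
#' Missing raw scores leave the domain unavailable (z = NA) rather than
#' failing; unavailable domains are excluded from the deficit count by
#' [classify_impairment()].
#'
#' @param scores Long tibble with columns `subject_id`, `domain`, `score`.
#' @param norms A [normative_table()] covering every domain in `scores`.
#' @param z_cut Deficit threshold on z (default -1.65, the 5th percentile).
#' @return The input tibble with an added `z` column and a `deficit` flag
#'   (z <= -1.65, the 5th-percentile criterion).
#' @examples
#' norms <- normative_table("D1", 100, 15)
#' domain_z_scores(
#'   tibble::tibble(subject_id = "S1", domain = "D1", score = 100 - 1.65 * 15),
#'   norms
#' )
#' @export
domain_z_scores <- function(scores, norms, z_cut = -1.65) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("subject_id", "domain", "score") %in% names(scores)))
  missing_domains <- setdiff(unique(scores$domain), norms$domain)
  if (length(missing_domains) > 0) {
    stop("domains missing from norms: ", paste(missing_domains, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(scores, norms, by = "domain")
  out <- dplyr::mutate(
    out,
    z = (.data$score - .data$mean) / .data$sd,
    z = ifelse(.data$higher_better, .data$z, -.data$z),
    deficit = !is.na(.data$z) & .data$z <= z_cut
  )
  dplyr::select(out, -"mean", -"sd", -"higher_better")
}

#' Classify neurocognitive impairment from domain z-scores
#'
#' A domain is a deficit when its z-score falls at or below `z_cut`
#' (default -1.65, the standard-normal 5th percentile; the boundary is
#' inclusive). A subject is impaired when at least `min_deficits` domains
#' (default 2) are deficits. Deficits are counted over available
#' (non-missing) domains; subjects with fewer than two available domains
#' are unclassifiable and get `impaired = NA`.
#'
#' @param z_scores Long tibble with columns `subject_id`, `domain`, `z`
#'   (as produced by [domain_z_scores()]).
#' @param z_cut Deficit threshold on z (default -1.65).
#' @param min_deficits Minimum deficit count for impairment (default 2).
#' @return A tibble with one row per subject: `subject_id`, `n_available`,
#'   `n_deficits`, `impaired` (logical, `NA` when unclassifiable).
#' @examples
#' z <- tibble::tibble(
#'   subject_id = "S1", domain = paste0("D", 1:5),
#'   z = c(-2.0, -1.7, 0, 0, 0)
#' )
#' classify_impairment(z)  # impaired, 2 deficits
#' @export
classify_impairment <- function(z_scores, z_cut = -1.65, min_deficits = 2) {
  z_scores <- tibble::as_tibble(z_scores)
  stopifnot(all(c("subject_id", "z") %in% names(z_scores)))
  out <- dplyr::summarise(
    dplyr::group_by(z_scores, .data$subject_id),
    n_available = sum(!is.na(.data$z)),
    n_deficits = sum(.data$z <= z_cut, na.rm = TRUE),
    .groups = "drop"
  )
  dplyr::mutate(
    out,
    impaired = dplyr::if_else(.data$n_available >= 2,
                              .data$n_deficits >= min_deficits,
                              NA)
  )
}

#' Full scoring pipeline: raw domain scores to impairment labels
#'
#' Convenience wrapper chaining [domain_z_scores()] and
#' [classify_impairment()].
#'
#' @inheritParams domain_z_scores
#' @inheritParams classify_impairment
#' @return The per-subject classification tibble of
#'   [classify_impairment()].
#' @export
score_cognition <- function(scores, norms, z_cut = -1.65, min_deficits = 2) {
  z <- domain_z_scores(scores, norms, z_cut = z_cut)
  classify_impairment(z, z_cut = z_cut, min_deficits = min_deficits)
}
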