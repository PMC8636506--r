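#' TFCE parameters
#'
#' Parameters of threshold-free cluster enhancement. Defaults are the
#' standard published ones: height exponent H = 2, extent exponent E = 0.5,
#' 6-connectivity, and an integration step of 1/100 of the maximum
#' statistic (set `dh = NULL` to keep that adaptive choice).
#'
#' @param H Height exponent (>= 0).
#' @param E Extent exponent (>= 0).
#' @param dh Integration step; `NULL` means max(statistic)/100, chosen per
#'   map.
#' @param connectivity Voxel neighbourhood: 6, 18 or 26.
#' @param extent_scale Multiplier applied to the voxel-count extent before
#'   exponentiation (set to the voxel volume for mm^3 extents). Default 1
#'   (extents in voxels).
#' @return An object of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 6,
                        extent_scale = 1) {
  if (H < 0 || E < 0) stop("H and E must be >= 0", call. = FALSE)
  if (!is.null(dh) && dh <= 0) stop("dh must be > 0", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  if (extent_scale <= 0) stop("extent_scale must be > 0", call. = FALSE)
  structure(list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity),
                 extent_scale = extent_scale),
            class = "tfce_params")
}

# ---- voxelwise GLM -------------------------------------------------------

# residualise the rows of a voxels-by-subjects matrix against covariates
# (with intercept), returning the residual matrix
residualise_rows <- function(X, covariates) {
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  Q <- qr.Q(qr(mm))
  X - (X %*% Q) %*% t(Q)
}

# pooled-variance two-sample t per row of X; zero-variance rows -> 0
row_pooled_t <- function(X, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  Xa <- X[, idx_a, drop = FALSE]; Xb <- X[, idx_b, drop = FALSE]
  ma <- rowMeans(Xa); mb <- rowMeans(Xb)
  ssa <- rowSums((Xa - ma)^2); ssb <- rowSums((Xb - mb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0] <- 0
  t
}

# one-sample t per row; zero-variance rows -> 0
row_onesample_t <- function(D) {
  k <- ncol(D)
  m <- rowMeans(D)
  s <- sqrt(rowSums((D - m)^2) / (k - 1))
  t <- m / (s / sqrt(k))
  t[s == 0] <- 0
  t
}

#' Voxelwise group GLM on an image stack
#'
#' Computes the per-voxel two-sample t statistic (pooled variance) between
#' the stack's two groups, after residualising out any covariates. The sign
#' convention is positive = first group higher. A paired design takes
#' within-pair differences (first group minus second, by `pair_id`) and
#' returns the one-sample t on those differences.
#'
#' Voxels with zero residual variance (e.g. noiseless phantoms) are
#' degenerate for a t statistic; they are set to 0 and counted in
#' `n_degenerate`, with a warning.
#'
#' @param stack An [image_stack()] with exactly two groups, each of size
#'   >= 2.
#' @param design `"two_sample"` (default) or `"paired"`.
#' @param pair_id Pair identifiers (length = number of images), required for
#'   the paired design: each pair must contain one image of each group.
#' @return A `stat_map`: a [volume_image] carrying the t statistic plus
#'   design metadata (`design`, `groups`, `df`, `n_degenerate`).
#' @export
fit_voxelwise_glm <- function(stack, design = c("two_sample", "paired"),
                              pair_id = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  design <- match.arg(design)
  if (is.null(stack$group)) stop("stack needs group labels", call. = FALSE)
  groups <- unique(stack$group)
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  idx_a <- which(stack$group == groups[1])
  idx_b <- which(stack$group == groups[2])
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    stop("each group needs at least 2 images", call. = FALSE)
  }

  X <- stack$data
  if (!is.null(stack$covariates)) X <- residualise_rows(X, stack$covariates)

  if (design == "two_sample") {
    t <- row_pooled_t(X, idx_a, idx_b)
    df <- length(idx_a) + length(idx_b) - 2
  } else {
    D <- paired_differences(X, stack$group, groups, pair_id)
    t <- row_onesample_t(D)
    df <- ncol(D) - 1
  }
  n_degen <- sum(t == 0 & apply_zero_variance_flag(X, idx_a, idx_b, design, pair_id, stack$group, groups))
  if (n_degen > 0) {
    warning(sprintf("%d voxel(s) with zero residual variance set to t = 0", n_degen))
  }
  structure(
    list(data = array(t, dim = stack$shape), voxel_size = stack$voxel_size,
         design = design, groups = groups, df = df, n_degenerate = n_degen),
    class = c("stat_map", "volume_image")
  )
}

# matrix of within-pair differences (group a minus group b)
paired_differences <- function(X, group, groups, pair_id) {
  if (is.null(pair_id)) stop("paired design requires `pair_id`", call. = FALSE)
  if (length(pair_id) != ncol(X)) stop("one pair_id per image", call. = FALSE)
  pid <- as.character(pair_id)
  pairs <- unique(pid)
  D <- vapply(pairs, function(p) {
    ia <- which(pid == p & group == groups[1])
    ib <- which(pid == p & group == groups[2])
    if (length(ia) != 1L || length(ib) != 1L) {
      stop("each pair must contain exactly one image of each group", call. = FALSE)
    }
    X[, ia] - X[, ib]
  }, numeric(nrow(X)))
  D
}

# identify voxels whose residual variance is exactly zero (degenerate)
apply_zero_variance_flag <- function(X, idx_a, idx_b, design, pair_id, group, groups) {
  if (design == "two_sample") {
    va <- rowSums((X[, idx_a, drop = FALSE] - rowMeans(X[, idx_a, drop = FALSE]))^2)
    vb <- rowSums((X[, idx_b, drop = FALSE] - rowMeans(X[, idx_b, drop = FALSE]))^2)
    (va + vb) == 0
  } else {
    D <- paired_differences(X, group, groups, pair_id)
    rowSums((D - rowMeans(D))^2) == 0
  }
}

# ---- TFCE ----------------------------------------------------------------

# enhancement of a plain numeric vector/array; returns vector
tfce_vector <- function(v, shape, params) {
  dh <- params$dh
  amax <- max(abs(v))
  if (amax == 0) return(numeric(length(v)))
  if (is.null(dh)) dh <- amax / 100
  scale_pow <- params$extent_scale^params$E
  pos <- .tfce_pos(pmax(v, 0), as.integer(shape), params$E, params$H, dh,
                   params$connectivity)
  neg <- .tfce_pos(pmax(-v, 0), as.integer(shape), params$E, params$H, dh,
                   params$connectivity)
  scale_pow * (pos - neg)
}

#' Threshold-free cluster enhancement
#'
#' Enhances a voxelwise statistic map: each voxel's value becomes the
#' integral, over all thresholds h below its statistic, of
#' `extent(h)^E * h^H dh`, where `extent(h)` is the size of the connected
#' supra-threshold component containing the voxel at height h. Spatially
#' extended signal is boosted without committing to a single
#' cluster-forming threshold. Negative statistics are enhanced separately
#' on the negated map and returned with negative sign.
#'
#' The integral is evaluated by the midpoint rule with step `dh` (default:
#' max |statistic| / 100).
#'
#' @param map A `stat_map` or [volume_image] (or bare 3D array).
#' @param params A [tfce_params()].
#' @return A `tfce_map`: a [volume_image] of signed enhanced values with the
#'   parameters attached.
#' @examples
#' a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
#' tfce_enhance(volume_image(a), tfce_params(dh = 0.01))
#' @export
tfce_enhance <- function(map, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  if (is.array(map)) map <- volume_image(map)
  stopifnot(is_volume_image(map))
  enh <- tfce_vector(as.vector(map$data), dim(map$data), params)
  structure(
    list(data = array(enh, dim = dim(map$data)), voxel_size = map$voxel_size,
         params = params),
    class = c("tfce_map", "volume_image")
  )
}

# ---- permutation engine --------------------------------------------------

# all choose(n, k) index sets of size k from 1..n, as a list (first = 1..k)
all_group_assignments <- function(n, k) {
  cmb <- utils::combn(n, k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Permutation max-statistic test with TFCE correction
#'
#' The voxelwise inference engine: computes the observed TFCE-enhanced
#' statistic map, rebuilds it under permuted group labels (two-sample) or
#' flipped difference signs (paired), and corrects each voxel's p-value
#' against the permutation distribution of the image-wide maximum enhanced
#' statistic. This controls the family-wise error rate exactly under
#' exchangeability.
#'
#' When the number of distinct relabelings (`choose(n, n_a)` or `2^pairs`)
#' is at most `n_perm`, the full enumeration is used and p-values are exact
#' permutation fractions (the identity relabeling included). Otherwise
#' `n_perm` random relabelings are drawn — without replacement from the
#' distinct relabelings whenever their number is small enough to enumerate —
#' and the add-one estimator `p = (1 + #{null max >= observed}) / (1 +
#' n_perm)` is used, so p-values are never zero.
#'
#' @inheritParams fit_voxelwise_glm
#' @param params A [tfce_params()].
#' @param n_perm Number of permutations (>= 1).
#' @param alternative `"two.sided"` (default; the null maximum is taken over
#'   the absolute enhanced map), `"greater"` (first group higher) or
#'   `"less"`.
#' @param seed Integer seed, recorded in the result.
#' @return An object of class `perm_result` with elements `statistic`
#'   (observed t `stat_map`), `enhanced` (`tfce_map`), `p` ([volume_image]
#'   of corrected p-values), `null_max` (numeric vector), `n_perm`,
#'   `exhaustive`, `alternative`, `seed`.
#' @export
permutation_maxstat_test <- function(stack, params = tfce_params(),
                                     n_perm = 999,
                                     design = c("two_sample", "paired"),
                                     pair_id = NULL,
                                     alternative = c("two.sided", "greater", "less"),
                                     seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  design <- match.arg(design)
  alternative <- match.arg(alternative)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  groups <- unique(stack$group)
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  X <- stack$data
  if (!is.null(stack$covariates)) X <- residualise_rows(X, stack$covariates)
  shape <- stack$shape

  score <- switch(alternative,
                  two.sided = abs,
                  greater = identity,
                  less = function(x) -x)

  if (design == "two_sample") {
    idx_a <- which(stack$group == groups[1])
    n <- ncol(X); na <- length(idx_a)
    stat_fun <- function(ia) row_pooled_t(X, ia, setdiff(seq_len(n), ia))
    n_distinct <- choose(n, na)
    exhaustive <- n_distinct <= n_perm
    if (exhaustive) {
      assigns <- all_group_assignments(n, na)
      # put the observed assignment first
      obs_key <- paste(sort(idx_a), collapse = ",")
      keys <- vapply(assigns, function(a) paste(a, collapse = ","), character(1))
      assigns <- c(assigns[keys == obs_key], assigns[keys != obs_key])
    } else if (n_distinct <= 5e4) {
      assigns <- all_group_assignments(n, na)
      keys <- vapply(assigns, function(a) paste(a, collapse = ","), character(1))
      obs_key <- paste(sort(idx_a), collapse = ",")
      pool <- assigns[keys != obs_key]
      assigns <- c(list(sort(idx_a)), sample(pool, n_perm))
    } else {
      assigns <- c(list(sort(idx_a)),
                   replicate(n_perm, sort(sample.int(n, na)), simplify = FALSE))
    }
    stats_list <- lapply(assigns, stat_fun)
  } else {
    D <- paired_differences(X, stack$group, groups, pair_id)
    k <- ncol(D)
    stat_fun <- function(signs) row_onesample_t(D * rep(signs, each = nrow(D)))
    n_distinct <- 2^k
    exhaustive <- n_distinct <= n_perm
    if (exhaustive) {
      signs_list <- lapply(0:(n_distinct - 1), function(m) {
        1 - 2 * as.integer(intToBits(m)[seq_len(k)])
      })
      # identity (all +1) is m = 0, already first
    } else {
      signs_list <- c(list(rep(1, k)),
                      replicate(n_perm, sample(c(-1, 1), k, replace = TRUE),
                                simplify = FALSE))
    }
    stats_list <- lapply(signs_list, stat_fun)
  }

  # adaptive dh must be common across permutations for a comparable null
  params_run <- params
  if (is.null(params_run$dh)) {
    params_run$dh <- max(abs(stats_list[[1]])) / 100
    if (params_run$dh == 0) params_run$dh <- 1  # flat observed map
  }

  enh_list <- lapply(stats_list, function(s) score(tfce_vector(s, shape, params_run)))
  obs_enh_signed <- tfce_vector(stats_list[[1]], shape, params_run)
  obs_score <- enh_list[[1]]
  null_max <- vapply(enh_list, max, numeric(1))

  if (exhaustive) {
    p <- vapply(obs_score, function(o) mean(null_max >= o), numeric(1))
    n_used <- length(null_max)
  } else {
    nm <- null_max[-1]
    p <- vapply(obs_score, function(o) (1 + sum(nm >= o)) / (1 + n_perm), numeric(1))
    n_used <- n_perm
  }

  structure(
    list(
      statistic = structure(
        list(data = array(stats_list[[1]], dim = shape),
             voxel_size = stack$voxel_size, design = design, groups = groups,
             df = NA_integer_, n_degenerate = NA_integer_),
        class = c("stat_map", "volume_image")),
      enhanced = structure(
        list(data = array(obs_enh_signed, dim = shape),
             voxel_size = stack$voxel_size, params = params_run),
        class = c("tfce_map", "volume_image")),
      p = volume_image(array(p, dim = shape), stack$voxel_size),
      null_max = null_max,
      n_perm = n_used,
      exhaustive = exhaustive,
      alternative = alternative,
      design = design,
      params = params_run,
      seed = seed
    ),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "<perm_result> %s %s design, %d %s permutations\n",
    x$alternative, x$design, x$n_perm,
    if (x$exhaustive) "exhaustive" else "random"))
  cat(sprintf("  min corrected p: %.4g\n", min(x$p$data)))
  invisible(x)
}

#' One-row summary of a permutation test
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return A tibble with the permutation count, mode, minimum corrected p,
#'   number of significant voxels at 0.05, and seed.
#' @method glance perm_result
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    exhaustive = x$exhaustive,
    alternative = x$alternative,
    min_p = min(x$p$data),
    n_sig_05 = sum(x$p$data < 0.05),
    max_enhanced = max(abs(x$enhanced$data)),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Per-voxel table of a permutation test
#'
#' @param x A `perm_result`.
#' @param p_max Keep voxels with corrected p <= `p_max` (default 1, all).
#' @param ... Unused.
#' @return A tibble with voxel coordinates, the raw statistic, the signed
#'   enhanced statistic and the corrected p-value.
#' @method tidy perm_result
#' @export
tidy.perm_result <- function(x, p_max = 1, ...) {
  shape <- dim(x$p$data)
  keep <- which(x$p$data <= p_max)
  idx <- arrayInd(keep, shape)
  stat <- x$statistic$data[keep]
  enh <- x$enhanced$data[keep]
  pc <- x$p$data[keep]
  tibble::tibble(
    x = idx[, 1], y = idx[, 2], z = idx[, 3],
    statistic = stat, enhanced = enh, p_corrected = pc
  )
}

# ---- supra-threshold ROI -------------------------------------------------

#' Extract the supra-threshold cluster ROI from a permutation result
#'
#' Builds the region of interest used for downstream ROI summarisation: all
#' voxels with corrected p below `alpha`, with per-voxel weights summing to
#' one. An empty result is a valid outcome (`roi$empty` is `TRUE`), not an
#' error.
#'
#' @param result A `perm_result`.
#' @param alpha Corrected-p threshold in (0, 1); default 0.05.
#' @param weighting `"uniform"` (each surviving voxel weighted 1/k, default)
#'   or `"statistic"` (weights proportional to the absolute enhanced
#'   statistic).
#' @return An object of class `cluster_roi`: logical `mask` array, numeric
#'   `weights` array summing to 1 over the mask (all zero when empty),
#'   `size` (voxel count), `empty` flag, plus provenance (`alpha`,
#'   `weighting`).
#' @export
threshold_and_extract_roi <- function(result, alpha = 0.05,
                                      weighting = c("uniform", "statistic")) {
  stopifnot(inherits(result, "perm_result"))
  weighting <- match.arg(weighting)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  mask <- result$p$data < alpha
  size <- sum(mask)
  weights <- array(0, dim = dim(mask))
  if (size > 0) {
    if (weighting == "uniform") {
      weights[mask] <- 1 / size
    } else {
      w <- abs(result$enhanced$data[mask])
      if (sum(w) == 0) w <- rep(1, size)
      weights[mask] <- w / sum(w)
    }
  }
  structure(
    list(mask = mask, weights = weights, size = size, empty = size == 0,
         alpha = alpha, weighting = weighting,
         voxel_size = result$p$voxel_size),
    class = "cluster_roi"
  )
}

#' @export
print.cluster_roi <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<cluster_roi> empty (no voxel with corrected p < %g)\n", x$alpha))
  } else {
    cat(sprintf("<cluster_roi> %d voxels at corrected p < %g, %s weights\n",
                x$size, x$alpha, x$weighting))
  }
  invisible(x)
}

#' Middle-slice heatmap of a statistic or p map
#'
#' @param object A `stat_map`, `tfce_map` or [volume_image].
#' @param z Slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot volume_image
#' @export
autoplot.volume_image <- function(object, z = NULL, ...) {
  d <- dim(object$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$data[, , z])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice z = %d", z), fill = "value") +
    ggplot2::theme_minimal()
}

#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, z = NULL, ...) {
  autoplot.volume_image(object, z = z, ...) + ggplot2::labs(fill = "t")
}

#' @method autoplot tfce_map
#' @export
autoplot.tfce_map <- function(object, z = NULL, ...) {
  autoplot.volume_image(object, z = z, ...) + ggplot2::labs(fill = "TFCE")
}
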