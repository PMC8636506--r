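single_voxel_stack <- function(values_a, values_b) {
  image_stack(
    data = matrix(c(values_a, values_b), nrow = 1),
    shape = c(1, 1, 1),
    group = rep(c("A", "B"), c(length(values_a), length(values_b)))
  )
}

test_that("voxelwise GLM equals the closed-form two-sample t", {
  st <- single_voxel_stack(c(1, 2, 3), c(4, 5, 6))
  sm <- fit_voxelwise_glm(st)
  expect_equal(sm$data[1, 1, 1], pooled_t_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(sm$data[1, 1, 1], -3.6742346, tolerance = 1e-6)

  # identical groups (same images duplicated) -> t = 0 everywhere
  set.seed(41)
  imgs <- matrix(rnorm(27 * 4), nrow = 27)
  dup <- image_stack(cbind(imgs, imgs), shape = c(3, 3, 3),
                     group = rep(c("A", "B"), each = 4))
  sm0 <- fit_voxelwise_glm(dup)
  expect_true(all(sm0$data == 0))

  # noiseless groups with a mean offset: zero residual variance is flagged
  # as degenerate (t set to 0), not reported as an infinite statistic
  flat <- image_stack(
    cbind(matrix(0.5, 27, 3), matrix(0.6, 27, 3)),
    shape = c(3, 3, 3), group = rep(c("A", "B"), each = 3)
  )
  expect_warning(smf <- fit_voxelwise_glm(flat), "zero residual variance")
  expect_true(all(smf$data == 0))
  expect_equal(smf$n_degenerate, 27)

  expect_error(fit_voxelwise_glm(single_voxel_stack(1, c(2, 3))), "at least 2")
})

test_that("covariate residualisation removes a linear confound", {
  set.seed(42)
  n <- 20
  grp <- rep(c("A", "B"), 10)
  # age is confounded with group and drives the signal entirely
  age <- rnorm(n, 55, 3) + 8 * (grp == "A")
  X <- matrix(rep(2 * age, each = 8), nrow = 8) + rnorm(8 * n, sd = 0.5)
  st_conf <- image_stack(X, shape = c(2, 2, 2), group = grp,
                         covariates = data.frame(age = age))
  st_raw <- image_stack(X, shape = c(2, 2, 2), group = grp)
  t_conf <- fit_voxelwise_glm(st_conf)$data
  t_raw <- fit_voxelwise_glm(st_raw)$data
  expect_lt(max(abs(t_conf)), max(abs(t_raw)))
  expect_lt(max(abs(t_conf)), 2)
})

test_that("paired GLM is the one-sample t on within-pair differences", {
  set.seed(43)
  k <- 6
  a <- matrix(rnorm(8 * k, mean = 0.3), nrow = 8)
  b <- matrix(rnorm(8 * k), nrow = 8)
  st <- image_stack(cbind(a, b), shape = c(2, 2, 2),
                    group = rep(c("A", "B"), each = k))
  sm <- fit_voxelwise_glm(st, design = "paired", pair_id = rep(seq_len(k), 2))
  d1 <- a[1, ] - b[1, ]
  expect_equal(sm$data[1, 1, 1], unname(stats::t.test(d1)$statistic),
               tolerance = 1e-10)
  expect_error(fit_voxelwise_glm(st, design = "paired"), "pair_id")
})

test_that("TFCE matches closed form and the naive per-height oracle", {
  # isolated voxel of height 1: integral of h^2 -> 1/3 (midpoint rule 0.333325)
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  e <- tfce_enhance(a, tfce_params(E = 0.5, H = 2, dh = 0.01))
  expect_equal(e$data[3, 3, 3], 0.333325, tolerance = 1e-9)
  expect_equal(e$data[3, 3, 3], 1 / 3, tolerance = 1e-4)
  expect_equal(sum(e$data != 0), 1)

  # random small maps, all connectivities, against the flood-fill oracle
  set.seed(44)
  for (conn in c(6, 18, 26)) {
    v <- array(round(runif(4 * 4 * 3), 2), dim = c(4, 4, 3))
    got <- tfce_enhance(v, tfce_params(E = 0.5, H = 2, dh = 0.05,
                                       connectivity = conn))
    ref <- naive_tfce(v, E = 0.5, H = 2, dh = 0.05, connectivity = conn)
    expect_equal(got$data, ref, tolerance = 1e-10)
  }

  # all-zero map stays zero; negative lobes enhanced on the negated map
  expect_true(all(tfce_enhance(array(0, c(3, 3, 3)))$data == 0))
  s <- array(0, c(7, 3, 3)); s[1:2, 1, 1] <- 2; s[6:7, 1, 1] <- -2
  es <- tfce_enhance(s, tfce_params(dh = 0.1))
  expect_equal(es$data[1, 1, 1], -es$data[6, 1, 1])
  expect_lt(es$data[6, 1, 1], 0)
})

test_that("TFCE is monotone and translation invariant", {
  set.seed(45)
  base <- array(runif(4 * 4 * 4, 0, 1), dim = c(4, 4, 4))
  p <- tfce_params(dh = 0.05)
  e0 <- tfce_enhance(base, p)$data
  for (i in 1:5) {
    bumped <- base
    j <- sample(length(base), 1)
    bumped[j] <- bumped[j] + runif(1, 0, 0.5)
    e1 <- tfce_enhance(bumped, p)$data
    expect_true(all(e1 >= e0 - 1e-12))
  }

  # two disjoint identical blobs enhance identically
  tw <- array(0, c(11, 5, 5))
  tw[2:3, 2:3, 2:3] <- 1
  tw[8:9, 2:3, 2:3] <- 1
  et <- tfce_enhance(tw, tfce_params(dh = 0.02))$data
  expect_equal(et[2:3, 2:3, 2:3], et[8:9, 2:3, 2:3])
})

test_that("exhaustive permutation p equals full enumeration on tiny designs", {
  set.seed(46)
  vals <- c(2.3, 1.1, 3.7, -0.4, 0.9)
  st <- single_voxel_stack(vals[1:3], vals[4:5])
  pr <- permutation_maxstat_test(st, n_perm = 100, seed = 1)
  expect_true(pr$exhaustive)
  expect_equal(pr$n_perm, 10)  # C(5,2) relabelings
  p <- pr$p$data[1, 1, 1]
  expect_equal(p * 10, round(p * 10))  # multiple of 1/10
  expect_equal(p, perm_p_oracle(vals, 3))

  # several random tiny designs, two-sided max-|t|
  for (i in 1:5) {
    n_a <- sample(3:5, 1); n_b <- sample(2:4, 1)
    vals <- round(rnorm(n_a + n_b), 3)
    st <- single_voxel_stack(vals[seq_len(n_a)], vals[-seq_len(n_a)])
    pr <- permutation_maxstat_test(st, n_perm = 500, seed = i)
    expect_true(pr$exhaustive)
    expect_equal(pr$p$data[1, 1, 1], perm_p_oracle(vals, n_a))
  }
})

test_that("sampled permutation p respects the add-one floor and approaches enumeration", {
  set.seed(47)
  vals <- c(10, 11, 12, 13, -10, -11, -12)  # strong separation
  st <- single_voxel_stack(vals[1:4], vals[5:7])
  # sampled mode: force by tiny n_perm
  pr <- permutation_maxstat_test(st, n_perm = 9, seed = 2)
  expect_false(pr$exhaustive)
  expect_gte(pr$p$data[1, 1, 1], 1 / 10)

  # with n_perm just below the full count, sampled p ~ exhaustive p
  full <- permutation_maxstat_test(st, n_perm = choose(7, 4), seed = 3)
  expect_true(full$exhaustive)
  near <- permutation_maxstat_test(st, n_perm = choose(7, 4) - 1, seed = 3)
  expect_lt(abs(near$p$data[1, 1, 1] - full$p$data[1, 1, 1]), 0.06)
})

test_that("paired permutation enumerates sign flips exhaustively", {
  set.seed(48)
  k <- 5
  a <- matrix(rnorm(4 * k, 1.5), nrow = 4)
  b <- matrix(rnorm(4 * k), nrow = 4)
  st <- image_stack(cbind(a, b), shape = c(2, 2, 1),
                    group = rep(c("A", "B"), each = k))
  pr <- permutation_maxstat_test(st, n_perm = 64, design = "paired",
                                 pair_id = rep(seq_len(k), 2), seed = 4)
  expect_true(pr$exhaustive)
  expect_equal(pr$n_perm, 2^k)
  expect_true(all(pr$p$data >= 1 / 2^k))

  # brute-force sign-flip oracle at one voxel
  d1 <- a[1, ] - b[1, ]
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  tmax <- apply(signs, 1, function(s) {
    ds <- d1 * s
    abs(mean(ds) / (sd(ds) / sqrt(k)))
  })
  # per-voxel p uses the map-wide max; check the p bound at voxel 1 holds
  obs_enh <- abs(pr$enhanced$data[1, 1, 1])
  expect_gte(pr$p$data[1, 1, 1], mean(tmax >= abs(stats::t.test(d1)$statistic) - 1e-12) / 2^k)
})

test_that("blob phantoms yield significant voxels inside the blob and ROI weights normalise", {
  spec <- phantom_spec(shape = c(12, 12, 12), blob_centre = c(6, 6, 6),
                       blob_radius = 3, amplitude = 0.15, noise_sd = 0.05,
                       seed = 7)
  st <- generate_phantom_cohort(spec, 6, 6)
  pr <- permutation_maxstat_test(st, n_perm = 199, seed = 8)
  roi <- threshold_and_extract_roi(pr, alpha = 0.05)
  expect_false(roi$empty)
  blob <- sphere_mask(c(12, 12, 12), c(6, 6, 6), 3) == 1
  # surviving voxels should be concentrated in the blob
  expect_gt(sum(roi$mask & blob) / roi$size, 0.8)
  expect_equal(sum(roi$weights), 1)
  expect_equal(unique(roi$weights[roi$mask]), 1 / roi$size)

  # statistic-proportional weighting also normalises
  roi_s <- threshold_and_extract_roi(pr, alpha = 0.05, weighting = "statistic")
  expect_equal(sum(roi_s$weights), 1)
  expect_true(all(roi_s$weights >= 0))

  # no survivor at an extreme alpha -> explicit empty ROI, not an error
  roi_e <- threshold_and_extract_roi(pr, alpha = 1 / (pr$n_perm + 2))
  expect_true(roi_e$empty)
  expect_equal(roi_e$size, 0)
  expect_error(threshold_and_extract_roi(pr, alpha = 0), "alpha")
})

test_that("tidy and glance summarise permutation results", {
  st <- single_voxel_stack(c(1, 2, 3), c(4, 5, 6))
  pr <- permutation_maxstat_test(st, n_perm = 20, seed = 9)
  g <- glance(pr)
  expect_equal(g$n_perm, choose(6, 3))
  td <- tidy(pr)
  expect_equal(nrow(td), 1)
  expect_named(td, c("x", "y", "z", "statistic", "enhanced", "p_corrected"))
})
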