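test_that("weighted ROI mean reduces to plain means and single voxels", {
  shape <- c(4, 4, 4)
  mask <- array(FALSE, shape); mask[1:2, 1, 1] <- TRUE
  roi_u <- structure(list(mask = mask,
                          weights = array(mask / sum(mask), shape),
                          size = 2L, empty = FALSE, alpha = 0.05,
                          weighting = "uniform", voxel_size = c(2, 2, 2)),
                     class = "cluster_roi")
  vals <- array(seq_len(prod(shape)), shape)
  img <- volume_image(vals)
  expect_equal(weighted_roi_mean(img, roi_u), mean(vals[mask]))

  w1 <- array(0, shape); w1[2, 1, 1] <- 1
  roi_1 <- structure(list(mask = w1 > 0, weights = w1, size = 1L, empty = FALSE,
                          alpha = 0.05, weighting = "uniform",
                          voxel_size = c(2, 2, 2)),
                     class = "cluster_roi")
  expect_equal(weighted_roi_mean(img, roi_1), vals[2, 1, 1])

  # constant map -> the constant, for any normalised weighting
  expect_equal(weighted_roi_mean(volume_image(array(7, shape)), roi_u), 7)

  roi_empty <- structure(list(mask = array(FALSE, shape),
                              weights = array(0, shape), size = 0L,
                              empty = TRUE, alpha = 0.05,
                              weighting = "uniform", voxel_size = c(2, 2, 2)),
                         class = "cluster_roi")
  expect_error(weighted_roi_mean(img, roi_empty), "empty")
})

test_that("full-sample threshold scan reproduces the frozen fixture oracle", {
  fx <- sah_roi_fixture()
  out <- full_sample_threshold(fx)
  expect_equal(out$threshold, fixture_expected$threshold)
  expect_equal(out$accuracy, fixture_expected$accuracy)

  # perfectly separated groups: 100% at the separating midpoint
  sep <- tibble::tibble(roi_value = c(1, 2, 3, 10, 11, 12),
                        impaired = rep(c(FALSE, TRUE), each = 3))
  out_sep <- full_sample_threshold(sep)
  expect_equal(out_sep$accuracy, 1)
  expect_equal(out_sep$threshold, 6.5)

  # all-identical values: accuracy = majority class fraction
  same <- tibble::tibble(roi_value = rep(1, 5),
                         impaired = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(full_sample_threshold(same)$accuracy, 3 / 5)

  expect_error(full_sample_threshold(
    tibble::tibble(roi_value = 1:3, impaired = rep(TRUE, 3))), "both")
})

test_that("threshold accuracy never falls below the majority-class rate", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    d <- tibble::tibble(roi_value = round(rnorm(n), 1),
                        impaired = sample(c(TRUE, FALSE), n, replace = TRUE))
    if (all(d$impaired) || !any(d$impaired)) next
    maj <- max(mean(d$impaired), 1 - mean(d$impaired))
    expect_gte(full_sample_threshold(d)$accuracy, maj - 1e-12)
  }
})

test_that("LOOCV on the fixture reproduces the frozen per-fold oracle", {
  fit <- loocv_classify(sah_roi_fixture())
  expect_equal(unname(fit$confusion),
               c(fixture_expected$tp, fixture_expected$fn,
                 fixture_expected$fp, fixture_expected$tn))
  expect_equal(fit$sensitivity, fixture_expected$sensitivity)
  expect_equal(fit$specificity, fixture_expected$specificity)
  expect_equal(fit$accuracy, 21 / 25)
  expect_equal(fit$threshold, fixture_expected$threshold)

  g <- glance(fit)
  expect_equal(g$tp, 9)
  td <- tidy(fit)
  expect_equal(nrow(td), 25)
  expect_false(any(td$excluded))
})

test_that("LOOCV metrics are invariant under common affine rescaling", {
  fx <- sah_roi_fixture()
  shifted <- dplyr::mutate(fx, roi_value = 3 * roi_value + 10)
  a <- glance(loocv_classify(fx))
  b <- glance(loocv_classify(shifted))
  expect_equal(a[c("tp", "fn", "fp", "tn", "sensitivity", "specificity",
                   "accuracy")],
               b[c("tp", "fn", "fp", "tn", "sensitivity", "specificity",
                   "accuracy")])
  expect_equal(b$threshold, 3 * a$threshold + 10)
})

test_that("LOOCV handles separation, label flips and null-label designs", {
  sep <- tibble::tibble(roi_value = c(1, 2, 3, 10, 11, 12),
                        impaired = rep(c(FALSE, TRUE), each = 3))
  fit <- loocv_classify(sep)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 1)

  # the maximal full-sample accuracy is invariant under mirroring the data
  # (negate values, flip labels); per-fold LOOCV thresholds need not be,
  # because the lowest-interval tie-break is direction-specific
  fx <- sah_roi_fixture()
  mirr <- dplyr::mutate(fx, roi_value = -roi_value, impaired = !impaired)
  expect_equal(full_sample_threshold(mirr)$accuracy,
               full_sample_threshold(fx)$accuracy)

  # exchangeable labels: held-out accuracy hovers near the majority rate
  set.seed(82)
  n <- 60
  null_d <- tibble::tibble(roi_value = rnorm(n),
                           impaired = rep(c(TRUE, FALSE), n / 2))
  accs <- replicate(10, {
    perm <- dplyr::mutate(null_d, impaired = sample(impaired))
    loocv_classify(perm)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("AUC equals the pair-count value on the fixture and edge cases", {
  fx <- sah_roi_fixture()
  roc <- roc_auc(fx)
  expect_equal(roc$auc, fixture_expected$auc)
  expect_equal(round(roc$auc, 3), 0.805)

  # all ties -> 0.5; perfect separation -> 1; flipped labels -> 1 - AUC
  same <- tibble::tibble(roi_value = rep(1, 6),
                         impaired = rep(c(TRUE, FALSE), 3))
  expect_equal(roc_auc(same)$auc, 0.5)
  sep <- tibble::tibble(roi_value = c(1, 2, 3, 10, 11, 12),
                        impaired = rep(c(FALSE, TRUE), each = 3))
  expect_equal(roc_auc(sep)$auc, 1)
  expect_equal(roc_auc(dplyr::mutate(fx, impaired = !impaired))$auc,
               1 - roc$auc)

  # invariance under strictly increasing transforms
  expect_equal(roc_auc(dplyr::mutate(fx, roi_value = exp(roi_value)))$auc,
               roc$auc)
})

test_that("AUC agrees with pROC and with the normalised Mann-Whitney U", {
  set.seed(83)
  for (i in 1:5) {
    pos <- rnorm(8, 1); neg <- rnorm(11)
    d <- tibble::tibble(roi_value = c(pos, neg),
                        impaired = rep(c(TRUE, FALSE), c(8, 11)))
    auc <- roc_auc(d)$auc
    # cross-module identity: AUC = U / (n1 n2) with U from the rank test
    u <- mann_whitney_test(pos, neg)$u
    expect_equal(auc, u / (8 * 11))
    # independent implementation
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = d$impaired, predictor = d$roi_value,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    expect_equal(auc, ref)
  }
})

test_that("bootstrap CI brackets the point AUC and is reproducible", {
  fx <- sah_roi_fixture()
  r1 <- roc_auc(fx, n_boot = 200, seed = 84)
  r2 <- roc_auc(fx, n_boot = 200, seed = 84)
  expect_equal(r1$ci, r2$ci)
  expect_lt(r1$ci[1], r1$auc)
  expect_gt(r1$ci[2], r1$auc)
})

test_that("Cohen's d matches hand values and recovers a planted effect", {
  d1 <- cohens_d(tibble::tibble(roi_value = c(1, 3, 0, 2),
                                impaired = c(TRUE, TRUE, FALSE, FALSE)),
                 roi_value, impaired)
  expect_equal(d1$d, 1 / sqrt(2))  # means 2 vs 1, both sds sqrt(2)

  two <- tibble::tibble(
    roi_value = c(exact_moment_sample(10, 1, 1, seed = 1),
                  exact_moment_sample(10, 0, 1, seed = 2)),
    impaired = rep(c(TRUE, FALSE), each = 10)
  )
  expect_equal(cohens_d(two)$d, 1)

  ident <- tibble::tibble(roi_value = rep(c(1, 2), 2),
                          impaired = rep(c(TRUE, FALSE), each = 2))
  expect_equal(cohens_d(ident)$d, 0)
  expect_error(cohens_d(tibble::tibble(roi_value = rep(1, 4),
                                       impaired = rep(c(TRUE, FALSE), 2))),
               "pooled")
})

test_that("ROI values table joins outcomes and feeds the classifier", {
  spec <- phantom_spec(shape = c(8, 8, 8), blob_centre = c(4, 4, 4),
                       blob_radius = 2, amplitude = 0.2, noise_sd = 0.02,
                       seed = 85)
  st <- generate_phantom_cohort(spec, 5, 5)
  mask <- sphere_mask(c(8, 8, 8), c(4, 4, 4), 2) == 1
  roi <- structure(list(mask = mask, weights = array(mask / sum(mask), dim(mask)),
                        size = sum(mask), empty = FALSE, alpha = 0.05,
                        weighting = "uniform", voxel_size = c(2, 2, 2)),
                   class = "cluster_roi")
  outcomes <- tibble::tibble(subject_id = st$subject_id,
                             impaired = st$group == "B")
  tab <- roi_values_table(st, roi, outcomes)
  expect_equal(nrow(tab), 10)
  # group B carries the blob, so its ROI values sit ~0.2 higher
  expect_gt(mean(tab$roi_value[tab$impaired]) -
            mean(tab$roi_value[!tab$impaired]), 0.15)
  fit <- loocv_classify(tab)
  expect_gt(fit$accuracy, 0.8)
})
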