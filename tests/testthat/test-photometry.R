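test_that("patch statistics match direct summation", {
  m <- matrix(50, 60, 60)
  p <- sample_patches(m, locations = tibble::tibble(x = 10, y = 10))
  expect_equal(p$mean, 50)
  expect_equal(p$sd, 0)
  expect_true(is.na(p$snr))

  # 13 rows of 100 and 12 rows of 0 in a 25x25 patch
  m2 <- matrix(0, 40, 40)
  m2[seq(1, 25, by = 2), ] <- 100
  p2 <- sample_patches(m2, locations = tibble::tibble(x = 0, y = 0))
  expect_equal(p2$mean, 13 * 25 * 100 / 625)
  mu <- p2$mean
  expect_equal(p2$sd, sqrt((13 * 25 * (100 - mu)^2 + 12 * 25 * mu^2) / 625))
})

test_that("patch evaluation is pure and order independent", {
  m <- matrix(runif(100 * 100, 0, 255), 100)
  a <- tibble::tibble(x = 5, y = 5); b <- tibble::tibble(x = 60, y = 60)
  p_ab <- sample_patches(m, locations = dplyr::bind_rows(a, b))
  p_ba <- sample_patches(m, locations = dplyr::bind_rows(b, a))
  expect_equal(p_ab$mean, rev(p_ba$mean))
  expect_equal(p_ab$sd, rev(p_ba$sd))
})

test_that("out-of-bounds patches are rejected by location", {
  m <- matrix(0, 50, 50)
  expect_error(sample_patches(m, locations = tibble::tibble(x = 30, y = 10)),
               "x = 30")
})

test_that("auto-sampling respects the mask and non-overlap rule", {
  m <- matrix(10, 200, 200)
  mask <- matrix(FALSE, 200, 200); mask[30:170, 30:170] <- TRUE
  p <- sample_patches(m, mask = mask, n = 12, seed = 4)
  expect_equal(nrow(p), 12)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_true(abs(p$x[i] - p$x[j]) >= 25 || abs(p$y[i] - p$y[j]) >= 25)
  }
  expect_error(sample_patches(m, mask = mask, n = 50, seed = 4),
               "could only place")
})

test_that("contrast follows its definition and bootstrap brackets the truth", {
  p <- dplyr::bind_rows(
    tibble::tibble(x = 0, y = 0, side = 25, label = "viable", mean = 100,
                   sd = 7, snr = 100 / 7),
    tibble::tibble(x = 0, y = 0, side = 25, label = "non_viable",
                   mean = 6.49, sd = 7, snr = 6.49 / 7))
  ctr <- patch_contrast(p, n_boot = 50)
  expect_equal(ctr$contrast, 100 / 6.49, tolerance = 1e-12)

  same <- dplyr::mutate(p, mean = 80)
  expect_equal(patch_contrast(same, n_boot = 50)$contrast, 1)

  zero <- dplyr::mutate(p, mean = ifelse(label == "non_viable", 0, mean))
  expect_error(patch_contrast(zero), "zero")
})

test_that("bootstrap CI of the contrast covers the generating ratio", {
  true_ratio <- 15
  hits <- 0
  for (i in 1:60) {
    dat <- withr::with_seed(1000 + i, dplyr::bind_rows(
      tibble::tibble(x = 0, y = 0, side = 25, label = "viable",
                     mean = rnorm(40, 97.5, 7), sd = 7, snr = 14),
      tibble::tibble(x = 0, y = 0, side = 25, label = "non_viable",
                     mean = rnorm(40, 6.5, 1.5), sd = 7, snr = 1)))
    ci <- patch_contrast(dat, n_boot = 400, seed = i)$ci
    if (ci[1] <= true_ratio && true_ratio <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)
})

test_that("the ROC sweep matches the brute-force oracle exactly", {
  set.seed(31)
  p <- dplyr::bind_rows(
    tibble::tibble(x = 0, y = 0, side = 25, label = "viable",
                   mean = round(rnorm(90, 95, 20)), sd = 7, snr = 14),
    tibble::tibble(x = 0, y = 0, side = 25, label = "non_viable",
                   mean = pmax(0, round(rnorm(90, 20, 15))), sd = 7, snr = 2))
  r <- patch_roc(p)
  oracle <- roc_oracle(p)
  expect_equal(r$curve$sensitivity, oracle$sensitivity)
  expect_equal(r$curve$specificity, oracle$specificity)
  expect_true(all(diff(r$curve$sensitivity) <= 0))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(p$label == "viable", p$mean,
                                            quiet = TRUE)))
  expect_equal(r$auc, auc_ref, tolerance = 1e-9)
})

test_that("ROC endpoints: perfect separation and shuffled labels", {
  sep <- dplyr::bind_rows(
    tibble::tibble(x = 0, y = 0, side = 25, label = "viable",
                   mean = c(100, 110, 120), sd = 7, snr = 14),
    tibble::tibble(x = 0, y = 0, side = 25, label = "non_viable",
                   mean = c(5, 9, 12), sd = 7, snr = 1))
  r <- patch_roc(sep, cutoff = 50)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  shuffled <- withr::with_seed(8, tibble::tibble(
    x = 0, y = 0, side = 25,
    label = sample(rep(c("viable", "non_viable"), each = 400)),
    mean = runif(800, 0, 255), sd = 7, snr = 1))
  expect_lt(abs(patch_roc(shuffled)$auc - 0.5), 0.05)

  expect_error(patch_roc(dplyr::filter(sep, label == "viable")),
               "both classes")
})

test_that("the Youden cutoff breaks ties toward the lower threshold", {
  p <- dplyr::bind_rows(
    tibble::tibble(x = 0, y = 0, side = 25, label = "viable",
                   mean = c(100, 120), sd = 7, snr = 14),
    tibble::tibble(x = 0, y = 0, side = 25, label = "non_viable",
                   mean = c(10, 20), sd = 7, snr = 1))
  r <- patch_roc(p, youden = TRUE)
  # J is maximal (and tied) for all thresholds in [20, 99]; pick the lowest
  expect_equal(r$cutoff, 20)
})
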