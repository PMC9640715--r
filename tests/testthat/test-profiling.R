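test_that("SNV normalization standardizes rows and is affine-invariant", {
  set.seed(1)
  m <- matrix(rnorm(100), 5, 20,
              dimnames = list(paste0("B", 1:5), NULL))
  s <- snv_normalize(m)
  expect_lt(max(abs(rowMeans(s))), 1e-12)
  expect_lt(max(abs(apply(s, 1, sd) - 1)), 1e-12)

  already <- snv_normalize(s)
  expect_equal(already, s, tolerance = 1e-12)

  shifted <- snv_normalize(m + 17)           # location invariance
  expect_equal(shifted, s, tolerance = 1e-12)
  affine <- snv_normalize(3.2 * m - 4)       # snv(a x + b) = snv(x)
  expect_equal(affine, s, tolerance = 1e-12)

  m[2, ] <- 7
  expect_error(snv_normalize(m), "zero-variance.*B2")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(2)
  m <- matrix(rnorm(500), 10, 50)
  pca <- fit_pca(m)
  expect_equal(pca$n_components, 9L)

  ev_oracle <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
  frac_oracle <- ev_oracle / sum(ev_oracle)
  expect_equal(pca$variance_explained, frac_oracle[1:9], tolerance = 1e-8)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  expect_true(all(pca$variance_explained >= 0 & pca$variance_explained <= 1))
  expect_lte(sum(pca$variance_explained), 1 + 1e-12)

  # loadings orthonormal; scores reconstruct the centered data
  expect_equal(unname(crossprod(pca$loadings)), diag(9), tolerance = 1e-8)
  centered <- sweep(m, 2, colMeans(m))
  recon <- pca$scores %*% t(pca$loadings)
  expect_lt(norm(recon - centered, "F") / norm(centered, "F"), 1e-8)
})

test_that("PCA degenerate geometries behave as expected", {
  set.seed(3)
  t <- runif(12)
  line <- outer(t, c(1, -2, 0.5)) + rep(c(3, 1, 2), each = 12)
  pca <- fit_pca(line)
  expect_equal(pca$variance_explained[1], 1, tolerance = 1e-12)

  m <- matrix(rnorm(40), 4, 10)
  dup <- rbind(m, m[2, ])
  p2 <- fit_pca(dup)
  expect_equal(p2$scores[2, ], p2$scores[5, ], tolerance = 1e-9)

  expect_warning(p3 <- fit_pca(m, n_components = 99), "clipped")
  expect_equal(p3$n_components, 3L)
})

test_that("cross-validation separates separable clouds and is deterministic", {
  set.seed(4)
  n <- 30
  x <- rbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2) + 10, n, 2))
  y <- rep(c("a", "b"), each = n)
  for (alg in c("bagged_trees", "linear_svm")) {
    cv <- crossval_classify(x, y, alg, k = 6, seed = 5)
    expect_equal(cv$accuracy, 1.0)
    expect_equal(sum(cv$confusion_matrix), 60)
    expect_equal(rowSums(cv$confusion_matrix), c(a = n, b = n))
    expect_equal(unname(cv$per_class_auc), c(1, 1))
  }
  cv1 <- crossval_classify(x, y, "boosted_trees", k = 6, seed = 9)
  cv2 <- crossval_classify(x, y, "boosted_trees", k = 6, seed = 9)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$accuracy, cv2$accuracy)
})

test_that("permuted labels fall back to chance-level accuracy", {
  set.seed(6)
  x <- matrix(rnorm(240), 60, 4)
  y <- sample(rep(c("a", "b"), c(40, 20)))  # labels independent of x
  cv <- crossval_classify(x, y, "linear_svm", k = 6, seed = 7)
  # chance level: majority-class fraction 2/3, binomial 99% envelope
  expect_lt(abs(cv$accuracy - 2 / 3), 2.58 * sqrt(2 / 9 / 60) + 0.05)
})

test_that("a simulated four-class TMA classifies by tissue type", {
  sheet <- brain_cohort_sheet(seed = 10)
  lay <- build_tma_layout(sheet_plates(sheet), 4)
  g <- mz_grid(500, 1000, 0.05)
  sim <- simulate_fullscan_run(lay, sheet, noise_model(seed = 10), g,
                               scans_per_spot = 3)
  res <- process_fullscan(sim$stream, sim$stage_log, lay, sim$plate_map, g)
  m <- drop_low_columns(profile_matrix(res$profiles))
  pca <- fit_pca(snv_normalize(m))
  labels <- sheet$tissue_class[match(rownames(m), sheet$biopsy_id)]
  w <- capture_warnings(cv <- crossval_classify(pca$scores, labels,
                                                "bagged_trees",
                                                k = 6, seed = 10))
  expect_length(w, 2)  # meningioma (5) and pituitary (4) classes < 6 folds
  expect_match(w, "fewer samples", all = TRUE)
  expect_gt(cv$accuracy, 0.9)
  wrong <- cv$predictions[as.character(cv$predictions$truth) !=
                            as.character(cv$predictions$predicted), ]
  # residual confusion is between parenchyma and glioma only
  expect_true(all(wrong$truth %in% c("NCB", "glioma")))
  expect_true(all(wrong$predicted %in% c("NCB", "glioma")))
})

test_that("marker ranking reports both extremes of a component", {
  set.seed(8)
  m <- matrix(rnorm(200, sd = 0.05), 20, 10)
  m[, 4] <- rnorm(20, sd = 5)  # dominant variable
  colnames(m) <- sprintf("%.4f", seq(700, 790, 10))
  pca <- fit_pca(m)
  rk <- rank_markers(pca, 1, top_n = 3)
  expect_equal(rk$mz[1], 730)
  expect_gt(rk$coefficient[1], 0)  # sign convention: dominant loading positive
  expect_true(all(diff(rk$coefficient) <= 0))
  expect_setequal(unique(rk$direction), c("positive", "negative"))
})

test_that("planted class markers occupy opposite extremes of PC1", {
  # two-class cohort: pure low-TCP vs high-TCP glioma
  sheet <- sample_sheet(tissue_class = rep("glioma", 12),
                        tcp = rep(c(0.05, 0.95), each = 6),
                        idh = "wildtype", true_2hg_glu_ratio = 0)
  lay <- build_tma_layout(sheet_plates(sheet), 2)
  g <- mz_grid(500, 1000, 0.05)
  sim <- simulate_fullscan_run(lay, sheet, noise_model(seed = 3), g,
                               scans_per_spot = 3)
  res <- process_fullscan(sim$stream, sim$stage_log, lay, sim$plate_map, g)
  m <- drop_low_columns(profile_matrix(res$profiles))
  pca <- fit_pca(snv_normalize(m))
  rk <- rank_markers(pca, 1, top_n = 5)
  tab <- builtin_marker_table()
  near <- function(mzv, name) {
    any(abs(mzv - tab$theoretical_mz[tab$name == name]) < 0.05)
  }
  pos <- rk$mz[rk$direction == "positive"]
  neg <- rk$mz[rk$direction == "negative"]
  # the normal-tissue base peak and the tumor base peak land on opposite ends
  ps_pos <- near(pos, "PS 36:1"); ps_neg <- near(neg, "PS 36:1")
  pe_pos <- near(pos, "PE 38:4"); pe_neg <- near(neg, "PE 38:4")
  expect_true((ps_pos && pe_neg) || (ps_neg && pe_pos))
})
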