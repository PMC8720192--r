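mk_design <- function(n, seed = 1) {
  set.seed(seed)
  cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
}

test_that("residualize removes design variance and leaves orthogonal
           residuals", {
  d <- mk_design(80)
  # a design column residualizes to ~0
  r <- residualize(cbind(x = d[, "a"]), d)
  expect_lt(max(abs(r)), 1e-10)
  # intercept-only design centers the data
  x <- matrix(rnorm(80), ncol = 1)
  r2 <- residualize(x, matrix(1, 80, 1))
  expect_equal(as.numeric(r2), as.numeric(x - mean(x)), tolerance = 1e-12)
  # residuals orthogonal to every design column
  xm <- matrix(rnorm(240), 80, 3)
  res <- residualize(xm, d)
  expect_lt(max(abs(crossprod(d, res))), 1e-8)
  # idempotence
  expect_equal(residualize(res, d), res, tolerance = 1e-10)
})

test_that("residualize recovers known confound coefficients", {
  set.seed(3)
  n <- 600
  d <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
  beta <- c(2, 0.8, -1.5)
  y <- d %*% beta + rnorm(n, sd = 0.3)
  res <- residualize(cbind(y = y), d)
  # implied fitted coefficients: refit on (y - res)
  coef_hat <- qr.solve(d, y - res)
  expect_equal(as.numeric(coef_hat), beta, tolerance = 0.05)
})

test_that("residualize skips missing rows per variable and errors on
           rank deficiency", {
  d <- mk_design(50)
  x <- matrix(rnorm(100), 50, 2)
  x[c(3, 9), 1] <- NA
  res <- residualize(x, d)
  expect_true(all(is.na(res[c(3, 9), 1])))
  obs <- !is.na(x[, 1])
  expect_lt(max(abs(crossprod(d[obs, ], res[obs, 1]))), 1e-8)
  bad <- cbind(d, dup = d[, "a"])
  expect_error(residualize(x, bad), "collinear.*dup")
})

test_that("knn imputation fills from the nearest twin and never touches
           observed cells", {
  twin <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(9, 9, 9, 9))
  holed <- twin
  holed[1, 3] <- NA
  out <- knn_impute(holed, k = 1)
  expect_identical(out[1, 3], 3)
  expect_identical(out[-1, ], twin[-1, ])
  # no missing cells: identity
  expect_identical(knn_impute(twin, k = 2), twin)
})

test_that("knn imputation matches the exhaustive-distance oracle", {
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(rnorm(24), 6, 4)
    m[sample(24, 3)] <- NA
    keep <- rowSums(!is.na(m)) > 0 & TRUE
    for (k in 1:2) {
      expect_equal(knn_impute(m, k = k), oracle_knn(m, k),
                   tolerance = 1e-10)
    }
  }
})

test_that("knn imputation respects modality groups and errors on empty
           rows", {
  m <- cbind(g1a = c(1, NA, 5), g1b = c(1, 2, 5),
             g2a = c(100, 2, 3), g2b = c(100, 2, 3))
  # within group g1, row 2 is closest to row 1 on g1b; g2 values must not
  # drive the distance
  out <- knn_impute(m, k = 1, groups = c("g1", "g1", "g2", "g2"))
  expect_identical(unname(out[2, "g1a"]), 1)
  allna <- cbind(a = c(NA, 1), b = c(NA, 2))
  expect_error(knn_impute(allna, groups = c("g", "g")), "all variables missing")
})

test_that("PCA retains the minimal component count for the variance
           target", {
  set.seed(12)
  iid <- matrix(rnorm(2000 * 10), ncol = 10)
  fit <- fit_pca_group(iid, "iid", 0.5)
  expect_identical(fit$n_comp, 5L)
  # rank-1 data: one component explaining everything
  v <- rnorm(50)
  rank1 <- outer(v, c(1, 2, -1)) + 1e-8 * matrix(rnorm(150), 50)
  f1 <- fit_pca_group(rank1, "r1", 0.5)
  expect_identical(f1$n_comp, 1L)
  expect_gt(f1$explained, 0.999)
  # monotone non-decreasing retained count in the target
  x <- matrix(rnorm(300 * 8), ncol = 8)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9),
                   function(vt) fit_pca_group(x, "m", vt)$n_comp, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("projection reproduces training scores and hand-computed
           products", {
  set.seed(4)
  x <- matrix(rnorm(120 * 6), ncol = 6)
  colnames(x) <- paste0("v", 1:6)
  fit <- fit_pca_group(x, "m", 0.6)
  scores_fit <- pca_project(fit, x)
  hand <- scale(x, fit$centers, fit$scalings) %*% fit$rotation
  expect_equal(scores_fit, hand, tolerance = 1e-12, ignore_attr = TRUE)
  # held-out rows equal the same matrix product
  new <- matrix(rnorm(60), ncol = 6)
  colnames(new) <- colnames(x)
  expect_equal(
    pca_project(fit, new),
    sweep(sweep(new, 2, fit$centers), 2, fit$scalings, "/") %*% fit$rotation,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # zero-vector subject (at the training means) projects to zero scores
  at_mean <- matrix(fit$centers, 1)
  colnames(at_mean) <- colnames(x)
  expect_lt(max(abs(pca_project(fit, at_mean))), 1e-12)
  wrong <- new
  colnames(wrong) <- paste0("w", 1:6)
  expect_error(pca_project(fit, wrong), "variable set")
})

test_that("PCA sign convention puts the dominant loading positive and the
           model round-trips through JSON", {
  set.seed(6)
  x <- matrix(rnorm(200 * 5), ncol = 5)
  colnames(x) <- paste0("v", 1:5)
  fit <- fit_pca_group(x, "m", 0.8)
  peaks <- apply(fit$rotation, 2L, function(cc) cc[which.max(abs(cc))])
  expect_true(all(peaks > 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(fit, path)
  back <- read_pca_model(path)
  expect_equal(back$rotation, fit$rotation, tolerance = 1e-12)
  expect_equal(pca_project(back, x), pca_project(fit, x), tolerance = 1e-12)
})
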