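test_that("identical single columns give a perfect canonical correlation", {
  set.seed(1)
  x <- matrix(rnorm(50), ncol = 1)
  fit <- fit_cca(x, x)
  expect_equal(fit$r, 1, tolerance = 1e-10)
})

test_that("canonical score pairs reproduce r and are orthogonal across
           modes", {
  set.seed(2)
  x <- matrix(rnorm(200 * 6), ncol = 6)
  y <- matrix(rnorm(200 * 4), ncol = 4)
  fit <- fit_cca(x, y)
  expect_true(all(diff(fit$r) <= 1e-12))
  for (k in seq_along(fit$r)) {
    expect_equal(cor(fit$U[, k], fit$V[, k]), fit$r[k], tolerance = 1e-10)
  }
  cu <- cor(fit$U); cv <- cor(fit$V)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  peaks <- apply(fit$B, 2L, function(cc) cc[which.max(abs(cc))])
  expect_true(all(peaks > 0))
})

test_that("canonical correlations agree with the stats::cancor oracle and
           are invariant to within-block recombination", {
  set.seed(3)
  x <- matrix(rnorm(120 * 5), ncol = 5)
  y <- matrix(rnorm(120 * 3), ncol = 3)
  fit <- fit_cca(x, y)
  oracle <- stats::cancor(x, y)
  expect_equal(fit$r, oracle$cor, tolerance = 1e-9)
  mx <- matrix(rnorm(25), 5) + diag(5)
  my <- matrix(rnorm(9), 3) + diag(3)
  refit <- fit_cca(x %*% mx, y %*% my + 2)
  expect_equal(refit$r, fit$r, tolerance = 1e-9)
})

test_that("the null leading canonical correlation sits near its maximized
           expectation, not zero", {
  set.seed(4)
  r1 <- replicate(10, {
    fit_cca(matrix(rnorm(200 * 10), ncol = 10),
            matrix(rnorm(200 * 5), ncol = 5))$r[1]
  })
  # (sqrt(p) + sqrt(q)) / sqrt(n) ~ 0.38 for p=10, q=5, n=200
  expect_gt(mean(r1), 0.2)
  expect_lt(mean(r1), 0.6)
})

test_that("rank-deficient blocks are rejected with the block named", {
  set.seed(5)
  x <- matrix(rnorm(60 * 3), ncol = 3)
  expect_error(fit_cca(cbind(x, x[, 1]), matrix(rnorm(60), ncol = 1)),
               "block 'x'")
  expect_error(fit_cca(x, cbind(rnorm(60), rep(0, 60))), "block 'y'")
})

test_that("permutation p-values use the add-one rule and both-block
           shuffling preserves the observed fit", {
  set.seed(6)
  x <- matrix(rnorm(150 * 4), ncol = 4)
  y <- 0.5 * x[, 1:2] + matrix(rnorm(150 * 2), ncol = 2) * 0.8
  fit <- fit_cca(x, y)
  out <- cca_permutation(x, y, n_perm = 200, seed = 2)
  expect_equal(out$r, fit$r, tolerance = 1e-12)
  expect_true(all(out$p_perm >= 1 / 201))
  expect_true(all(out$p_perm <= 1))
  expect_identical(dim(out$null_r), c(200L, 2L))
  # strong planted signal: p at the resolution floor
  expect_equal(out$p_perm[1], 1 / 201, tolerance = 1e-12)
  expect_error(cca_permutation(x, y, n_perm = 0), "positive count")
  expect_warning(cca_permutation(x, y, n_perm = 50, seed = 1),
                 "fewer than 100")
})

test_that("the documented Bonferroni threshold arises from the IDP
           inventory counts", {
  thr <- bonferroni_threshold(c(3466, 346, 16))
  expect_equal(thr, 0.05 / 3828, tolerance = 1e-15)
  expect_equal(signif(thr, 2), 1.3e-5)
})

test_that("averaged-UV loadings are exact for self-correlation and less
           optimistic than U-side loadings", {
  set.seed(7)
  n <- 300
  x <- matrix(rnorm(n * 6), ncol = 6)
  y <- x[, 1:3] * 0.6 + matrix(rnorm(n * 3), ncol = 3)
  fit <- fit_cca(x, y)
  uv <- (scale(fit$U[, 1]) + scale(fit$V[, 1])) / 2
  idps <- cbind(self = as.numeric(uv), x)
  lt <- uv_loadings(fit, idps)
  expect_equal(lt$loading[lt$idp == "self"], 1, tolerance = 1e-10)
  expect_s3_class(lt, "loading_table")
  # optimism reduction for IDPs in the span of X
  u_load <- abs(cor(fit$U[, 1], x))
  uv_load <- abs(lt$loading[-1])
  expect_true(all(uv_load <= u_load + 1e-8))
  expect_error(uv_loadings(fit, idps, mode = 10), "mode out of range")
})

test_that("self-replication reproduces the training canonical
           correlations", {
  set.seed(8)
  x <- matrix(rnorm(150 * 5), ncol = 5)
  y <- 0.4 * x[, 1:3] + matrix(rnorm(150 * 3), ncol = 3)
  fit <- fit_cca(x, y)
  rep <- cca_replicate(fit, x, y)
  expect_equal(rep$r, fit$r, tolerance = 1e-10)
  expect_error(cca_replicate(fit, x[, 1:3], y), "dimensions")
})

test_that("without a planted effect, held-out canonical correlations
           center on zero", {
  set.seed(9)
  r_new <- replicate(12, {
    x <- matrix(rnorm(400 * 6), ncol = 6)
    y <- matrix(rnorm(400 * 3), ncol = 3)
    fit <- fit_cca(x[1:200, ], y[1:200, ])
    cca_replicate(fit, x[201:400, ], y[201:400, ])$r[1]
  })
  # training r1 for these dimensions sits near 0.3; held-out r1 does not
  expect_lt(abs(mean(r_new)), 0.1)
})

test_that("tidy and glance expose modes and the subjects-per-variable
           ratio", {
  set.seed(10)
  x <- matrix(rnorm(131 * 4), ncol = 4)
  y <- matrix(rnorm(131 * 2), ncol = 2)
  fit <- fit_cca(x, y)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L)
  gl <- glance(fit)
  expect_equal(gl$subjects_per_variable, 131 / 6, tolerance = 1e-12)
})
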