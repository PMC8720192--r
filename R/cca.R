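#' Canonical correlation analysis of two variable blocks
#'
#' Finds coefficient matrices `A` and `B` such that successive pairs of
#' canonical scores `U = Xc A`, `V = Yc B` have maximal correlation subject
#' to orthogonality of earlier modes. The solver whitens each block with
#' the inverse square root of its covariance and takes the SVD of the
#' whitened cross-covariance, which keeps the orthogonality invariants
#' exact. Sign convention: in each mode the largest-magnitude Y-side
#' coefficient is positive.
#'
#' @param x Brain-side block (e.g., PCA component scores), subjects x p.
#' @param y Phenotype-side block (residualized summary scores), subjects x q.
#' @return A `cca_model`: coefficients `A`, `B`, canonical correlations
#'   `r` (non-increasing), scores `U`, `V`, column centers, and block
#'   dimensions. `p_perm` is filled by [cca_permutation()].
#' @export
fit_cca <- function(x, y) {
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  assert_that(
    "blocks must have the same number of subjects" = nrow(x) == nrow(y),
    "need more subjects than variables in each block" =
      nrow(x) > ncol(x) && nrow(y) > ncol(y)
  )
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  wx <- whitener(xc, "x")
  wy <- whitener(yc, "y")
  k <- crossprod(xc %*% wx, yc %*% wy) / (nrow(x) - 1)
  sv <- svd(k)
  m <- min(ncol(x), ncol(y))
  a <- wx %*% sv$u[, seq_len(m), drop = FALSE]
  b <- wy %*% sv$v[, seq_len(m), drop = FALSE]
  for (kk in seq_len(m)) {
    peak <- which.max(abs(b[, kk]))
    if (b[peak, kk] < 0) {
      b[, kk] <- -b[, kk]
      a[, kk] <- -a[, kk]
    }
  }
  rownames(a) <- colnames(x); rownames(b) <- colnames(y)
  structure(
    list(
      A = a, B = b, r = pmin(sv$d[seq_len(m)], 1),
      U = xc %*% a, V = yc %*% b,
      centers_x = cx, centers_y = cy,
      x_names = colnames(x), y_names = colnames(y),
      n = nrow(x), p = ncol(x), q = ncol(y),
      p_perm = NULL
    ),
    class = "cca_model"
  )
}

# inverse square root of a block covariance; rank deficiency is reported
# with the offending block's name
whitener <- function(xc, block) {
  s <- crossprod(xc) / (nrow(xc) - 1)
  eg <- eigen(s, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  if (any(eg$values < tol)) {
    abort(sprintf("block '%s' is rank deficient; drop collinear columns",
                  block))
  }
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> n = %d, %d x-vars vs %d y-vars (%.1f subjects/variable)\n",
              x$n, x$p, x$q, x$n / (x$p + x$q)))
  cat("  canonical r:", paste(sprintf("%.3f", x$r), collapse = ", "), "\n")
  if (!is.null(x$p_perm)) {
    cat("  permutation p:", paste(signif(x$p_perm, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Permutation inference for canonical correlations
#'
#' For each permutation the subject order of the two blocks is shuffled
#' *independently* to break subject correspondence, the CCA is refit, and
#' all canonical correlations are recorded. Per mode,
#' `p_k = (1 + #\{perm r_k >= observed r_k\}) / (1 + n_perm)`, so p is never
#' exactly zero. The null distribution of the leading canonical correlation
#' does not center on zero — the statistic is explicitly maximized — which
#' is why permutation calibration matters here.
#'
#' @param x,y The blocks passed to [fit_cca()].
#' @param n_perm Number of permutations (default 2000; must be >= 1, and
#'   at least 100 for usable resolution).
#' @param seed Integer seed for the permutation stream.
#' @param model Optional prefitted `cca_model` for the observed statistics.
#' @return The `cca_model` with `p_perm` filled and the permutation null
#'   (an `n_perm` x modes matrix) in `$null_r`.
#' @export
cca_permutation <- function(x, y, n_perm = 2000L, seed = 1L, model = NULL) {
  assert_that("n_perm must be a positive count" = is_count(n_perm))
  if (n_perm < 100L) warn("fewer than 100 permutations gives coarse p values")
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  model <- model %||% fit_cca(x, y)
  n <- nrow(x)
  xc <- sweep(x, 2L, model$centers_x)
  yc <- sweep(y, 2L, model$centers_y)
  xw <- xc %*% whitener(xc, "x")
  yw <- yc %*% whitener(yc, "y")
  m <- length(model$r)
  null_r <- matrix(NA_real_, n_perm, m)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p1 <- sample.int(n)
      p2 <- sample.int(n)
      k <- crossprod(xw[p1, , drop = FALSE], yw[p2, , drop = FALSE]) / (n - 1)
      null_r[b, ] <- svd(k, nu = 0L, nv = 0L)$d[seq_len(m)]
    }
  })
  exceed <- vapply(seq_len(m), function(kk) {
    sum(null_r[, kk] >= model$r[kk])
  }, numeric(1))
  model$p_perm <- (1 + exceed) / (1 + n_perm)
  model$null_r <- null_r
  model$n_perm <- n_perm
  model
}

#' Bonferroni threshold across all tested IDPs
#'
#' @param counts Integer vector of IDP counts per group (summed), or a
#'   single total.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test significance threshold `alpha / sum(counts)`.
#' @export
#' @examples
#' bonferroni_threshold(c(3466, 346, 16)) # 1.3e-05
bonferroni_threshold <- function(counts, alpha = 0.05) {
  assert_that("counts must be positive" = all(counts >= 1))
  alpha / sum(counts)
}

#' Averaged-UV loadings of original IDPs on a canonical mode
#'
#' The `U` and `V` subject scores of the chosen mode are z-scored and
#' averaged within subject; correlating this averaged score (rather than
#' `U`, which is optimized for the brain block) against each original IDP
#' gives a less optimistic estimate of the IDP's contribution. Raw p values
#' come from the correlation t test; the Bonferroni flag uses
#' `alpha / n_tests` with `n_tests` defaulting to the number of IDPs
#' supplied.
#'
#' @param model A fitted `cca_model`.
#' @param idps Residualized original IDP matrix, row-aligned with the
#'   subjects the model was fitted on.
#' @param mode Canonical mode index (default 1, the strongest).
#' @param modality Optional per-IDP modality tags.
#' @param n_tests Total number of IDPs tested for the Bonferroni threshold.
#' @param alpha Family-wise error rate.
#' @return A `loading_table` tibble: `idp`, `modality`, `loading`,
#'   `p_value`, `significant`; threshold and mode in attributes.
#' @export
uv_loadings <- function(model, idps, mode = 1L, modality = NULL,
                        n_tests = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "cca_model"))
  assert_that("mode out of range" = is_count(mode) && mode <= length(model$r))
  idps <- as_numeric_matrix(idps, "idps")
  assert_that("IDP rows must align with the fitted subjects" =
                nrow(idps) == model$n)
  uv <- (as.numeric(scale(model$U[, mode])) +
           as.numeric(scale(model$V[, mode]))) / 2
  n_tests <- n_tests %||% ncol(idps)
  thr <- bonferroni_threshold(n_tests, alpha)
  loading <- as.numeric(cor(uv, idps, use = "pairwise.complete.obs"))
  n_obs <- colSums(!is.na(idps))
  tt <- loading * sqrt((n_obs - 2) / pmax(1 - loading^2, 1e-300))
  p <- 2 * pt(-abs(tt), df = n_obs - 2)
  out <- tibble::tibble(
    idp = colnames(idps) %||% sprintf("idp_%03d", seq_len(ncol(idps))),
    modality = modality %||% NA_character_,
    loading = loading, p_value = p, significant = p < thr
  )
  attr(out, "threshold") <- thr
  attr(out, "mode") <- mode
  attr(out, "uv_mean") <- uv
  class(out) <- c("loading_table", class(out))
  out
}

#' Replicate a fitted CCA in an independent sample
#'
#' Held-out subjects are projected with the training PCA loadings and the
#' training canonical coefficients (`U' = X' A`, `V' = Y' B`; nothing is
#' refit), and the replication canonical correlation per mode is
#' `cor(U'_k, V'_k)`. Because the held-out correlation is not a maximized
#' statistic, its p value comes from the parametric correlation test,
#' Bonferroni-corrected by the number of modes.
#'
#' @param model Training `cca_model`.
#' @param x_new Held-out brain block projected onto the training PCA
#'   subspace (columns must match the training block).
#' @param y_new Held-out phenotype block, residualized within its own
#'   sample.
#' @return Tibble: `mode`, `r`, `p_value` (uncorrected), `p_bonferroni`.
#' @export
cca_replicate <- function(model, x_new, y_new) {
  stopifnot(inherits(model, "cca_model"))
  x_new <- as_numeric_matrix(x_new, "x_new")
  y_new <- as_numeric_matrix(y_new, "y_new")
  if (ncol(x_new) != model$p || ncol(y_new) != model$q) {
    abort("held-out block dimensions do not match the stored model")
  }
  if (!is.null(colnames(x_new)) && !is.null(model$x_names) &&
      !identical(colnames(x_new), model$x_names)) {
    abort("held-out x columns do not match the stored model")
  }
  u <- scale(x_new, center = TRUE, scale = FALSE) %*% model$A
  v <- scale(y_new, center = TRUE, scale = FALSE) %*% model$B
  m <- length(model$r)
  n <- nrow(x_new)
  r_new <- vapply(seq_len(m), function(kk) cor(u[, kk], v[, kk]), numeric(1))
  tt <- r_new * sqrt((n - 2) / pmax(1 - r_new^2, 1e-300))
  p <- 2 * pt(-abs(tt), df = n - 2)
  tibble::tibble(
    mode = seq_len(m), r = r_new, p_value = p,
    p_bonferroni = pmin(1, m * p)
  )
}
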