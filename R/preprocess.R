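#' Build the confound design matrix
#'
#' Constructs the "simple" imaging confound design: scanning site (one-hot
#' with the first level as reference), age, age squared, sex, age x sex,
#' head size, head motion in resting and task fMRI, acquisition date (days
#' since the sample's earliest scan) and date squared, plus an intercept.
#' Continuous columns are centered before squaring or interacting.
#'
#' @param tbl Phenotype table rows for one sample (one row per subject).
#' @return Numeric design matrix with an intercept column, checked to be
#'   full column rank.
#' @export
confound_design <- function(tbl) {
  needed <- c("site", "age", "sex", "head_size", "head_motion_rest",
              "head_motion_task", "scan_date")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("confound column(s) absent: ",
                 paste(missing_cols, collapse = ", ")))
  }
  site <- factor(tbl$site)
  site_mat <- NULL
  if (nlevels(site) > 1L) {
    site_mat <- stats::model.matrix(~site)[, -1L, drop = FALSE]
    colnames(site_mat) <- paste0("site_", levels(site)[-1L])
  }
  age_c <- tbl$age - mean(tbl$age)
  date_c <- (tbl$scan_date - min(tbl$scan_date))
  date_c <- date_c - mean(date_c)
  design <- cbind(
    intercept = 1,
    site_mat,
    age = age_c,
    age2 = age_c^2,
    sex = tbl$sex,
    age_sex = age_c * tbl$sex,
    head_size = tbl$head_size - mean(tbl$head_size),
    head_motion_rest = tbl$head_motion_rest,
    head_motion_task = tbl$head_motion_task,
    date = date_c,
    date2 = date_c^2
  )
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    abort(paste0("confound design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  design
}

#' Residualize variables on a confound design
#'
#' Removes, per variable, the least-squares fit on the design. Rows with a
#' missing value in a variable are skipped for that variable's fit and stay
#' missing in the output; residuals are orthogonal to every design column.
#'
#' @param data Subjects x variables matrix or data frame (may contain NA).
#' @param design Design matrix from [confound_design()] (same rows).
#' @return Matrix of residuals, missing cells preserved.
#' @export
residualize <- function(data, design) {
  x <- as_numeric_matrix(data, "data")
  design <- as.matrix(design)
  assert_that("data and design row counts differ" = nrow(x) == nrow(design))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- x
  complete_cols <- which(colSums(is.na(x)) == 0L)
  if (length(complete_cols)) {
    out[, complete_cols] <- qr.resid(qr_d, x[, complete_cols, drop = FALSE])
  }
  for (j in setdiff(seq_len(ncol(x)), complete_cols)) {
    obs <- which(!is.na(x[, j]))
    if (length(obs) <= ncol(design)) {
      abort(sprintf("too few observed rows to residualize column %s",
                    colnames(x)[j] %||% j))
    }
    fit <- lm.fit(design[obs, , drop = FALSE], x[obs, j])
    out[obs, j] <- fit$residuals
  }
  out
}

#' Nearest-neighbour imputation of missing cells
#'
#' Fills each missing cell with the mean of that variable's values from the
#' `k` nearest subjects. Distance between two subjects is the Euclidean
#' distance over the variables observed in both rows, computed within the
#' same modality group; donors must have the target variable observed.
#' Observed cells are never altered.
#'
#' @param data Subjects x variables matrix or data frame with missing cells.
#' @param k Number of neighbours (default 1).
#' @param groups Optional per-column group labels; distances and donors are
#'   restricted to columns/rows of the same group. Default: one group.
#' @return Completed matrix.
#' @export
knn_impute <- function(data, k = 1L, groups = NULL) {
  x <- as_numeric_matrix(data, "data")
  assert_that("k must be a positive count" = is_count(k))
  if (!anyNA(x)) return(x)
  groups <- groups %||% rep("all", ncol(x))
  assert_that("groups must label every column" = length(groups) == ncol(x))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    sub <- x[, cols, drop = FALSE]
    if (!anyNA(sub)) next
    obs <- !is.na(sub)
    if (any(rowSums(obs) == 0L)) {
      abort(sprintf("subject with all variables missing in group '%s'", g))
    }
    bad_col <- colSums(obs) == 0L
    if (any(bad_col)) {
      abort(sprintf("variable(s) with no observed values in group '%s'", g))
    }
    x0 <- sub
    x0[!obs] <- 0
    o <- matrix(as.numeric(obs), nrow(sub))
    sq <- x0^2
    # squared distance over jointly observed columns, via masked products
    d2 <- sq %*% t(o) + o %*% t(sq) - 2 * tcrossprod(x0)
    d2[d2 < 0] <- 0
    shared <- tcrossprod(o)
    d2[shared == 0] <- Inf
    diag(d2) <- Inf
    for (jj in which(colSums(!obs) > 0L)) {
      donors <- which(obs[, jj])
      for (i in which(!obs[, jj])) {
        ord <- donors[order(d2[i, donors], donors)]
        use <- head(ord, k)
        if (!length(use) || !is.finite(d2[i, use[1L]])) {
          abort("no donor shares observed variables with a missing row")
        }
        sub[i, jj] <- mean(sub[use, jj])
      }
    }
    x[, cols] <- sub
  }
  x
}

#' Fit a per-modality-group PCA retaining a variance target
#'
#' Variables are standardized (unit variance), the correlation-structure
#' eigendecomposition is taken, and the minimal number of leading
#' components whose cumulative explained variance reaches
#' `variance_target` is retained. Sign convention: in each component the
#' largest-magnitude loading is positive.
#'
#' @param data Complete subjects x variables matrix (residualized IDPs).
#' @param group Label for the modality group (recorded in the model).
#' @param variance_target Fraction of variance to reach, in (0, 1].
#' @return A `pca_model`: means, scalings, loading matrix, component count,
#'   cumulative explained variance.
#' @export
fit_pca_group <- function(data, group = "all", variance_target = 0.5) {
  x <- as_numeric_matrix(data, "data")
  assert_that(
    "variance_target must lie in (0, 1]" =
      is.numeric(variance_target) && variance_target > 0 &&
        variance_target <= 1,
    "PCA input must be complete; impute first" = !anyNA(x)
  )
  centers <- colMeans(x)
  scalings <- apply(x, 2L, sd)
  xs <- standardize(x, centers, scalings)
  sv <- svd(xs)
  ev <- sv$d^2
  explained <- cumsum(ev) / sum(ev)
  n_comp <- which(explained >= variance_target - 1e-12)[1L]
  if (is.na(n_comp) || n_comp > min(nrow(x) - 1L, ncol(x))) {
    abort("variance target needs more components than the data's rank")
  }
  rotation <- sv$v[, seq_len(n_comp), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (kk in seq_len(n_comp)) {
    peak <- which.max(abs(rotation[, kk]))
    if (rotation[peak, kk] < 0) rotation[, kk] <- -rotation[, kk]
  }
  dimnames(rotation) <- list(colnames(x),
                             sprintf("%s_pc%02d", group, seq_len(n_comp)))
  structure(
    list(
      group = group, centers = centers, scalings = scalings,
      rotation = rotation, n_comp = n_comp,
      explained = explained[n_comp], explained_curve = explained,
      variables = colnames(x)
    ),
    class = "pca_model"
  )
}

#' Project data onto a fitted PCA subspace
#'
#' Applies the stored means, scalings and loadings; the PCA is never refit,
#' so held-out samples are projected onto the training subspace.
#'
#' @param model A `pca_model` from [fit_pca_group()].
#' @param data Matrix with exactly the model's variables.
#' @return Component-score matrix (subjects x retained components).
#' @export
pca_project <- function(model, data) {
  stopifnot(inherits(model, "pca_model"))
  x <- as_numeric_matrix(data, "data")
  if (!is.null(colnames(x)) && !identical(colnames(x), model$variables)) {
    abort("variable set does not match the fitted PCA model")
  }
  assert_that("column count does not match the fitted model" =
                ncol(x) == length(model$centers))
  standardize(x, model$centers, model$scalings) %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %s> %d variables -> %d components (%.1f%% variance)\n",
              x$group, length(x$variables), x$n_comp, 100 * x$explained))
  invisible(x)
}

#' Serialize / restore a PCA model
#'
#' Stores means, scalings, loadings and metadata as JSON at full precision
#' so held-out projection is reproducible across runs.
#'
#' @param model A `pca_model`.
#' @param path File path.
#' @return `path` (write) or the restored `pca_model` (read).
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  payload <- list(
    group = model$group, centers = model$centers, scalings = model$scalings,
    rotation = model$rotation, n_comp = model$n_comp,
    explained = model$explained, explained_curve = model$explained_curve,
    variables = model$variables,
    rotation_dimnames = dimnames(model$rotation)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rotation <- matrix(unlist(p$rotation), ncol = p$n_comp)
  dimnames(rotation) <- p$rotation_dimnames
  structure(
    list(
      group = p$group,
      centers = setNames(as.numeric(p$centers), p$variables),
      scalings = setNames(as.numeric(p$scalings), p$variables),
      rotation = rotation, n_comp = as.integer(p$n_comp),
      explained = p$explained, explained_curve = p$explained_curve,
      variables = p$variables
    ),
    class = "pca_model"
  )
}
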