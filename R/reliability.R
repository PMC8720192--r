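#' ICC(A,1): two-way absolute-agreement single-measure intraclass
#' correlation
#'
#' From the two-way ANOVA decomposition with subjects as rows and the two
#' scan sessions as columns:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`.
#' Absolute agreement penalizes systematic between-session offsets, unlike
#' the consistency form.
#'
#' @param scan1,scan2 Paired measurements; incomplete pairs are dropped
#'   (>= 3 required).
#' @return ICC(A,1) as a single number in `[-1, 1]`.
#' @export
icc_a1 <- function(scan1, scan2) {
  keep <- complete.cases(scan1, scan2)
  x <- cbind(scan1[keep], scan2[keep])
  n <- nrow(x)
  assert_that("need at least 3 complete pairs" = n >= 3L)
  k <- 2L
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  if (sd(row_means) == 0) {
    abort("zero between-subject variance; ICC undefined")
  }
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' ICC(A,1) after regressing a covariate out of each timepoint
#'
#' The covariate (e.g., inter-scan interval in days, or the change in
#' RDS-4 between sessions) is removed from the chosen timepoint(s) by
#' simple linear regression before the ICC is computed. A constant
#' covariate leaves the values untouched (no-op, not an error).
#'
#' @inheritParams icc_a1
#' @param covariate Per-subject scalar, complete.
#' @param timepoints Which sessions to adjust: `"both"` (default),
#'   `"first"` or `"second"`.
#' @return Adjusted ICC(A,1).
#' @export
adjusted_icc <- function(scan1, scan2, covariate,
                         timepoints = c("both", "first", "second")) {
  timepoints <- match.arg(timepoints)
  assert_that("covariate must be complete" = !anyNA(covariate))
  strip <- function(y) {
    if (sd(covariate) == 0) return(y)
    keep <- !is.na(y)
    fit <- lm.fit(cbind(1, covariate[keep]), y[keep])
    y[keep] <- fit$residuals
    y
  }
  s1 <- if (timepoints %in% c("both", "first")) strip(scan1) else scan1
  s2 <- if (timepoints %in% c("both", "second")) strip(scan2) else scan2
  icc_a1(s1, s2)
}

#' ICC(A,1) within symptom-change subgroups
#'
#' Partitions subjects by whether their RDS-4 score changed between
#' sessions (`|delta| = 0` vs `>= 1`) and reports the ICC per subgroup. An
#' empty subgroup is omitted with a warning.
#'
#' @inheritParams icc_a1
#' @param rds_change Per-subject integer RDS-4 difference between
#'   timepoints (sign irrelevant).
#' @return Tibble: `subgroup` in `{stable, changed}`, `n`, `icc`.
#' @export
subgroup_icc <- function(scan1, scan2, rds_change) {
  assert_that("rds_change length must match" =
                length(rds_change) == length(scan1))
  stable <- abs(rds_change) == 0
  purrr::map_dfr(c(stable = TRUE, changed = FALSE), function(want) {
    idx <- which(stable == want & !is.na(stable))
    name <- if (want) "stable" else "changed"
    if (length(idx) < 3L) {
      warn(sprintf("subgroup '%s' has fewer than 3 subjects; omitted", name))
      return(NULL)
    }
    tibble::tibble(subgroup = name, n = length(idx),
                   icc = icc_a1(scan1[idx], scan2[idx]))
  })
}

#' Per-IDP test-retest reliability table
#'
#' Computes ICC(A,1) for every IDP between the two scan sessions, plus the
#' requested adjustment variants: interval-regressed ICC, symptom-change
#' subgroup ICCs, and symptom-change-regressed ICC.
#'
#' @param scan1,scan2 Subjects x IDPs matrices of deconfounded IDP values
#'   (aligned rows and columns).
#' @param modality Per-IDP modality tags.
#' @param interval Optional per-subject inter-scan interval (days).
#' @param rds_change Optional per-subject RDS-4 change between sessions.
#' @param adjust_timepoints Passed to [adjusted_icc()].
#' @return A `reliability_table` tibble: `idp`, `modality`, `icc`, and when
#'   the inputs are supplied `icc_interval_adj`, `icc_stable`,
#'   `icc_changed`, `icc_change_adj`.
#' @export
reliability_table <- function(scan1, scan2, modality, interval = NULL,
                              rds_change = NULL,
                              adjust_timepoints = "both") {
  scan1 <- as_numeric_matrix(scan1, "scan1")
  scan2 <- as_numeric_matrix(scan2, "scan2")
  assert_that(
    "scan matrices must have identical shape" =
      all(dim(scan1) == dim(scan2)),
    "modality must tag every IDP column" = length(modality) == ncol(scan1)
  )
  idp_names <- colnames(scan1) %||% sprintf("idp_%03d", seq_len(ncol(scan1)))
  sub <- if (!is.null(rds_change)) {
    stable <- abs(rds_change) == 0
  } else {
    NULL
  }
  rows <- purrr::map_dfr(seq_len(ncol(scan1)), function(j) {
    s1 <- scan1[, j]; s2 <- scan2[, j]
    row <- tibble::tibble(idp = idp_names[j], modality = modality[j],
                          icc = icc_a1(s1, s2))
    if (!is.null(interval)) {
      row$icc_interval_adj <- adjusted_icc(s1, s2, interval,
                                           adjust_timepoints)
    }
    if (!is.null(rds_change)) {
      both <- complete.cases(s1, s2)
      row$icc_stable <- if (sum(sub & both, na.rm = TRUE) >= 3L) {
        icc_a1(s1[which(sub)], s2[which(sub)])
      } else {
        NA_real_
      }
      row$icc_changed <- if (sum(!sub & both, na.rm = TRUE) >= 3L) {
        icc_a1(s1[which(!sub)], s2[which(!sub)])
      } else {
        NA_real_
      }
      row$icc_change_adj <- adjusted_icc(s1, s2, rds_change,
                                         adjust_timepoints)
    }
    row
  })
  class(rows) <- c("reliability_table", class(rows))
  rows
}

#' Per-modality summary of a reliability table
#'
#' @param table A `reliability_table`.
#' @param column Which ICC column to summarise (default `"icc"`).
#' @return Tibble: `modality`, `n`, `q1`, `median`, `q3`, `mean`.
#' @export
reliability_summary <- function(table, column = "icc") {
  assert_that("column not present in the reliability table" =
                column %in% names(table))
  dplyr::summarise(
    dplyr::group_by(table, .data$modality),
    n = dplyr::n(),
    q1 = quantile(.data[[column]], 0.25, na.rm = TRUE),
    median = median(.data[[column]], na.rm = TRUE),
    q3 = quantile(.data[[column]], 0.75, na.rm = TRUE),
    mean = mean(.data[[column]], na.rm = TRUE),
    .groups = "drop"
  )
}
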