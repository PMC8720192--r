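#' Cohen's d between two groups
#'
#' `(mean_1 - mean_0) / s_pooled` with the pooled standard deviation using
#' (n-1) weights. The grouping is the raw binary label (a residualized
#' binary variable would no longer be categorical); the values are
#' typically residualized IDPs.
#'
#' @param values Numeric vector (e.g., one residualized IDP).
#' @param group Binary group labels (0/1, logical, or two-level factor).
#' @return Cohen's d as a single number.
#' @export
cohen_d <- function(values, group) {
  if (is.factor(group)) group <- as.integer(group) - 1L
  group <- as.numeric(group)
  keep <- complete.cases(values, group)
  values <- values[keep]; group <- group[keep]
  assert_that(
    "group must be binary 0/1" = all(group %in% c(0, 1)),
    "both groups must have at least two members" =
      sum(group == 0) >= 2L && sum(group == 1) >= 2L
  )
  v0 <- values[group == 0]; v1 <- values[group == 1]
  sp2 <- ((length(v1) - 1) * var(v1) + (length(v0) - 1) * var(v0)) /
    (length(v1) + length(v0) - 2)
  if (sp2 <= 0) abort("zero pooled standard deviation; d undefined")
  (mean(v1) - mean(v0)) / sqrt(sp2)
}

#' Univariate effect sizes of selected IDPs in a held-out sample
#'
#' For every selected IDP (those flagged significant in the exploratory
#' averaged-UV loadings, or any user-supplied list), computes Cohen's d
#' against probable depression status and the Pearson correlation with each
#' continuous mental-health measure. Selection must come from the
#' exploratory sample and the effect sizes from the confirmatory sample;
#' computing both on the same subjects demonstrates selection-induced
#' optimism instead of a generalizable effect.
#'
#' @param idps Residualized confirmatory IDP matrix (subjects x IDPs).
#' @param scores Residualized continuous measures for the same subjects: a
#'   data frame with columns `rds4`, `phq9`, `gad7`, `n12`.
#' @param status Raw 0/1 probable depression status for the same subjects.
#' @param selection Character vector of IDP names, or a `loading_table`
#'   (its significant rows are used).
#' @param modality Optional per-IDP modality tags (named by IDP or aligned
#'   with `idps` columns).
#' @return An `effect_size_table` tibble: `idp`, `modality`, `cohen_d`,
#'   `r_rds4`, `r_phq9`, `r_gad7`, `r_n12`.
#' @export
effect_size_table <- function(idps, scores, status, selection,
                              modality = NULL) {
  idps <- as_numeric_matrix(idps, "idps")
  measures <- c("rds4", "phq9", "gad7", "n12")
  assert_that(
    "scores must contain rds4, phq9, gad7, n12" =
      all(measures %in% names(scores)),
    "status length must match the IDP rows" = length(status) == nrow(idps)
  )
  if (inherits(selection, "loading_table")) {
    selection <- selection$idp[selection$significant]
  }
  if (length(selection) == 0L) {
    return(structure(
      tibble::tibble(
        idp = character(), modality = character(), cohen_d = numeric(),
        r_rds4 = numeric(), r_phq9 = numeric(), r_gad7 = numeric(),
        r_n12 = numeric()
      ),
      class = c("effect_size_table", class(tibble::tibble()))
    ))
  }
  missing_sel <- setdiff(selection, colnames(idps))
  if (length(missing_sel)) {
    abort(paste0("selected IDP(s) absent from the confirmatory matrix: ",
                 paste(head(missing_sel, 5L), collapse = ", ")))
  }
  if (!is.null(modality) && is.null(names(modality))) {
    names(modality) <- colnames(idps)
  }
  rows <- purrr::map_dfr(selection, function(id) {
    v <- idps[, id]
    cors <- vapply(measures, function(mm) {
      cor(v, scores[[mm]], use = "complete.obs")
    }, numeric(1))
    tibble::tibble(
      idp = id,
      modality = if (is.null(modality)) NA_character_ else
        unname(modality[id]),
      cohen_d = cohen_d(v, status),
      r_rds4 = cors[["rds4"]], r_phq9 = cors[["phq9"]],
      r_gad7 = cors[["gad7"]], r_n12 = cors[["n12"]]
    )
  })
  class(rows) <- c("effect_size_table", class(rows))
  rows
}

#' Modality-grouped summary of effect sizes
#'
#' Box-plot style summaries (quartiles, mean, median, 1.5 IQR fences) of
#' absolute effect sizes per modality and measure.
#'
#' @param table An `effect_size_table`.
#' @return Tibble: `modality`, `measure`, `n`, `q1`, `median`, `q3`,
#'   `mean`, `fence_lo`, `fence_hi`.
#' @export
effect_size_summary <- function(table) {
  long <- tidyr::pivot_longer(
    table, cols = c("cohen_d", "r_rds4", "r_phq9", "r_gad7", "r_n12"),
    names_to = "measure", values_to = "effect"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$modality, .data$measure),
    n = dplyr::n(),
    q1 = quantile(abs(.data$effect), 0.25),
    median = median(abs(.data$effect)),
    q3 = quantile(abs(.data$effect), 0.75),
    mean = mean(abs(.data$effect)),
    fence_lo = pmax(0, .data$q1 - 1.5 * (.data$q3 - .data$q1)),
    fence_hi = .data$q3 + 1.5 * (.data$q3 - .data$q1),
    .groups = "drop"
  )
}
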