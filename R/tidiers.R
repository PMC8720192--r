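#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted CCA model
#'
#' One row per canonical mode with its correlation and, when permutation
#' inference has been run, the permutation p value.
#'
#' @param x A `cca_model`.
#' @param ... Unused.
#' @return Tibble: `mode`, `r`, `p_perm`.
#' @export
tidy.cca_model <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$r),
    r = x$r,
    p_perm = if (is.null(x$p_perm)) NA_real_ else x$p_perm
  )
}

#' Glance at a fitted CCA model
#'
#' @param x A `cca_model`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `p_x`, `q_y`, `n_modes`,
#'   `subjects_per_variable`, `r1`.
#' @export
glance.cca_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, p_x = x$p, q_y = x$q, n_modes = length(x$r),
    subjects_per_variable = x$n / (x$p + x$q), r1 = x$r[1]
  )
}

#' Tidy a fitted PCA model
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return Tibble with the retained components' cumulative explained
#'   variance.
#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(
    group = x$group,
    component = seq_len(x$n_comp),
    cumulative_variance = x$explained_curve[seq_len(x$n_comp)]
  )
}

#' Glance at a fitted PCA model
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return One-row tibble: `group`, `n_variables`, `n_components`,
#'   `explained`.
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    group = x$group, n_variables = length(x$variables),
    n_components = x$n_comp, explained = x$explained
  )
}
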