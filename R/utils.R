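#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor pt qnorm rnorm runif rlnorm rbinom sd var approx
#'   ks.test complete.cases quantile median lm.fit setNames pnorm rbeta
#' @importFrom utils head
NULL

# stop unless all conditions hold; `...` are named `condition = "message"` pairs
assert_that <- function(...) {
  conds <- list(...)
  msgs <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) abort(msgs[i], call = NULL)
  }
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

# column-standardize guarding zero-variance columns
standardize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2L, sd)
  if (any(scale <= 0 | !is.finite(scale))) {
    abort(paste0(
      "zero-variance column(s): ",
      paste(colnames(x)[scale <= 0 | !is.finite(scale)], collapse = ", ")
    ))
  }
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

as_numeric_matrix <- function(data, what = "data") {
  if (is.data.frame(data)) {
    data[] <- lapply(data, function(col) {
      if (is.logical(col)) as.numeric(col) else col
    })
    ok <- vapply(data, is.numeric, logical(1))
    if (!all(ok)) {
      abort(paste0(what, " contains non-numeric columns: ",
                   paste(names(data)[!ok], collapse = ", ")))
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data)) data <- matrix(data, ncol = 1L)
  storage.mode(data) <- "double"
  data
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
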