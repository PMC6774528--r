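#' @keywords internal
#' @import stats
"_PACKAGE"

# Shared internal helpers: design-matrix construction and input checks.

#' Build a design matrix with intercept from named data columns
#'
#' @param data data frame holding numeric covariate columns.
#' @param covariates character vector of column names (order preserved).
#' @return numeric matrix with a leading `(Intercept)` column.
#' @export
build_design <- function(data, covariates) {
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols) > 0L) {
    stop("covariates not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (is.logical(x)) x <- as.numeric(x)
    if (!is.numeric(x)) {
      stop("covariate '", v, "' is not numeric", call. = FALSE)
    }
    x
  })
  X <- cbind(1, do.call(cbind, c(list(), cols)))
  if (length(covariates) == 0L) X <- matrix(1, nrow = nrow(data), ncol = 1L)
  colnames(X) <- c("(Intercept)", covariates)
  X
}

# TRUE for a 0/1 (or logical) column -- used to pick the discrete-change
# convention for marginal effects.
is_binary_col <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single fraction in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop("'", name, "' must be a single ",
         if (strict) "positive" else "non-negative", " number", call. = FALSE)
  }
  invisible(x)
}

# Draw from a normal truncated to (lower, upper) by inverse-CDF. Adequate for
# the moderate truncation used by the survey generator (the probability mass
# retained is never vanishingly small there).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  q <- qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper)
}
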