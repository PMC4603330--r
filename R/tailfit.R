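#' Fit an exponential to the tail of a multiplicity distribution
#'
#' Fits `f(B) = a * exp(-c * B)` by unweighted ordinary least squares of
#' `ln f(B)` on `B` (the "log-linear" fit), over the multiplicities
#' `B >= B_min` with strictly positive counts. Zero counts are excluded from
#' the regression, never imputed. The returned decay rate `c = -slope` is the
#' signature statistic: a genome whose multiplicity tail decays slowly (small
#' c) carries more whole-genome-duplication signal than one with a fast
#' decaying tail (large c). The amplitude `a = exp(intercept)` is retained
#' but is much less stable across tail definitions than c, which is why only
#' c is used downstream.
#'
#' The solution is the closed-form normal-equation OLS; no iterative
#' optimisation is involved and results are exactly reproducible.
#'
#' @param dist a `multiplicity_distribution`, or a named numeric vector of
#'   counts (names are B values).
#' @param B_min smallest multiplicity included in the fit; the analysis sweep
#'   uses 2 (all B), 3 and 4.
#' @return object of class `wgd_tailfit` with elements `a`, `c`, `B_min`,
#'   `n_points`, `B` and `counts` (the points used) and `provenance`.
#'   If fewer than two positive-count multiplicities are available the fit is
#'   undefined and an error of class `wgdsig_fit_undefined` is signalled;
#'   panel code records such cells as missing.
#' @seealso [fit_all_cutoffs()] for the three-cutoff sweep.
#' @examples
#' fit <- fit_exponential_tail(c(`2` = 64, `3` = 16, `4` = 4, `5` = 1))
#' coef(fit)  # a = 1024, c = log(4): exactly geometric data
#' @export
fit_exponential_tail <- function(dist, B_min = 2L) {
  B_min <- as.integer(B_min)
  if (inherits(dist, "multiplicity_distribution")) {
    counts <- dist$counts
    provenance <- dist$provenance
  } else {
    counts <- dist
    provenance <- list()
  }
  b <- as.integer(names(counts))
  if (length(counts) > 0L && anyNA(b)) stop("counts must be named by integer B")
  keep <- !is.na(b) & b >= B_min & counts > 0
  b <- b[keep]
  y <- log(as.numeric(counts[keep]))
  n <- length(b)
  if (n < 2L) {
    stop(errorCondition(
      sprintf("fewer than 2 positive multiplicities with B >= %d; exponential fit undefined",
              B_min),
      class = c("wgdsig_fit_undefined", "error")))
  }
  sx <- sum(b); sy <- sum(y)
  sxx <- sum(b * b); sxy <- sum(b * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  structure(
    list(a = exp(intercept), c = -slope, B_min = B_min, n_points = n,
         B = b, counts = as.numeric(counts[keep]),
         provenance = c(provenance, list(B_min = B_min))),
    class = "wgd_tailfit"
  )
}

#' Fit the exponential tail at every cutoff of the standard sweep
#'
#' Applies [fit_exponential_tail()] at each tail cutoff (by default
#' `B >= 2`, `B >= 3` and `B >= 4`: the whole domain, the tail without B = 2,
#' and the strict tail). Cutoffs for which the fit is undefined (fewer than
#' two positive points) are recorded as `NULL`, not errors.
#'
#' @param dist a `multiplicity_distribution` or named count vector.
#' @param cutoffs integer vector of B_min values.
#' @return named list (names are cutoffs) of `wgd_tailfit` objects or `NULL`.
#' @export
fit_all_cutoffs <- function(dist, cutoffs = c(2L, 3L, 4L)) {
  fits <- lapply(cutoffs, function(bm) {
    tryCatch(fit_exponential_tail(dist, bm),
             wgdsig_fit_undefined = function(e) NULL)
  })
  names(fits) <- as.character(cutoffs)
  fits
}

#' @export
print.wgd_tailfit <- function(x, digits = 4L, ...) {
  cat(sprintf("Exponential tail fit f(B) = a * exp(-c B), B >= %d (%d points)\n",
              x$B_min, x$n_points))
  cat(sprintf("  a = %s, c = %s\n",
              format(x$a, digits = digits), format(x$c, digits = digits)))
  invisible(x)
}

#' @export
coef.wgd_tailfit <- function(object, ...) {
  c(a = object$a, c = object$c)
}

#' @export
summary.wgd_tailfit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object,
                 rss_log = sum(r^2),
                 provenance = object$provenance),
            class = "summary.wgd_tailfit")
}

#' @export
print.summary.wgd_tailfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sum of squares (log scale): %.6g\n", x$rss_log))
  if (length(x$provenance) > 0L) {
    cat("  provenance:", paste(names(x$provenance), unlist(x$provenance),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted counts from an exponential tail fit
#'
#' @param object a `wgd_tailfit`.
#' @param newdata multiplicities B at which to evaluate `a * exp(-c * B)`;
#'   either a numeric vector or a data.frame with a column `B`. Defaults to
#'   the multiplicities used in the fit.
#' @param ... unused.
#' @export
predict.wgd_tailfit <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$B
       else if (is.data.frame(newdata)) newdata$B
       else newdata
  object$a * exp(-object$c * b)
}

#' @export
fitted.wgd_tailfit <- function(object, ...) {
  predict(object)
}

#' Residuals of the log-linear fit (on the log scale it was fitted on)
#' @param object a `wgd_tailfit`.
#' @param ... unused.
#' @export
residuals.wgd_tailfit <- function(object, ...) {
  log(object$counts) - (log(object$a) - object$c * object$B)
}

#' @export
plot.wgd_tailfit <- function(x, ...) {
  graphics::plot(x$B, x$counts, log = "y", pch = 19,
                 xlab = "multiplicity B", ylab = "f(B)", ...)
  xs <- seq(min(x$B), max(x$B), length.out = 100L)
  graphics::lines(xs, x$a * exp(-x$c * xs))
  invisible(x)
}
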