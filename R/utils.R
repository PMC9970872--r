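#' Pooled-variance two-sided t-test p-value with degenerate-data conventions
#'
#' Equal-variance two-sample two-tailed test, the flavor used throughout the
#' package for differential activity, per-day tumor comparisons and expression
#' contrasts. Degenerate inputs follow fixed conventions rather than erroring:
#' fewer than 2 observations in either group gives `NA`; two constant groups
#' give p = 1 when their means agree and p = 0 when they differ (the latter is
#' flagged by [differential_profile()] and friends).
#'
#' @param x,y numeric vectors of observations for the two groups.
#' @return a single p-value in `[0, 1]`, or `NA`.
#' @keywords internal
ttest_p <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

# Vectorized pooled-variance two-sided t-test over the rows of two matrices
# (units x replicates). Same conventions as ttest_p(); used where hundreds of
# units are tested at once.
ttest_p_rows <- function(X, Y) {
  nx <- rowSums(is.finite(X))
  ny <- rowSums(is.finite(Y))
  mx <- rowMeans(X, na.rm = TRUE)
  my <- rowMeans(Y, na.rm = TRUE)
  vx <- apply(X, 1L, stats::var, na.rm = TRUE)
  vy <- apply(Y, 1L, stats::var, na.rm = TRUE)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  tstat <- (mx - my) / se
  p <- 2 * stats::pt(abs(tstat), df = nx + ny - 2, lower.tail = FALSE)
  degenerate <- is.finite(sp2) & sp2 == 0
  p[degenerate & abs(mx - my) < 1e-12] <- 1
  p[degenerate & abs(mx - my) >= 1e-12] <- 0
  p[nx < 2 | ny < 2] <- NA_real_
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kamdecon <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "kamdecon_error")))
}
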