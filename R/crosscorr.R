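#' Lagged cross-correlation between two annual series
#'
#' Correlation at lag k is the Pearson correlation of `(x[t+k], y[t])`
#' over the years where both are available, i.e. positive lags mean x
#' LEADS y by k years. This orientation is fixed and recorded in the
#' result and every output header, since lag-sign conventions differ
#' between software environments. Each lag uses its own
#' pairwise-complete overlap; a lag with fewer than 3 overlapping
#' years is reported as NA, never as zero.
#'
#' The accompanying threshold `1.96/sqrt(n_overlap)` (n at lag 0) is
#' the band a white-noise pair would exceed about 5% of the time by
#' chance. It is a descriptive reference, not a hypothesis test:
#' annual series interpolated by a state-space model violate the
#' independence this band assumes.
#'
#' @param x,y named numeric vectors (names = years), e.g.
#'   `fitted(ssm_fit)`, or data frames with `year` and a value column
#'   (`map` preferred, else `value`).
#' @param max_lag maximum |lag| scanned (default 10).
#' @return An object of class `ccf_annual`: data frame `lag, r, n`
#'   with attributes `threshold`, `series`, `peak`.
#' @examples
#' yrs <- 1961:2005
#' x <- stats::setNames(cumsum(rnorm(45)), yrs)
#' ccf_annual(x, x)[["r"]][11]  # lag 0 autocorrelation = 1
#' @export
ccf_annual <- function(x, y, max_lag = 10) {
  x <- as_year_vector(x); y <- as_year_vector(y)
  lags <- seq.int(-max_lag, max_lag)
  r <- n <- rep(NA_real_, length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    t_y <- as.integer(names(y))
    xv <- x[as.character(t_y + k)]
    ok <- !is.na(xv) & !is.na(y)
    n[j] <- sum(ok)
    if (n[j] >= 3 && stats::sd(xv[ok]) > 0 && stats::sd(y[ok]) > 0)
      r[j] <- stats::cor(xv[ok], y[ok])
  }
  n0 <- n[lags == 0]
  if (is.na(n0) || n0 < 3)
    stop("fewer than 3 overlapping years at lag 0")
  out <- data.frame(lag = lags, r = r, n = n)
  peak_i <- which.max(abs(out$r))
  structure(out,
            threshold = 1.96 / sqrt(n0),
            series = c(x = attr(x, "series_name") %||% "x",
                       y = attr(y, "series_name") %||% "y"),
            orientation = "r(k) = cor(x[t+k], y[t]); positive lag: x leads y",
            peak = c(lag = out$lag[peak_i], r = out$r[peak_i]),
            class = c("ccf_annual", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_year_vector <- function(v) {
  if (is.data.frame(v)) {
    col <- if ("map" %in% names(v)) "map" else "value"
    if (!all(c("year", col) %in% names(v)))
      stop("data frame series needs 'year' and 'map' or 'value'")
    out <- stats::setNames(as.numeric(v[[col]]), v$year)
    return(out)
  }
  if (is.null(names(v))) stop("vector series must be named by year")
  stats::setNames(as.numeric(v), names(v))
}

#' @export
print.ccf_annual <- function(x, ...) {
  s <- attr(x, "series")
  cat(sprintf("Cross-correlation %s ~ %s  [%s]\n", s["x"], s["y"],
              attr(x, "orientation")))
  cat(sprintf("white-noise band: +/- %.3f (n = %d at lag 0)\n",
              attr(x, "threshold"), x$n[x$lag == 0]))
  pk <- attr(x, "peak")
  cat(sprintf("peak: r = %.3f at lag %d\n", pk["r"], pk["lag"]))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
plot.ccf_annual <- function(x, ...) {
  graphics::plot(x$lag, x$r, type = "h", ylim = c(-1, 1),
                 xlab = "lag (years; positive = x leads y)",
                 ylab = "cross-correlation", ...)
  graphics::abline(h = 0)
  graphics::abline(h = c(-1, 1) * attr(x, "threshold"),
                   lty = 2, col = "blue")
  invisible(x)
}

#' Squared cross-correlation at a given lag
#'
#' @param ccf_result a [ccf_annual()] result.
#' @param lag the lag of interest (must be inside the scanned window
#'   and not missing).
#' @return `r^2` at that lag.
#' @export
lagged_r2 <- function(ccf_result, lag) {
  stopifnot(inherits(ccf_result, "ccf_annual"))
  i <- match(lag, ccf_result$lag)
  if (is.na(i)) stop("lag ", lag, " not in the scanned window")
  if (is.na(ccf_result$r[i])) stop("lag ", lag, " has no estimate")
  ccf_result$r[i]^2
}

#' Pearson product-moment correlation with validation
#'
#' Plain Pearson correlation for station-level pairings (e.g. FCL
#' against zooplankton biovolume, protist residuals against FCL),
#' refusing degenerate inputs instead of returning NA.
#'
#' @param x,y numeric vectors of equal length; pairs with any NA are
#'   dropped.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Write a cross-correlation result to CSV plus JSON sidecar
#'
#' @param ccf_result a [ccf_annual()] result.
#' @param path output CSV (`lag,r,n`); the sidecar `<path>.json`
#'   holds the threshold, the orientation note and the peak.
#' @return `path`, invisibly.
#' @export
write_ccf <- function(ccf_result, path) {
  stopifnot(inherits(ccf_result, "ccf_annual"))
  con <- file(path, "w")
  writeLines(paste0("# ", attr(ccf_result, "orientation")), con)
  utils::write.csv(as.data.frame(ccf_result), con, row.names = FALSE)
  close(con)
  pk <- attr(ccf_result, "peak")
  jsonlite::write_json(
    list(series = as.list(attr(ccf_result, "series")),
         orientation = attr(ccf_result, "orientation"),
         threshold = attr(ccf_result, "threshold"),
         peak = list(lag = pk[["lag"]], r = pk[["r"]])),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
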