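#' Read a year-by-taxon community abundance matrix from CSV
#'
#' First column `year`, remaining columns taxon abundances
#' (individuals per square metre, nonnegative).
#'
#' @param path CSV path.
#' @return Numeric matrix, rows named by year (strictly increasing),
#'   columns by taxon.
#' @export
read_community <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "year") stop("first column must be 'year'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$year
  validate_community(m)
}

validate_community <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("negative abundances")
  yrs <- as.integer(rownames(m))
  if (anyNA(yrs) || any(diff(yrs) <= 0))
    stop("row names must be strictly increasing years")
  m
}

#' Log-transform an abundance matrix
#'
#' Elementwise `ln(a + offset)`; the default offset of 1 keeps zero
#' abundances defined (ln(1) = 0) and is the conventional choice for
#' count-like plankton data.
#'
#' @param m nonnegative abundance matrix.
#' @param offset added before the log (default 1).
#' @return Transformed matrix.
#' @export
log_abundance <- function(m, offset = 1) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("negative abundances")
  log(m + offset)
}

#' Bray-Curtis dissimilarity between years
#'
#' `d(i,j) = sum|a_ik - a_jk| / sum(a_ik + a_jk)` over taxa, in
#' [0, 1], computed with `vegan::vegdist`. A pair of all-zero rows has
#' an undefined quotient; it is defined as 0 (identical communities)
#' with a warning.
#'
#' @param m year-by-taxon matrix (typically [log_abundance()]
#'   output).
#' @return Symmetric dissimilarity matrix with zero diagonal, dimnames
#'   from the rows of `m`.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 years")
  if (any(m < 0)) stop("negative abundances")
  zero <- rowSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (sum(zero) >= 2) {
    warning("all-zero year pair(s): dissimilarity defined as 0")
    d[zero, zero] <- 0
  }
  diag(d) <- 0
  d
}

cluster_dispersion <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
}

#' Chronologically constrained clustering of a community time series
#'
#' Agglomerative clustering in which only temporally adjacent clusters
#' may merge, with an incremental sum-of-squares criterion computed
#' from squared dissimilarities (the stratigraphically constrained
#' CONISS approach): a cluster's dispersion is
#' `sum of squared within-cluster dissimilarities / cluster size`, and
#' each step performs the adjacent merge with the smallest dispersion
#' increase. The full merge profile is returned so the analyst can
#' judge where the deep breaks fall; a largest-increment suggestion is
#' offered but the zone count is deliberately left to the user.
#'
#' @param d square symmetric dissimilarity matrix (e.g.
#'   [bray_curtis()]).
#' @param years the years labelling rows of `d`; defaults to its
#'   dimnames.
#' @return Object of class `chron_zonation`: per-merge `increment`
#'   and cumulative `height`, the `boundary_removed` (first year of
#'   the right-hand block) at each merge, and `suggested_n_zones`
#'   from the largest merge increment. Use [zones()] to extract a
#'   zonation at any zone count.
#' @export
chronological_cluster <- function(d, years = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("'d' must be square and symmetric")
  if (is.null(years)) years <- as.integer(rownames(d))
  if (length(years) != n || anyNA(years))
    stop("'years' must label every row of 'd'")
  d2 <- d^2
  blocks <- as.list(seq_len(n))
  disp <- numeric(n)
  increment <- height <- numeric(n - 1)
  boundary_removed <- integer(n - 1)
  total <- 0
  for (step in seq_len(n - 1)) {
    nb <- length(blocks)
    cost <- vapply(seq_len(nb - 1), function(j) {
      cluster_dispersion(d2, c(blocks[[j]], blocks[[j + 1]])) -
        disp[j] - disp[j + 1]
    }, numeric(1))
    j <- which.min(cost)
    boundary_removed[step] <- years[blocks[[j + 1]][1]]
    merged <- c(blocks[[j]], blocks[[j + 1]])
    new_disp <- cluster_dispersion(d2, merged)
    blocks[[j]] <- merged
    blocks[[j + 1]] <- NULL
    disp <- c(disp[seq_len(j - 1)], new_disp,
              if (j + 2 <= nb) disp[seq.int(j + 2, nb)])
    total <- total + cost[j]
    increment[step] <- cost[j]
    height[step] <- total
  }
  structure(list(years = years, increment = increment, height = height,
                 boundary_removed = boundary_removed,
                 suggested_n_zones = n - which.max(increment) + 1L),
            class = "chron_zonation")
}

#' Extract a zonation at a given number of zones
#'
#' Zones are contiguous blocks of years obtained by undoing the last
#' `n_zones - 1` merges of a [chronological_cluster()] result.
#'
#' @param x a `chron_zonation`.
#' @param n_zones number of zones in `[1, n_years]`.
#' @return Integer vector of zone memberships named by year, with
#'   attribute `boundaries`: the first year of each zone after the
#'   first.
#' @export
zones <- function(x, n_zones) {
  stopifnot(inherits(x, "chron_zonation"))
  n <- length(x$years)
  if (n_zones < 1 || n_zones > n)
    stop("'n_zones' must be in [1, ", n, "]")
  # boundaries still standing = those removed in the last n_zones-1 merges
  keep <- if (n_zones > 1)
    sort(x$boundary_removed[seq.int(n - n_zones + 1, n - 1)])
  else integer(0)
  z <- cumsum(x$years %in% keep) + 1L
  structure(stats::setNames(z, x$years), boundaries = keep)
}

#' @export
print.chron_zonation <- function(x, ...) {
  n <- length(x$years)
  cat(sprintf("Chronologically constrained clustering of %d years (%d-%d)\n",
              n, min(x$years), max(x$years)))
  cat(sprintf("total dispersion %.4f; largest merge increment %.4f at step %d\n",
              x$height[n - 1], max(x$increment), which.max(x$increment)))
  cat(sprintf("suggested zone count (largest-increment heuristic): %d\n",
              x$suggested_n_zones))
  bnd <- attr(zones(x, x$suggested_n_zones), "boundaries")
  if (length(bnd))
    cat("suggested break year(s):", paste(bnd, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.chron_zonation <- function(x, ...) {
  graphics::plot(seq_along(x$height), x$height, type = "s",
                 xlab = "merge step", ylab = "total dispersion", ...)
  invisible(x)
}

#' Z-score a series
#'
#' `(v - mean)/SD` over the full series, with the sample (n-1) SD.
#'
#' @param values numeric vector (>= 2 non-missing values, nonzero SD);
#'   NAs are preserved in place.
#' @return Z-scored vector (mean 0, SD 1 over the non-missing values).
#' @export
zscore_series <- function(values) {
  v <- as.numeric(values)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need at least 2 values")
  s <- stats::sd(v[ok])
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  out <- (v - mean(v[ok])) / s
  names(out) <- names(values)
  out
}

#' Aggregate taxon columns of a community matrix
#'
#' Utility for groupings such as "small copepods" (sum of all taxa
#' tagged small) versus a single large taxon.
#'
#' @param m year-by-taxon matrix.
#' @param taxa column names to sum.
#' @return Named numeric vector (year -> summed abundance).
#' @export
aggregate_taxa <- function(m, taxa) {
  m <- as.matrix(m)
  miss <- setdiff(taxa, colnames(m))
  if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
  rowSums(m[, taxa, drop = FALSE])
}
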