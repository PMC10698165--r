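#' Yearly large:small larval size-ratio series from length-class counts
#'
#' Pools counts over stations within each year and returns, per year,
#' the ratio of larvae in the large bin to larvae in the small bin.
#' Length classes are taken from the column names (mm); bins are
#' half-open `[lower, upper)`, so a 10 mm larva counts as large and a
#' 20 mm larva falls outside the default large bin — this avoids
#' double-counting at shared edges. Years whose small-larva count is
#' zero become missing (with a warning), never infinite.
#'
#' @param counts data frame with a `year` column, optionally a
#'   `station` column, and one column per length class named by its
#'   length in mm (e.g. `"6"`, `"9.5"`, `"15"`); nonnegative counts.
#' @param small,large `c(lower, upper)` bin bounds in mm; default
#'   `[5, 10)` and `[10, 20)`. The bins must not overlap.
#' @return An [annual_series()] named `"size_ratio"`, missing years
#'   dropped.
#' @examples
#' counts <- data.frame(year = 1990, `6` = 4, `9.5` = 6, `10` = 5,
#'                      `19` = 5, `20` = 7, check.names = FALSE)
#' size_ratio_series(counts)  # (5+5)/(4+6) = 1
#' @export
size_ratio_series <- function(counts, small = c(5, 10),
                              large = c(10, 20)) {
  stopifnot(length(small) == 2, length(large) == 2)
  if (small[1] >= small[2] || large[1] >= large[2])
    stop("ill-formed bin (lower must be < upper)")
  if (small[1] < large[2] && large[1] < small[2])
    stop("overlapping size bins")
  if (!"year" %in% names(counts)) stop("'counts' needs a 'year' column")
  len_cols <- setdiff(names(counts), c("year", "station"))
  mm <- suppressWarnings(as.numeric(len_cols))
  if (anyNA(mm))
    stop("length-class columns must be named by their length in mm: ",
         paste(len_cols[is.na(mm)], collapse = ", "))
  cmat <- as.matrix(counts[len_cols])
  if (any(cmat < 0, na.rm = TRUE)) stop("negative counts")
  in_bin <- function(b) mm >= b[1] & mm < b[2]
  tot <- function(b) {
    v <- rowSums(cmat[, in_bin(b), drop = FALSE], na.rm = TRUE)
    as.numeric(rowsum(v, counts$year))
  }
  yrs <- sort(unique(counts$year))
  n_small <- tot(small); n_large <- tot(large)
  zero <- n_small == 0
  if (any(zero))
    warning("zero small-larva count: year(s) ",
            paste(yrs[zero], collapse = ", "), " set to missing")
  annual_series(yrs[!zero], n_large[!zero] / n_small[!zero],
                name = "size_ratio",
                year_range = range(yrs))
}

#' Per-period means of an annual series and the contrast between them
#'
#' @param series named vector (year -> value) or a data frame with
#'   `year` and `map`/`value` (e.g. an SSM posterior summary).
#' @param periods named list of year vectors; must not overlap.
#' @return A list with `means` (per-period arithmetic means) and,
#'   when there are at least two periods, `percent_difference`:
#'   `(first - second)/second * 100`.
#' @examples
#' s <- stats::setNames(c(4, 6, 3, 3), 2001:2004)
#' period_summary(s, list(early = 2001:2002, late = 2003:2004))
#' @export
period_summary <- function(series, periods) {
  v <- as_year_vector(series)
  if (is.null(names(periods)) || !all(nzchar(names(periods))))
    stop("'periods' must be a named list")
  all_years <- unlist(periods)
  if (anyDuplicated(all_years)) stop("periods overlap")
  means <- vapply(periods, function(yrs) {
    x <- v[as.character(yrs)]
    x <- x[!is.na(x)]
    if (!length(x)) stop("empty period (no series years inside)")
    mean(x)
  }, numeric(1))
  out <- list(means = means)
  if (length(means) >= 2)
    out$percent_difference <-
      unname((means[1] - means[2]) / means[2] * 100)
  out
}

resolve_input <- function(x, reader) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("input file not found: ", x)
    reader(x)
  } else x
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis graph: per-specimen trophic metrics ->
#' annual series construction (FCL, energy-transfer efficiency,
#' larval size ratio, any extra series) -> one state-space fit per
#' series -> lagged cross-correlations between MAP series ->
#' community zonation -> boom/bust period contrasts. All artifacts
#' are written under `outdir` together with a manifest (input MD5
#' hashes, seed, package version, output list); runs are
#' deterministic given the seed.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{specimens}{specimen CSV path or `aa_profiles` data frame}
#'     \item{larval_counts}{optional length-class count CSV/data frame}
#'     \item{series}{optional named list of extra `year,value` CSVs or
#'       data frames (e.g. `ssb`, `zooplankton`)}
#'     \item{community}{optional community CSV path or matrix}
#'     \item{calibration}{optional [calib_constants()] argument list}
#'     \item{sl_range}{optional inclusive specimen length filter, mm}
#'     \item{complete_only}{drop partial-AA specimens (default FALSE)}
#'     \item{ssm}{optional [ssm_config()] argument list; `log_scale`
#'       may be a named logical vector per series}
#'     \item{ccf_pairs}{list of `list(x =, y =, max_lag =)` referring
#'       to fitted series names (`fcl`, `transfer_efficiency`,
#'       `size_ratio`, plus any extra series)}
#'     \item{periods}{named list of year vectors (e.g. boom/bust)}
#'     \item{period_series}{series summarised over periods
#'       (default `transfer_efficiency`)}
#'     \item{outdir}{output directory}
#'     \item{seed}{master seed}
#'   }
#' @return A list of class `fclssm_pipeline` with the per-stage
#'   results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% stop("config needs 'outdir'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  calib <- pipeline_stage("calibration", {
    if (is.null(config$calibration)) calib_constants()
    else if (inherits(config$calibration, "fcl_calibration"))
      config$calibration
    else do.call(calib_constants, config$calibration)
  })
  inputs <- list()
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  # --- specimen metrics ---------------------------------------------
  metrics <- NULL
  annual <- list()
  if (!is.null(config$specimens)) {
    if (is.character(config$specimens))
      inputs$specimens <- config$specimens
    metrics <- pipeline_stage("isotope_metrics", {
      prof <- resolve_input(config$specimens, read_aa_profiles)
      suppressWarnings(
        fcl_table(prof, calib, sl_range = config$sl_range,
                  complete_only = isTRUE(config$complete_only)))
    })
    f <- file.path(outdir, "fcl_table.csv")
    utils::write.csv(metrics, f, row.names = FALSE); emit(f)
    ok <- !is.na(metrics$fcl_trp_scr)
    annual$fcl <- annual_series(metrics$year[ok], metrics$fcl_trp_scr[ok],
                                name = "fcl")
    ok2 <- !is.na(metrics$transfer_efficiency)
    annual$transfer_efficiency <-
      annual_series(metrics$year[ok2], metrics$transfer_efficiency[ok2],
                    name = "transfer_efficiency")
  }
  if (!is.null(config$larval_counts)) {
    if (is.character(config$larval_counts))
      inputs$larval_counts <- config$larval_counts
    annual$size_ratio <- pipeline_stage("size_ratio", {
      counts <- resolve_input(config$larval_counts,
                              function(p) utils::read.csv(p,
                                check.names = FALSE))
      suppressWarnings(size_ratio_series(counts))
    })
  }
  for (nm in names(config$series)) {
    if (is.character(config$series[[nm]]))
      inputs[[nm]] <- config$series[[nm]]
    annual[[nm]] <- pipeline_stage(paste0("series_", nm), {
      s <- resolve_input(config$series[[nm]], read_annual_series)
      annual_series(s$year, s$value, replicate_id = s$replicate_id,
                    name = nm)
    })
  }
  if (!length(annual)) stop("pipeline has no input series")

  # --- state-space fits ---------------------------------------------
  ssm_args <- config$ssm %||% list()
  log_flags <- ssm_args$log_scale
  ssm_args$log_scale <- NULL
  fits <- list()
  for (i in seq_along(annual)) {
    nm <- names(annual)[i]
    fits[[nm]] <- pipeline_stage(paste0("ssm_", nm), {
      args <- ssm_args
      args$log_scale <-
        if (is.null(names(log_flags))) isTRUE(log_flags[1])
        else isTRUE(unname(log_flags[nm]))
      args$seed <- seed + i
      fit <- suppressWarnings(
        fit_ssm(annual[[nm]], do.call(ssm_config, args)))
      f <- file.path(outdir, paste0("ssm_", nm, ".csv"))
      write_ssm_summary(fit, f); emit(f); emit(paste0(f, ".json"))
      fit
    })
  }

  # --- cross-correlations -------------------------------------------
  ccfs <- list()
  for (pair in config$ccf_pairs) {
    key <- paste0(pair$x, "~", pair$y)
    ccfs[[key]] <- pipeline_stage(paste0("ccf_", key), {
      for (nm in c(pair$x, pair$y))
        if (is.null(fits[[nm]]))
          stop("no fitted series named '", nm, "'")
      cc <- ccf_annual(fitted(fits[[pair$x]]), fitted(fits[[pair$y]]),
                       max_lag = pair$max_lag %||% 10)
      f <- file.path(outdir, paste0("ccf_", pair$x, "_", pair$y, ".csv"))
      write_ccf(cc, f); emit(f); emit(paste0(f, ".json"))
      cc
    })
  }

  # --- community zonation -------------------------------------------
  zonation <- NULL
  if (!is.null(config$community)) {
    if (is.character(config$community))
      inputs$community <- config$community
    zonation <- pipeline_stage("community", {
      m <- validate_community(resolve_input(config$community,
                                            read_community))
      cl <- chronological_cluster(bray_curtis(log_abundance(m)))
      f <- file.path(outdir, "merge_heights.csv")
      utils::write.csv(data.frame(step = seq_along(cl$height),
                                  increment = cl$increment,
                                  height = cl$height,
                                  boundary_removed = cl$boundary_removed),
                       f, row.names = FALSE); emit(f)
      zb <- attr(zones(cl, cl$suggested_n_zones), "boundaries")
      jf <- file.path(outdir, "zonation.json")
      jsonlite::write_json(list(suggested_n_zones = cl$suggested_n_zones,
                                boundaries = zb),
                           jf, auto_unbox = TRUE, digits = NA); emit(jf)
      zf <- file.path(outdir, "community_zscores.csv")
      utils::write.csv(data.frame(year = rownames(m),
                                  apply(m, 2, zscore_series),
                                  check.names = FALSE),
                       zf, row.names = FALSE); emit(zf)
      cl
    })
  }

  # --- period contrasts ---------------------------------------------
  period <- NULL
  if (!is.null(config$periods)) {
    period <- pipeline_stage("periods", {
      nm <- config$period_series %||% "transfer_efficiency"
      if (is.null(fits[[nm]])) stop("no fitted series named '", nm, "'")
      period_summary(fits[[nm]]$map, config$periods)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fclssm")),
    seed = seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = basename(outputs),
    series_fitted = names(fits),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(metrics = metrics, annual = annual, fits = fits,
                 ccf = ccfs, zonation = zonation, period = period,
                 manifest = manifest, outdir = outdir),
            class = "fclssm_pipeline")
}

#' @export
print.fclssm_pipeline <- function(x, ...) {
  cat("fclssm pipeline run ->", x$outdir, "\n")
  cat("  series fitted:", paste(names(x$fits), collapse = ", "), "\n")
  if (length(x$ccf))
    for (k in names(x$ccf)) {
      pk <- attr(x$ccf[[k]], "peak")
      cat(sprintf("  ccf %s: peak r = %.3f at lag %d (band +/- %.3f)\n",
                  k, pk["r"], pk["lag"], attr(x$ccf[[k]], "threshold")))
    }
  if (!is.null(x$zonation))
    cat("  community break suggestion:",
        paste(attr(zones(x$zonation, x$zonation$suggested_n_zones),
                   "boundaries"), collapse = ", "), "\n")
  if (!is.null(x$period)) {
    cat(sprintf("  period means: %s\n",
                paste(names(x$period$means),
                      signif(x$period$means, 4), sep = "=",
                      collapse = ", ")))
    if (!is.null(x$period$percent_difference))
      cat(sprintf("  first vs second period: %+.1f%%\n",
                  x$period$percent_difference))
  }
  invisible(x)
}
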