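TROPHIC_AAS <- c("Glu", "Ala", "Pro")
SOURCE_AAS <- c("Phe", "Gly")

#' Read per-specimen amino-acid d15N profiles from CSV
#'
#' Expects the header
#' `specimen_id,year,station,sl_mm,d15n_glu,d15n_ala,d15n_pro,d15n_phe,d15n_gly,d15n_bulk`;
#' empty cells are missing values. Extra columns are kept, missing
#' optional columns (`station`, `sl_mm`, `d15n_bulk`) are filled with NA.
#'
#' @param path path to the specimen CSV.
#' @return A data frame with one row per specimen, of class
#'   `aa_profiles`.
#' @export
read_aa_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  as_aa_profiles(df)
}

#' Validate a data frame of amino-acid profiles
#'
#' @param df data frame with at least `specimen_id`, `year` and one
#'   `d15n_<aa>` column per measured amino acid (glu, ala, pro, phe,
#'   gly, all permil vs air N2).
#' @return The validated data frame, classed `aa_profiles`.
#' @export
as_aa_profiles <- function(df) {
  req <- c("specimen_id", "year")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("profile table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("station", "sl_mm", "d15n_bulk"))
    if (is.null(df[[col]])) df[[col]] <- NA
  aa_cols <- paste0("d15n_", tolower(c(TROPHIC_AAS, SOURCE_AAS)))
  present <- intersect(aa_cols, names(df))
  if (!length(present))
    stop("profile table has no d15n_<aa> columns")
  for (col in setdiff(aa_cols, present)) df[[col]] <- NA_real_
  if (anyDuplicated(df$specimen_id))
    stop("duplicated specimen_id values")
  inf <- vapply(aa_cols, function(col) any(is.infinite(df[[col]])), logical(1))
  if (any(inf))
    stop("non-finite d15N values in: ", paste(aa_cols[inf], collapse = ", "))
  class(df) <- c("aa_profiles", "data.frame")
  df
}

aa_column <- function(aa) paste0("d15n_", tolower(aa))

#' Food chain length from the canonical Glu-Phe amino-acid pair
#'
#' Computes `FCL = (d15N_Glu - d15N_Phe - beta)/TDF + 1` with the
#' Glu-Phe calibration constants. Values below 1 are returned unclamped
#' (with a warning) since negative trophic steps flag data problems the
#' analyst must see.
#'
#' @param d15n_glu,d15n_phe glutamic acid and phenylalanine d15N
#'   (permil vs air N2); vectors are recycled to common length.
#' @param calib an [calib_constants()] object holding a `"Glu-Phe"`
#'   beta and TDF.
#' @param specimen_id optional ids used in error and warning messages.
#' @return Numeric vector of trophic levels; NA where either input is
#'   missing was requested via `na_ok`.
#' @param na_ok if `FALSE` (default), a missing amino acid raises an
#'   "insufficient amino acids" error; if `TRUE`, it yields NA.
#' @examples
#' calib <- calib_constants()
#' fcl_glu_phe(25.0, 8.0, calib)  # (25 - 8 - 3.6)/5.7 + 1
#' @export
fcl_glu_phe <- function(d15n_glu, d15n_phe, calib = calib_constants(),
                        specimen_id = NULL, na_ok = FALSE) {
  stopifnot(inherits(calib, "fcl_calibration"))
  if (!"Glu-Phe" %in% names(calib$beta))
    stop("calibration lacks a Glu-Phe beta/TDF")
  n <- max(length(d15n_glu), length(d15n_phe))
  d15n_glu <- rep_len(as.numeric(d15n_glu), n)
  d15n_phe <- rep_len(as.numeric(d15n_phe), n)
  ids <- if (is.null(specimen_id)) as.character(seq_len(n))
         else rep_len(as.character(specimen_id), n)
  bad <- !is.finite(d15n_glu) | !is.finite(d15n_phe)
  if (any(bad) && !na_ok)
    stop("insufficient amino acids (Glu or Phe missing) for specimen(s): ",
         paste(ids[bad], collapse = ", "))
  fcl <- (d15n_glu - d15n_phe - calib$beta[["Glu-Phe"]]) /
    calib$tdf[["Glu-Phe"]] + 1
  fcl[bad] <- NA_real_
  low <- !is.na(fcl) & fcl < 1 - 1e-9
  if (any(low))
    warning("FCL below 1 (negative trophic steps) for specimen(s): ",
            paste(ids[low], collapse = ", "))
  fcl
}

#' Inverse-variance weighted mean of amino-acid d15N values
#'
#' \deqn{\bar{x}_W = \sum(x/\sigma_x^2) / \sum(1/\sigma_x^2)}
#' where the weights are the per-AA procedural reproducibility SDs.
#'
#' @param values named numeric vector, AA name -> d15N (permil).
#' @param sds named numeric vector of SDs covering every name in
#'   `values`; defaults to the procedural SDs of [calib_constants()].
#' @return The weighted mean (permil).
#' @examples
#' weighted_mean_d15n(c(Glu = 20, Ala = 22, Pro = 21))
#' @export
weighted_mean_d15n <- function(values,
                               sds = calib_constants()$procedural_sd) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no amino-acid values supplied")
  if (is.null(names(values)) || !all(nzchar(names(values))))
    stop("'values' must be named by amino acid")
  miss <- setdiff(names(values), names(sds))
  if (length(miss))
    stop("no SD supplied for: ", paste(miss, collapse = ", "))
  s <- sds[names(values)]
  if (any(!is.finite(s)) || any(s <= 0))
    stop("all SDs must be finite and > 0")
  w <- 1 / s^2
  sum(values * w) / sum(w)
}

#' Multi-amino-acid food chain length (weighted-mean estimator)
#'
#' The robust FCL variant: d15N_Trp is the inverse-variance weighted
#' mean over the trophic AAs (Glu, Ala, Pro) and d15N_Scr over the
#' source AAs (Phe, Gly), weighted by the procedural SDs; beta and TDF
#' are replaced by `1/SD^2`-weighted means of the per-pairing
#' calibration constants over the pairings both of whose AAs are
#' measured. When an AA is absent, weights renormalise over the AAs
#' present and the estimate is flagged `"partial"` (see the
#' `"partial"` attribute of the result).
#'
#' @param profiles an `aa_profiles` data frame (or anything
#'   [as_aa_profiles()] accepts).
#' @param calib an [calib_constants()] object.
#' @return Numeric vector of trophic levels, one per row, with
#'   attribute `partial` (logical: fewer than all five AAs used).
#'   Values below 1 are returned with a warning, never clamped.
#' @examples
#' prof <- data.frame(specimen_id = "a", year = 1990,
#'                    d15n_glu = 18.3, d15n_ala = 19.1, d15n_pro = 17.8,
#'                    d15n_phe = 6.5, d15n_gly = 5.9)
#' fcl_trp_scr(prof)
#' @export
fcl_trp_scr <- function(profiles, calib = calib_constants()) {
  profiles <- as_aa_profiles(as.data.frame(profiles))
  stopifnot(inherits(calib, "fcl_calibration"))
  n <- nrow(profiles)
  fcl <- rep(NA_real_, n)
  partial <- rep(FALSE, n)
  for (i in seq_len(n)) {
    vals <- vapply(c(TROPHIC_AAS, SOURCE_AAS),
                   function(aa) as.numeric(profiles[[aa_column(aa)]][i]),
                   numeric(1))
    trp <- vals[TROPHIC_AAS][!is.na(vals[TROPHIC_AAS])]
    scr <- vals[SOURCE_AAS][!is.na(vals[SOURCE_AAS])]
    if (!length(trp) || !length(scr))
      stop("insufficient amino acids (need >=1 trophic and >=1 source) ",
           "for specimen ", profiles$specimen_id[i])
    pairs <- as.vector(outer(names(trp), names(scr), paste, sep = "-"))
    pairs <- intersect(pairs, names(calib$beta))
    if (!length(pairs))
      stop("calibration lacks constants for the AAs of specimen ",
           profiles$specimen_id[i])
    beta_bar <- weighted_constant(calib$beta, calib$beta_sd, pairs)
    tdf_bar <- weighted_constant(calib$tdf, calib$tdf_sd, pairs)
    d_trp <- weighted_mean_d15n(trp, calib$procedural_sd)
    d_scr <- weighted_mean_d15n(scr, calib$procedural_sd)
    fcl[i] <- (d_trp - d_scr - beta_bar) / tdf_bar + 1
    partial[i] <- length(trp) + length(scr) < 5L
  }
  low <- !is.na(fcl) & fcl < 1 - 1e-9
  if (any(low))
    warning("FCL below 1 (negative trophic steps) for specimen(s): ",
            paste(profiles$specimen_id[low], collapse = ", "))
  attr(fcl, "partial") <- partial
  fcl
}

#' Energy-transfer efficiency implied by a food chain length
#'
#' Assuming a constant gross growth efficiency (GGE) at every trophic
#' step, the fraction of energy fixed at the base of the food chain
#' that reaches a consumer at trophic level `fcl` is `gge^(fcl - 1)`;
#' log10 efficiency is linear in FCL with slope log10(gge).
#'
#' @param fcl trophic level(s), must be >= 1.
#' @param gge gross growth efficiency per trophic step, in (0, 1);
#'   default 0.20.
#' @return Efficiency fraction(s) in (0, 1].
#' @examples
#' transfer_efficiency(3.5)        # 0.2^2.5
#' @export
transfer_efficiency <- function(fcl, gge = 0.20) {
  if (!is.numeric(gge) || length(gge) != 1 || gge <= 0 || gge >= 1)
    stop("'gge' must be a single fraction in (0, 1)")
  fcl <- as.numeric(fcl)
  if (any(is.finite(fcl) & fcl < 1))
    stop("FCL below 1 is outside the domain of the efficiency conversion")
  gge^(fcl - 1)
}

#' Heterotrophic-protist residual index
#'
#' Alanine is the only trophic amino acid whose d15N is enriched by
#' heterotrophic protists, while glutamic acid is not. An ordinary
#' least-squares regression of d15N_Ala on d15N_Glu over a cohort is
#' fitted with intercept, and the Ala residuals are returned: positive
#' residuals indicate Ala enriched beyond its Glu-predicted value,
#' i.e. a longer protistan pathway in the specimen's food chain.
#'
#' @param profiles an `aa_profiles` data frame; at least 3 rows must
#'   carry both Ala and Glu.
#' @param standardize if TRUE return z-scored residuals
#'   (dimensionless) instead of raw permil residuals.
#' @return Named numeric vector, specimen_id -> residual (permil, or
#'   z-score when standardised). Specimens lacking Ala or Glu are
#'   absent from the result.
#' @export
protist_index <- function(profiles, standardize = FALSE) {
  profiles <- as_aa_profiles(as.data.frame(profiles))
  ok <- is.finite(profiles$d15n_ala) & is.finite(profiles$d15n_glu)
  if (sum(ok) < 3)
    stop("need >= 3 profiles with both Ala and Glu (got ", sum(ok), ")")
  glu <- profiles$d15n_glu[ok]
  ala <- profiles$d15n_ala[ok]
  if (stats::sd(glu) == 0)
    stop("zero variance in Glu d15N: regression undefined")
  fit <- stats::lm(ala ~ glu)
  res <- stats::residuals(fit)
  if (standardize) res <- (res - mean(res)) / stats::sd(res)
  names(res) <- profiles$specimen_id[ok]
  res
}

#' Per-specimen trophic metric table
#'
#' Runs both FCL estimators, the energy-transfer conversion and the
#' cohort protist index over a specimen table, collecting quality
#' flags (`partial` AA coverage, `fcl_lt_1`) per specimen.
#'
#' @param profiles an `aa_profiles` data frame.
#' @param calib an [calib_constants()] object.
#' @param sl_range optional inclusive standard-length filter in mm,
#'   e.g. `c(18, 23)`; rows with missing `sl_mm` are dropped when a
#'   filter is set.
#' @param complete_only drop specimens lacking any of the five AAs
#'   (flagged `partial`) before computing metrics.
#' @return Data frame with columns `specimen_id, year, station,
#'   fcl_glu_phe, fcl_trp_scr, transfer_efficiency, protist_residual,
#'   flags`.
#' @export
fcl_table <- function(profiles, calib = calib_constants(),
                      sl_range = NULL, complete_only = FALSE) {
  profiles <- as_aa_profiles(as.data.frame(profiles))
  if (!is.null(sl_range)) {
    stopifnot(length(sl_range) == 2, sl_range[1] <= sl_range[2])
    keep <- is.finite(profiles$sl_mm) & profiles$sl_mm >= sl_range[1] &
      profiles$sl_mm <= sl_range[2]
    profiles <- profiles[keep, , drop = FALSE]
  }
  if (!nrow(profiles)) stop("no specimens left after filtering")
  fcl_w <- withCallingHandlers(
    fcl_trp_scr(profiles, calib),
    warning = function(w) invokeRestart("muffleWarning"))
  partial <- attr(fcl_w, "partial")
  if (complete_only) {
    profiles <- profiles[!partial, , drop = FALSE]
    fcl_w <- fcl_w[!partial]
    partial <- partial[!partial]
    if (!nrow(profiles)) stop("no complete 5-AA specimens")
  }
  fcl_gp <- suppressWarnings(
    fcl_glu_phe(profiles$d15n_glu, profiles$d15n_phe, calib,
                specimen_id = profiles$specimen_id, na_ok = TRUE))
  te <- rep(NA_real_, nrow(profiles))
  ok_te <- !is.na(fcl_w) & fcl_w >= 1
  te[ok_te] <- transfer_efficiency(fcl_w[ok_te], calib$gge)
  pr <- tryCatch(protist_index(profiles), error = function(e) NULL)
  prot <- rep(NA_real_, nrow(profiles))
  if (!is.null(pr)) prot <- unname(pr[match(profiles$specimen_id, names(pr))])
  flags <- character(nrow(profiles))
  flags[partial] <- "partial"
  low <- !is.na(fcl_w) & fcl_w < 1
  flags[low] <- trimws(paste(flags[low], "fcl_lt_1"))
  if (any(low))
    warning("FCL below 1 for specimen(s): ",
            paste(profiles$specimen_id[low], collapse = ", "))
  data.frame(specimen_id = profiles$specimen_id, year = profiles$year,
             station = profiles$station, fcl_glu_phe = fcl_gp,
             fcl_trp_scr = as.numeric(fcl_w), transfer_efficiency = te,
             protist_residual = prot, flags = flags,
             stringsAsFactors = FALSE)
}
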