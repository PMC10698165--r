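#' Amino-acid calibration constants for trophic-position estimation
#'
#' Bundles the constants that close the food-chain-length (FCL) equation
#' \deqn{FCL = (\delta^{15}N_{Trp} - \delta^{15}N_{Scr} - \beta)/TDF + 1}
#' for every trophic/source amino-acid pairing, the per-AA procedural
#' reproducibility errors used as inverse-variance weights, and the gross
#' growth efficiency (GGE) used to convert FCL into an energy-transfer
#' efficiency.
#'
#' The trophic amino acids are glutamic acid (Glu), alanine (Ala) and
#' proline (Pro); the source amino acids are phenylalanine (Phe) and
#' glycine (Gly). \code{beta} is the producer-level offset between a
#' trophic and a source AA (permil) and \code{tdf} the per-trophic-step
#' enrichment (permil/step); both carry standard deviations used when the
#' multi-AA estimator averages constants across pairings with
#' \eqn{1/SD^2} weights.
#'
#' The default per-pairing values centre on the canonical Glu-Phe
#' calibration (beta = 3.6 permil, TDF = 5.7 permil); all constants are
#' data, not code: override any of them here or via a YAML config file
#' read with [read_calibration()].
#'
#' @param beta named numeric vector of producer offsets (permil), names
#'   of the form \code{"Glu-Phe"} covering each trophic-source pairing.
#' @param beta_sd standard deviations of \code{beta}, same names.
#' @param tdf named numeric vector of trophic discrimination factors
#'   (permil per trophic step), same pairing names.
#' @param tdf_sd standard deviations of \code{tdf}.
#' @param procedural_sd named numeric vector of per-AA procedural
#'   reproducibility SDs (permil) for Glu, Ala, Pro, Phe, Gly.
#' @param gge gross growth efficiency per trophic step, a fraction in
#'   (0, 1).
#' @return An object of class \code{fcl_calibration} (a list with the
#'   validated components above).
#' @examples
#' calib <- calib_constants()
#' calib$procedural_sd["Ala"]
#' @seealso [fcl_glu_phe()], [fcl_trp_scr()], [transfer_efficiency()]
#' @export
calib_constants <- function(beta = c("Glu-Phe" = 3.6, "Glu-Gly" = 3.1,
                                     "Ala-Phe" = 3.2, "Ala-Gly" = 2.7,
                                     "Pro-Phe" = 3.1, "Pro-Gly" = 2.6),
                            beta_sd = c("Glu-Phe" = 0.5, "Glu-Gly" = 0.9,
                                        "Ala-Phe" = 0.6, "Ala-Gly" = 1.0,
                                        "Pro-Phe" = 0.6, "Pro-Gly" = 1.0),
                            tdf = c("Glu-Phe" = 5.7, "Glu-Gly" = 5.7,
                                    "Ala-Phe" = 5.9, "Ala-Gly" = 5.9,
                                    "Pro-Phe" = 5.2, "Pro-Gly" = 5.2),
                            tdf_sd = c("Glu-Phe" = 0.3, "Glu-Gly" = 0.5,
                                       "Ala-Phe" = 0.4, "Ala-Gly" = 0.6,
                                       "Pro-Phe" = 0.4, "Pro-Gly" = 0.6),
                            procedural_sd = c(Glu = 0.24, Ala = 0.08,
                                              Pro = 0.25, Phe = 0.13,
                                              Gly = 0.19),
                            gge = 0.20) {
  beta <- unlist(beta); beta_sd <- unlist(beta_sd)
  tdf <- unlist(tdf); tdf_sd <- unlist(tdf_sd)
  procedural_sd <- unlist(procedural_sd)
  pairs <- names(beta)
  if (is.null(pairs) || !all(nzchar(pairs)))
    stop("'beta' must be named by trophic-source pairing, e.g. \"Glu-Phe\"")
  for (nm in c("beta_sd", "tdf", "tdf_sd")) {
    v <- get(nm)
    if (!all(pairs %in% names(v)))
      stop("'", nm, "' must cover every pairing named in 'beta'")
  }
  bad <- !grepl("^(Glu|Ala|Pro)-(Phe|Gly)$", pairs)
  if (any(bad))
    stop("malformed pairing name(s): ", paste(pairs[bad], collapse = ", "))
  if (any(!is.finite(tdf[pairs])) || any(tdf[pairs] <= 0))
    stop("all TDF values must be finite and > 0")
  if (any(!is.finite(beta[pairs])))
    stop("all beta values must be finite")
  if (any(beta_sd[pairs] <= 0) || any(tdf_sd[pairs] <= 0))
    stop("calibration SDs must be > 0")
  if (!all(c("Glu", "Ala", "Pro", "Phe", "Gly") %in% names(procedural_sd)))
    stop("'procedural_sd' must name Glu, Ala, Pro, Phe and Gly")
  if (any(!is.finite(procedural_sd)) || any(procedural_sd <= 0))
    stop("'procedural_sd' values must be finite and > 0")
  if (!is.numeric(gge) || length(gge) != 1 || !is.finite(gge) ||
      gge <= 0 || gge >= 1)
    stop("'gge' must be a single fraction in (0, 1)")
  structure(list(beta = beta[pairs], beta_sd = beta_sd[pairs],
                 tdf = tdf[pairs], tdf_sd = tdf_sd[pairs],
                 procedural_sd = procedural_sd, gge = unname(gge)),
            class = "fcl_calibration")
}

#' @export
print.fcl_calibration <- function(x, ...) {
  cat("Amino-acid calibration constants\n")
  tab <- data.frame(beta = x$beta, beta_sd = x$beta_sd,
                    tdf = x$tdf, tdf_sd = x$tdf_sd)
  print(tab)
  cat("Procedural SDs (permil):",
      paste(names(x$procedural_sd), x$procedural_sd, sep = "=",
            collapse = ", "), "\n")
  cat("GGE per trophic step:", x$gge, "\n")
  invisible(x)
}

#' Read calibration constants from a YAML config file
#'
#' The file holds a `calibration:` block with keys `beta`, `beta_sd`,
#' `tdf`, `tdf_sd` (maps pairing -> value), `procedural_sd` (map AA ->
#' value) and `gge`. Keys that are absent keep the package defaults.
#'
#' @param path path to a YAML file.
#' @return An `fcl_calibration` object.
#' @export
read_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  cal <- cfg$calibration
  if (is.null(cal)) cal <- cfg
  def <- formals(calib_constants)
  args <- list()
  for (key in c("beta", "beta_sd", "tdf", "tdf_sd", "procedural_sd", "gge"))
    if (!is.null(cal[[key]])) args[[key]] <- unlist(cal[[key]])
  do.call(calib_constants, args)
}

# Uncertainty-weighted (1/SD^2) mean of a per-pairing calibration constant
# over the pairings available in a profile.
weighted_constant <- function(values, sds, pairs) {
  w <- 1 / sds[pairs]^2
  sum(values[pairs] * w) / sum(w)
}
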