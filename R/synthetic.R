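#' Simulate a Gaussian random-walk latent series
#'
#' `x_t = x_{t-1} + w_t`, `w_t ~ N(0, Q)`; the building block of every
#' synthetic annual series.
#'
#' @param n_years number of years (>= 2).
#' @param Q process variance (>= 0; 0 gives a constant series).
#' @param x1 initial value.
#' @param years optional year labels (default `1:n_years`).
#' @param seed optional RNG seed.
#' @return Named numeric vector (year -> latent value).
#' @export
simulate_latent_walk <- function(n_years, Q, x1 = 0, years = NULL,
                                 seed = NULL) {
  if (n_years < 2) stop("'n_years' must be >= 2")
  if (Q < 0) stop("'Q' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- cumsum(c(x1, stats::rnorm(n_years - 1, 0, sqrt(Q))))
  if (is.null(years)) years <- seq_len(n_years)
  stats::setNames(x, years)
}

#' Simulate per-specimen amino-acid d15N profiles
#'
#' The forward model inverted by [fcl_trp_scr()]: each specimen in a
#' sampled year draws a true trophic level around the latent FCL of
#' its year, its source AAs record the latent baseline d15N, and its
#' trophic AAs sit one `beta + TDF * (FCL - 1)` above the baseline
#' (using the inverse-variance weighted means of the calibration
#' constants over all pairings), with independent per-AA procedural
#' noise scaled by the published reproducibility SDs. An optional
#' alanine enrichment plants a heterotrophic-protist signal in a
#' fraction of specimens.
#'
#' With `noise_scale = 0`, `fcl_sd = 0` and no enrichment, running
#' [fcl_trp_scr()] on the output recovers the latent FCL exactly.
#'
#' @param fcl_series named numeric vector, year -> latent FCL.
#' @param source_series named numeric vector, year -> latent source
#'   d15N (permil); same years as `fcl_series`.
#' @param calib an [calib_constants()] object.
#' @param n_per_year either a single count or a `c(min, max)` range
#'   sampled uniformly per year (default 3-15).
#' @param noise_scale multiplier on the per-AA procedural SDs
#'   (default 1; 0 = noiseless).
#' @param sampled_years years that actually have specimens (default:
#'   all years of `fcl_series`).
#' @param fcl_sd SD of specimen-level trophic spread around the
#'   yearly latent FCL (trophic levels; default 0).
#' @param ala_enrichment extra permil added to Ala in enriched
#'   specimens (default 0).
#' @param ala_fraction fraction of specimens enriched (default 0).
#' @param seed optional RNG seed.
#' @return An `aa_profiles` data frame with attributes `true_fcl`
#'   (specimen-level trophic level) and `ala_enriched` (logical).
#' @export
simulate_aa_profiles <- function(fcl_series, source_series,
                                 calib = calib_constants(),
                                 n_per_year = c(3, 15), noise_scale = 1,
                                 sampled_years = NULL, fcl_sd = 0,
                                 ala_enrichment = 0, ala_fraction = 0,
                                 seed = NULL) {
  stopifnot(inherits(calib, "fcl_calibration"))
  aas <- c(TROPHIC_AAS, SOURCE_AAS)
  if (!all(aas %in% names(calib$procedural_sd)))
    stop("calibration must cover all five amino acids")
  need <- as.vector(outer(TROPHIC_AAS, SOURCE_AAS, paste, sep = "-"))
  if (!all(need %in% names(calib$beta)))
    stop("calibration must hold beta/TDF for every trophic-source pairing")
  yrs <- names(fcl_series)
  if (is.null(yrs) || !identical(yrs, names(source_series)))
    stop("'fcl_series' and 'source_series' must share year names")
  if (is.null(sampled_years)) sampled_years <- as.integer(yrs)
  if (!is.null(seed)) set.seed(seed)
  beta_bar <- weighted_constant(calib$beta, calib$beta_sd, need)
  tdf_bar <- weighted_constant(calib$tdf, calib$tdf_sd, need)
  if (length(n_per_year) == 1) n_per_year <- rep(n_per_year, 2)

  rows <- list()
  for (yr in sampled_years) {
    k <- yr - as.integer(yrs[1]) + 1L
    n <- sample.int(n_per_year[2] - n_per_year[1] + 1L, 1L) +
      n_per_year[1] - 1L
    fcl_i <- fcl_series[[k]] + stats::rnorm(n, 0, fcl_sd)
    src <- source_series[[k]]
    enr <- stats::runif(n) < ala_fraction
    noise <- matrix(stats::rnorm(n * 5L), n, 5L,
                    dimnames = list(NULL, aas))
    noise <- sweep(noise, 2, noise_scale * calib$procedural_sd[aas], `*`)
    trp_level <- src + beta_bar + tdf_bar * (fcl_i - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = sprintf("%d_%02d", yr, seq_len(n)),
      year = yr, station = NA_character_,
      sl_mm = round(stats::runif(n, 18, 23), 1),
      d15n_glu = trp_level + noise[, "Glu"],
      d15n_ala = trp_level + noise[, "Ala"] + ala_enrichment * enr,
      d15n_pro = trp_level + noise[, "Pro"],
      d15n_phe = src + noise[, "Phe"],
      d15n_gly = src + noise[, "Gly"],
      d15n_bulk = NA_real_,
      true_fcl = fcl_i, enriched = enr,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  true_fcl <- df$true_fcl; enriched <- df$enriched
  df$true_fcl <- NULL; df$enriched <- NULL
  out <- as_aa_profiles(df)
  attr(out, "true_fcl") <- true_fcl
  attr(out, "ala_enriched") <- enriched
  out
}

#' Scenario settings for the coupled synthetic system
#'
#' Encodes the observational design being emulated: a 45-year window
#' of which roughly 20 springs have larval specimens (3-15 per
#' sampled year), a latent FCL random walk with a latent source-d15N
#' baseline, a larval large:small size-ratio series sharing the FCL
#' innovations (lag-0 coupling, default +0.8), a spawning-stock
#' biomass (SSB) series anti-coupled to the size ratio one year later
#' (default -0.6), and an optional boom-bust regime step that also
#' plants a community break.
#'
#' @param n_years window length (default 45).
#' @param start_year first calendar year (default 1961).
#' @param sampled_year_fraction fraction of years with specimens
#'   (default 0.45, i.e. about 20 of 45).
#' @param specimens_per_year `c(min, max)` specimens per sampled year.
#' @param Q_fcl process variance of the latent FCL walk (trophic
#'   levels squared per year).
#' @param R_fcl specimen-level variance around the yearly FCL.
#' @param fcl_start initial trophic level.
#' @param source_walk_Q process variance of the source-d15N walk.
#' @param source_start initial source d15N (permil).
#' @param Q_size,Q_ssb process variances of the log size-ratio and
#'   log SSB walks.
#' @param r_fcl_size lag-0 innovation coupling FCL -> size ratio.
#' @param r_size_ssb lag-1 innovation coupling size ratio -> SSB
#'   (negative: high size ratio precedes low SSB change).
#' @param obs_sd_size,obs_sd_ssb observation SDs on the log scale.
#' @param boom_bust NULL, or `list(year =, delta_fcl =,
#'   delta_source =)` step change (e.g. the abrupt regime shift the
#'   design emulates: FCL up, baseline d15N down).
#' @param noise_scale multiplier on procedural AA noise.
#' @param seed RNG seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 45, start_year = 1961,
                            sampled_year_fraction = 0.45,
                            specimens_per_year = c(3, 15),
                            Q_fcl = 0.01, R_fcl = 0.09, fcl_start = 3.2,
                            source_walk_Q = 0.04, source_start = 8,
                            Q_size = 0.04, Q_ssb = 0.04,
                            r_fcl_size = 0.8, r_size_ssb = -0.6,
                            obs_sd_size = 0.15, obs_sd_ssb = 0.1,
                            boom_bust = NULL, noise_scale = 1,
                            seed = 1L) {
  stopifnot(sampled_year_fraction > 0, sampled_year_fraction <= 1,
            Q_fcl > 0, source_walk_Q > 0, Q_size > 0, Q_ssb > 0,
            R_fcl >= 0)
  if (abs(r_fcl_size) >= 1 || abs(r_size_ssb) >= 1)
    stop("coupling correlations must satisfy |r| < 1")
  if (!is.null(boom_bust) &&
      !all(c("year", "delta_fcl", "delta_source") %in% names(boom_bust)))
    stop("'boom_bust' needs year, delta_fcl, delta_source")
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate the full coupled observational system
#'
#' Builds, in order: the latent FCL walk (plus optional regime step),
#' the latent source-d15N walk (plus step), a log size-ratio walk
#' whose innovations share the FCL innovations with loading
#' `r_fcl_size` (so the lag-0 correlation target is exact in
#' expectation), a log SSB walk whose innovations load on the
#' previous year's size-ratio innovation with `r_size_ssb`, specimen
#' AA profiles in the sampled years, a larval length-class count
#' table whose large:small ratio tracks the latent size ratio, and a
#' 12-taxon community matrix with a planted break at the regime-step
#' year. The complete latent truth is returned alongside the
#' observations so recovery tests can use it as an oracle.
#'
#' @param scenario a [scenario_config()].
#' @return A list of class `synthetic_dataset` with elements `truth`
#'   (data frame of latent yearly series), `specimens`
#'   (`aa_profiles`), `size_ratio`, `ssb` ([annual_series()]),
#'   `larval_counts` (year x length-class data frame), `community`
#'   (year x taxon matrix), `sampled_years`, `scenario`.
#' @export
simulate_coupled_system <- function(scenario = scenario_config()) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  n <- scenario$n_years
  years <- seq.int(scenario$start_year, length.out = n)

  w_std <- stats::rnorm(n - 1)               # standard FCL innovations
  step <- rep(0, n)
  if (!is.null(scenario$boom_bust)) {
    bb <- scenario$boom_bust
    step[years >= bb$year] <- bb$delta_fcl
  }
  fcl <- scenario$fcl_start +
    cumsum(c(0, sqrt(scenario$Q_fcl) * w_std)) + step
  # the step counts as part of the shared innovation so coupled series
  # inherit the regime shift
  w_tot <- diff(fcl) / sqrt(scenario$Q_fcl)

  src <- scenario$source_start +
    cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(scenario$source_walk_Q))))
  if (!is.null(scenario$boom_bust))
    src[years >= scenario$boom_bust$year] <-
      src[years >= scenario$boom_bust$year] + scenario$boom_bust$delta_source

  r1 <- scenario$r_fcl_size
  e_std <- r1 * w_tot + sqrt(1 - r1^2) * stats::rnorm(n - 1)
  log_size <- cumsum(c(0, sqrt(scenario$Q_size) * e_std))

  r2 <- scenario$r_size_ssb
  z <- stats::rnorm(n - 1)
  f_std <- c(z[1], r2 * e_std[-(n - 1)] + sqrt(1 - r2^2) * z[-1])
  log_ssb <- log(1e6) + cumsum(c(0, sqrt(scenario$Q_ssb) * f_std))

  n_sampled <- max(2L, round(scenario$sampled_year_fraction * n))
  sampled_years <- sort(sample(years, n_sampled))

  specimens <- simulate_aa_profiles(
    stats::setNames(fcl, years), stats::setNames(src, years),
    n_per_year = scenario$specimens_per_year,
    noise_scale = scenario$noise_scale,
    sampled_years = sampled_years, fcl_sd = sqrt(scenario$R_fcl))

  size_obs <- exp(log_size + stats::rnorm(n, 0, scenario$obs_sd_size))
  ssb_obs <- exp(log_ssb + stats::rnorm(n, 0, scenario$obs_sd_ssb))
  size_ratio <- annual_series(years, size_obs, name = "size_ratio")
  ssb <- annual_series(years, ssb_obs, name = "ssb")

  # larval length-class counts whose pooled ratio tracks the size ratio
  lambda_small <- 400
  small_cols <- c("6", "8", "9.5"); large_cols <- c("11", "15", "19")
  counts <- data.frame(year = years)
  for (cl in small_cols)
    counts[[cl]] <- stats::rpois(n, lambda_small / 3)
  for (cl in large_cols)
    counts[[cl]] <- stats::rpois(n, lambda_small * size_obs / 3)

  community <- simulate_community(
    years, break_year = if (is.null(scenario$boom_bust)) NA
                        else scenario$boom_bust$year)

  truth <- data.frame(year = years, fcl = fcl, source_d15n = src,
                      log_size_ratio = log_size,
                      size_ratio = exp(log_size),
                      log_ssb = log_ssb, ssb = exp(log_ssb))
  structure(list(truth = truth, specimens = specimens,
                 size_ratio = size_ratio, ssb = ssb,
                 larval_counts = counts, community = community,
                 sampled_years = sampled_years, scenario = scenario),
            class = "synthetic_dataset")
}

# Year x taxon matrix: lognormal noise around taxon means that shift at
# the break year ("small copepods" drop, the large calanoid rises).
simulate_community <- function(years, break_year = NA, n_taxa = 12,
                               shift_sd = 0.3) {
  taxa <- c(paste0("small_copepod_", 1:6), "calanoid_large",
            paste0("taxon_", 1:(n_taxa - 7)))
  base <- exp(stats::rnorm(n_taxa, log(200), 0.8))
  shift <- rep(1, n_taxa)
  if (!is.na(break_year)) {
    shift[1:6] <- 0.35      # small copepods collapse after the break
    shift[7] <- 2.5         # large calanoid gains
    shift[8:n_taxa] <- exp(stats::rnorm(n_taxa - 7, 0, 0.4))
  }
  m <- matrix(0, length(years), n_taxa, dimnames = list(years, taxa))
  for (j in seq_len(n_taxa)) {
    mu <- ifelse(!is.na(break_year) & years >= break_year,
                 base[j] * shift[j], base[j])
    m[, j] <- stats::rlnorm(length(years), log(mu), shift_sd)
  }
  m
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic coupled dataset\n")
  cat(sprintf("  years %d-%d; %d sampled years, %d specimens\n",
              min(x$truth$year), max(x$truth$year),
              length(x$sampled_years), nrow(x$specimens)))
  bb <- x$scenario$boom_bust
  if (!is.null(bb))
    cat(sprintf("  regime step at %d (dFCL %+0.2f, dsource %+0.2f permil)\n",
                bb$year, bb$delta_fcl, bb$delta_source))
  cat(sprintf("  couplings: FCL~size lag0 r=%.2f, size~SSB lag1 r=%.2f\n",
              x$scenario$r_fcl_size, x$scenario$r_size_ssb))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `specimens.csv`, `size_ratio.csv`, `ssb.csv`,
#' `larval_counts.csv`, `community.csv` and `truth.json`.
#'
#' @param dataset a [simulate_coupled_system()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(dataset$specimens),
                   file.path(dir, "specimens.csv"), row.names = FALSE)
  for (nm in c("size_ratio", "ssb"))
    utils::write.csv(as.data.frame(dataset[[nm]]),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  utils::write.csv(dataset$larval_counts,
                   file.path(dir, "larval_counts.csv"), row.names = FALSE)
  comm <- data.frame(year = rownames(dataset$community),
                     dataset$community, check.names = FALSE)
  utils::write.csv(comm, file.path(dir, "community.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
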