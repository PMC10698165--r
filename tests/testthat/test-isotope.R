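calib <- calib_constants()

test_that("Glu-Phe FCL follows the single-pair equation", {
  b <- calib$beta[["Glu-Phe"]]; tdf <- calib$tdf[["Glu-Phe"]]
  # zero and one trophic step by construction
  expect_equal(fcl_glu_phe(10 + b, 10, calib), 1.0)
  expect_equal(fcl_glu_phe(10 + b + tdf, 10, calib), 2.0)
  # independent hand calculation: (25 - 8 - 3.6)/5.7 + 1
  expect_equal(fcl_glu_phe(25.0, 8.0, calib), 3.3508772, tolerance = 1e-6)
  expect_error(fcl_glu_phe(NA, 8, calib, specimen_id = "L7"),
               "insufficient amino acids.*L7")
  expect_warning(fcl_glu_phe(8, 25, calib), "FCL below 1")
})

test_that("weighted mean d15N uses inverse-variance weights", {
  expect_equal(weighted_mean_d15n(c(Glu = 5, Ala = 5, Phe = 5)), 5)
  expect_equal(weighted_mean_d15n(c(Glu = 1, Ala = 3), sds = c(Glu = 2, Ala = 2)), 2)
  # frozen from the normal-equation oracle with the published SDs:
  # w = 1/c(.24, .08, .25)^2; sum(c(20,22,21)*w)/sum(w)
  expect_equal(weighted_mean_d15n(c(Glu = 20.0, Ala = 22.0, Pro = 21.0)),
               21.732486, tolerance = 1e-5)
  v <- c(Glu = 19.2, Ala = 21.4, Pro = 17.9, Phe = 7.7)
  expect_gte(weighted_mean_d15n(v), min(v))
  expect_lte(weighted_mean_d15n(v), max(v))
  expect_error(weighted_mean_d15n(numeric(0)), "no amino-acid values")
  expect_error(weighted_mean_d15n(c(Glu = 5), sds = c(Glu = 0)), "SD")
  expect_error(weighted_mean_d15n(c(Xyz = 5)), "no SD supplied")
})

test_that("multi-AA FCL estimator handles full, partial and degenerate profiles", {
  # every pairwise trophic-source difference equal to the weighted beta
  pairs <- names(calib$beta)
  beta_bar <- sum(calib$beta / calib$beta_sd^2) / sum(1 / calib$beta_sd^2)
  prof <- data.frame(specimen_id = "s1", year = 2000,
                     d15n_glu = 10 + beta_bar, d15n_ala = 10 + beta_bar,
                     d15n_pro = 10 + beta_bar, d15n_phe = 10, d15n_gly = 10)
  expect_equal(unname(as.numeric(fcl_trp_scr(prof, calib))), 1.0)
  expect_false(attr(fcl_trp_scr(prof, calib), "partial"))

  # single trophic + single source reduces to the Glu-Phe estimator when
  # the calibration only holds the Glu-Phe pairing
  cal_gp <- calib_constants(beta = c("Glu-Phe" = 3.6),
                            beta_sd = c("Glu-Phe" = 0.5),
                            tdf = c("Glu-Phe" = 5.7),
                            tdf_sd = c("Glu-Phe" = 0.3))
  prof2 <- data.frame(specimen_id = "s2", year = 2000,
                      d15n_glu = 24.1, d15n_phe = 7.3)
  f <- fcl_trp_scr(prof2, cal_gp)
  expect_equal(as.numeric(f), fcl_glu_phe(24.1, 7.3, cal_gp))
  expect_true(attr(f, "partial"))

  expect_error(fcl_trp_scr(data.frame(specimen_id = "s3", year = 2000,
                                      d15n_glu = 20), calib),
               "insufficient amino acids")
})

test_that("noiseless forward simulation inverts exactly (round trip)", {
  yrs <- as.character(1991:1995)
  fcl <- stats::setNames(c(3.2, 3.4, 2.9, 3.7, 3.2), yrs)
  src <- stats::setNames(c(8, 7.5, 9, 8.2, 8.8), yrs)
  prof <- simulate_aa_profiles(fcl, src, calib, n_per_year = 3,
                               noise_scale = 0, seed = 11)
  rec <- fcl_trp_scr(prof, calib)
  expect_equal(as.numeric(rec), fcl[as.character(prof$year)],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("both FCL estimators are invariant to a uniform d15N shift", {
  set.seed(42)
  prof <- data.frame(specimen_id = "p", year = 2000,
                     d15n_glu = 21.3, d15n_ala = 22.8, d15n_pro = 20.1,
                     d15n_phe = 8.4, d15n_gly = 7.2)
  for (c_shift in c(-3.7, 0.5, 12)) {
    shifted <- prof
    for (col in grep("^d15n_", names(prof), value = TRUE))
      shifted[[col]] <- prof[[col]] + c_shift
    expect_equal(as.numeric(fcl_trp_scr(shifted, calib)),
                 as.numeric(fcl_trp_scr(prof, calib)), tolerance = 1e-12)
    expect_equal(fcl_glu_phe(shifted$d15n_glu, shifted$d15n_phe, calib),
                 fcl_glu_phe(prof$d15n_glu, prof$d15n_phe, calib),
                 tolerance = 1e-12)
  }
})

test_that("transfer efficiency is gge^(fcl-1), decreasing, log-linear", {
  expect_equal(transfer_efficiency(1), 1.0)
  expect_equal(transfer_efficiency(2, 0.2), 0.2)
  # log-space oracle: 10^(2.5 * log10(0.2))
  expect_equal(transfer_efficiency(3.5, 0.2), 10^(2.5 * log10(0.2)),
               tolerance = 1e-12)
  expect_equal(transfer_efficiency(3.5, 0.2), 0.0178885, tolerance = 1e-5)
  fcl <- seq(1, 5, by = 0.25)
  te <- transfer_efficiency(fcl)
  expect_true(all(diff(te) < 0))
  expect_equal(transfer_efficiency(fcl + 1), 0.2 * te, tolerance = 1e-12)
  # log10 efficiency is linear in FCL with slope log10(gge)
  expect_equal(unname(coef(lm(log10(te) ~ fcl))[2]), log10(0.2),
               tolerance = 1e-9)
  expect_error(transfer_efficiency(0.8), "below 1")
  expect_error(transfer_efficiency(2, gge = 1.2), "gge")
})

test_that("protist index returns OLS residuals of Ala on Glu", {
  glu <- c(18.2, 19.5, 20.1, 21.3, 22.0, 18.9, 20.7, 21.8, 19.9, 22.4)
  # affine relation: all residuals zero
  prof0 <- data.frame(specimen_id = paste0("a", 1:10), year = 2000,
                      d15n_glu = glu, d15n_ala = 1.2 * glu + 0.5)
  expect_equal(unname(protist_index(prof0)), rep(0, 10), tolerance = 1e-10)

  # recorded disturbance; oracle = normal equations solved directly
  e <- c(0.31, -0.12, 0.05, -0.44, 0.22, 0.17, -0.28, 0.09, -0.15, 0.15)
  ala <- 1.2 * glu + 0.5 + e
  X <- cbind(1, glu)
  beta_hat <- solve(t(X) %*% X, t(X) %*% ala)
  oracle <- as.numeric(ala - X %*% beta_hat)
  prof <- prof0
  prof$d15n_ala <- ala
  res <- protist_index(prof)
  expect_equal(unname(res), oracle, tolerance = 1e-10)
  expect_equal(sum(res), 0, tolerance = 1e-10)
  expect_equal(sd(protist_index(prof, standardize = TRUE)), 1)

  expect_error(protist_index(prof[1:2, ]), ">= 3 profiles")
  prof_const <- prof
  prof_const$d15n_glu <- 20
  expect_error(protist_index(prof_const), "zero variance")
})

test_that("fcl_table assembles metrics, flags and filters", {
  yrs <- as.character(1990:1994)
  fcl <- stats::setNames(seq(3.0, 3.4, by = 0.1), yrs)
  src <- stats::setNames(rep(8, 5), yrs)
  prof <- simulate_aa_profiles(fcl, src, calib, n_per_year = 4, seed = 5)
  tab <- fcl_table(prof, calib)
  expect_named(tab, c("specimen_id", "year", "station", "fcl_glu_phe",
                      "fcl_trp_scr", "transfer_efficiency",
                      "protist_residual", "flags"))
  expect_equal(nrow(tab), nrow(prof))
  expect_equal(tab$transfer_efficiency,
               transfer_efficiency(tab$fcl_trp_scr, calib$gge))
  expect_equal(sum(tab$protist_residual), 0, tolerance = 1e-8)

  # partial profile is flagged, and complete_only drops it
  prof2 <- as.data.frame(prof)
  prof2$d15n_gly[1] <- NA
  tab2 <- fcl_table(prof2, calib)
  expect_equal(tab2$flags[1], "partial")
  expect_equal(nrow(fcl_table(prof2, calib, complete_only = TRUE)),
               nrow(prof2) - 1)

  # inclusive standard-length window
  prof3 <- as.data.frame(prof)
  prof3$sl_mm[1:3] <- c(17.9, 18.0, 23.0)
  tab3 <- fcl_table(prof3, calib, sl_range = c(18, 23))
  expect_false("17.9" %in% tab3$specimen_id)
  expect_equal(nrow(tab3), nrow(prof3) - 1)
})

test_that("specimen CSV round-trips through read_aa_profiles", {
  yrs <- as.character(2000:2002)
  prof <- simulate_aa_profiles(stats::setNames(rep(3.1, 3), yrs),
                               stats::setNames(rep(8, 3), yrs),
                               calib, n_per_year = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(prof), f, row.names = FALSE)
  back <- read_aa_profiles(f)
  expect_s3_class(back, "aa_profiles")
  expect_equal(back$d15n_glu, prof$d15n_glu, tolerance = 1e-12)
  expect_equal(as.numeric(fcl_trp_scr(back, calib)),
               as.numeric(fcl_trp_scr(prof, calib)), tolerance = 1e-12)
})

test_that("calibration constants are validated and YAML-configurable", {
  expect_error(calib_constants(gge = 1.5), "gge")
  expect_error(calib_constants(beta = c("Glu-Phe" = 3.6),
                               beta_sd = c("Glu-Phe" = 0.5),
                               tdf = c("Glu-Phe" = -1),
                               tdf_sd = c("Glu-Phe" = 0.3)), "TDF")
  expect_error(calib_constants(procedural_sd = c(Glu = 0.2)), "procedural_sd")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("calibration:",
               "  beta: {Glu-Phe: 3.4}",
               "  beta_sd: {Glu-Phe: 0.4}",
               "  tdf: {Glu-Phe: 6.0}",
               "  tdf_sd: {Glu-Phe: 0.2}",
               "  gge: 0.25"), f)
  cal <- read_calibration(f)
  expect_equal(cal$beta[["Glu-Phe"]], 3.4)
  expect_equal(cal$gge, 0.25)
  expect_equal(cal$procedural_sd[["Ala"]], 0.08)  # default retained
})
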