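quick_cfg <- function(...) {
  ssm_config(n_iterations = 4000, burn_in = 1000, thinning = 2, ...)
}

test_that("the test-suite Kalman smoother matches direct Gaussian conditioning", {
  # validates the oracle itself on a tiny instance before it is trusted
  n_t <- c(2, 0, 1)
  s_t <- c(6.2, 0, 4.1)
  km <- kalman_smoother_oracle(n_t, s_t, Q = 0.3, R = 0.5, m0 = 3, C0 = 2)
  jg <- joint_gaussian_oracle(n_t, s_t, Q = 0.3, R = 0.5, m0 = 3, C0 = 2)
  expect_equal(km$mean, jg$mean, tolerance = 1e-10)
  expect_equal(km$var, jg$var, tolerance = 1e-10)
})

test_that("states pin to the data in the noiseless observation limit", {
  set.seed(1)
  y <- cumsum(rnorm(15, 0, 0.5)) + 4
  ser <- annual_series(2001:2015, y)
  fit <- fit_ssm(ser, quick_cfg(fix_R = 1e-12, seed = 2))
  expect_equal(unname(fitted(fit)), y, tolerance = 1e-6)
})

test_that("Gibbs state posteriors match the exact smoother at fixed (Q, R)", {
  set.seed(8)
  x <- simulate_latent_walk(10, Q = 0.2, x1 = 1)
  yrs <- rep(1:10, each = 3)
  vals <- x[yrs] + rnorm(30, 0, 0.6)
  vals[yrs %in% c(4, 7)] <- NA
  keep <- !is.na(vals)
  ser <- annual_series(yrs[keep], vals[keep], year_range = c(1, 10))
  m0 <- mean(vals[keep][yrs[keep] == min(yrs[keep])])
  C0 <- 10 * var(vals[keep])
  cfg <- ssm_config(n_iterations = 22000, burn_in = 2000, thinning = 1,
                    fix_Q = 0.2, fix_R = 0.36, prior_x1 = c(m0, C0),
                    seed = 3)
  fit <- fit_ssm(ser, cfg)
  st <- series_stats(ser)
  oracle <- kalman_smoother_oracle(st$n_t, st$s_t, Q = 0.2, R = 0.36,
                                   m0 = m0, C0 = C0)
  pooled <- do.call(rbind, fit$draws)[, 1:10]
  post_mean <- colMeans(pooled)
  # MCMC standard error with a conservative autocorrelation inflation
  mcse <- apply(pooled, 2, sd) / sqrt(nrow(pooled) / 10)
  expect_true(all(abs(post_mean - oracle$mean) < 4 * mcse))
  expect_gte(mean(abs(post_mean - oracle$mean) < 2 * mcse), 0.9)
  # posterior variances agree with the smoother variances within 10%
  expect_equal(unname(apply(pooled, 2, var)), oracle$var, tolerance = 0.1)
})

test_that("missing years interpolate with inflated uncertainty", {
  yrs <- c(1:5, 7:11)           # year 6 missing
  vals <- seq(2, 11, by = 1)[yrs]  # monotone data
  ser <- annual_series(yrs, vals + rnorm(10, 0, 0.01), year_range = c(1, 11))
  fit <- fit_ssm(ser, quick_cfg(seed = 4))
  m <- fit$map
  i <- which(m$year == 6)
  expect_gt(m$map[i], m$map[i - 1] - 0.5)
  expect_lt(m$map[i], m$map[i + 1] + 0.5)
  width <- m$upper95 - m$lower95
  expect_gt(width[i], width[i - 1])
  expect_gt(width[i], width[i + 1])
})

test_that("adding a constant shifts states and leaves variances alone", {
  set.seed(5)
  ref <- make_reference_series(seed = 99)
  ser <- ref$series
  fit1 <- fit_ssm(ser, quick_cfg(seed = 6))
  ser2 <- annual_series(ser$year, ser$value + 7.5,
                        year_range = attr(ser, "year_range"))
  fit2 <- fit_ssm(ser2, quick_cfg(seed = 6))
  expect_equal(fit2$map$map, fit1$map$map + 7.5, tolerance = 0.05)
  expect_equal(coef(fit2), coef(fit1), tolerance = 0.05)
})

test_that("fits are bit-identical under the same seed and config", {
  ref <- make_reference_series(seed = 7)
  f1 <- fit_ssm(ref$series, quick_cfg(seed = 10))
  f2 <- fit_ssm(ref$series, quick_cfg(seed = 10))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_ssm(ref$series, quick_cfg(seed = 11))
  expect_false(identical(f1$draws, f2$draws) && identical(f1$draws, f3$draws))
})

test_that("degenerate and invalid inputs are rejected with guidance", {
  ser <- annual_series(rep(2001:2005, each = 2), rep(3, 10))
  expect_error(fit_ssm(ser, quick_cfg()), "fix_R")
  # fixed-R fallback actually works on the degenerate series
  fit <- fit_ssm(ser, quick_cfg(fix_R = 0.01, seed = 1))
  expect_equal(unname(fitted(fit)), rep(3, 5), tolerance = 0.2)
  expect_no_error(annual_series(2001, 5))
  expect_error(fit_ssm(annual_series(2001, 5), quick_cfg()),
               "2 distinct years")
  expect_error(ssm_config(n_chains = 1), "2 chains")
  expect_error(ssm_config(burn_in = 5000, n_iterations = 4000), "burn_in")
})

test_that("split-chain R-hat behaves at its reference points", {
  # identical chains: between-chain variance is exactly zero
  set.seed(12)
  v <- rnorm(1e6)
  expect_equal(gelman_rubin(cbind(v, v), split = FALSE), 1, tolerance = 1e-6)
  # two independent chains from the same distribution mix well
  ch <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(gelman_rubin(ch), 1.01)
  # separated chains are flagged
  ch2 <- cbind(rnorm(1e4), rnorm(1e4) + 5)
  expect_gt(gelman_rubin(ch2), 1.5)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("R-hat agrees with the coda implementation on sampler output", {
  skip_if_not_installed("coda")
  ref <- make_reference_series(seed = 21)
  fit <- fit_ssm(ref$series, quick_cfg(seed = 13))
  for (p in c("Q", "R", "x_1980")) {
    ml <- coda::mcmc.list(lapply(fit$draws, function(d) coda::mcmc(d[, p])))
    psrf <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1]
    mine <- gelman_rubin(sapply(fit$draws, function(d) d[, p]),
                         split = FALSE)
    expect_equal(mine, psrf, tolerance = 0.01)
  }
})

test_that("MAP extraction finds the dominant mode", {
  set.seed(14)
  sym <- matrix(rnorm(5000, 3, 0.4), ncol = 1)
  ms <- map_from_draws(sym, years = 2000)
  bw <- stats::density(sym[, 1])$bw
  expect_lt(abs(ms$map - ms$median), 2 * bw)
  # point mass
  pm <- matrix(rep(2.5, 400), ncol = 1)
  expect_equal(map_from_draws(pm, 2000)$map, 2.5)
  # bimodal with the heavier mode at 2.0
  bi <- matrix(c(rnorm(3000, 2, 0.15), rnorm(1500, 4, 0.15)), ncol = 1)
  bw2 <- stats::density(bi[, 1])$bw
  expect_lt(abs(map_from_draws(bi, 2000)$map - 2.0), max(bw2, 0.1))
  expect_error(map_from_draws(matrix(rnorm(150), ncol = 1), 2000),
               "too few pooled draws")
  # intervals always bracket the MAP for unimodal draws
  expect_true(ms$lower95 <= ms$map && ms$map <= ms$upper95)
})

test_that("log-scale fitting models multiplicative series", {
  set.seed(15)
  lx <- simulate_latent_walk(20, 0.02, x1 = log(1e6))
  yrs <- rep(1:20, each = 3)
  vals <- exp(lx[yrs] + rnorm(60, 0, 0.1))
  ser <- annual_series(yrs, vals)
  fit <- fit_ssm(ser, quick_cfg(log_scale = TRUE, seed = 16))
  expect_equal(unname(fitted(fit)), unname(lx), tolerance = 0.15)
  expect_error(fit_ssm(annual_series(1:3, c(-1, 2, 3)),
                       quick_cfg(log_scale = TRUE)), "positive")
})

test_that("ssm_fit methods are coherent", {
  ref <- make_reference_series(seed = 30)
  fit <- fit_ssm(ref$series, quick_cfg(seed = 17))
  expect_named(coef(fit), c("Q", "R"))
  expect_equal(length(fitted(fit)), 45)
  expect_equal(predict(fit, years = 1970)$map,
               fit$map$map[fit$map$year == 1970])
  expect_error(predict(fit, years = 1900), "outside the fitted grid")
  r <- residuals(fit)
  expect_equal(length(r), nrow(ref$series))
  expect_lt(abs(mean(r)), 0.2)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_named(sim, c("year", "sim_1", "sim_2"))
  expect_output(print(fit), "state-space fit")
  expect_output(print(summary(fit)), "Variance posteriors")
  f <- withr::local_tempfile(fileext = ".csv")
  write_ssm_summary(fit, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$seed, 17)
  back <- utils::read.csv(f)
  expect_equal(back$map, fit$map$map, tolerance = 1e-8)
})
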