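test_that("baseline normalization divides by the pre-addition mean", {
  tr <- fluorescence_trace(seq(-10, 50), rep(3, 61))
  n <- normalize_trace(tr)
  expect_equal(n$signal, rep(1, 61))                 # constant -> all ones
  # baseline mean 2.0, plateau 0.4 -> normalized plateau 0.2
  t <- seq(-10, 50)
  tr2 <- fluorescence_trace(t, ifelse(t < 0, 2.0, 0.4))
  n2 <- normalize_trace(tr2)
  expect_equal(mean(n2$signal[t < 0]), 1)
  expect_equal(n2$signal[t >= 0], rep(0.2, 51))
})

test_that("normalization is idempotent and requires a baseline", {
  tr <- gen_trace(0.01, 0.3, 60, 200, noise_model(0.01, 0, 2))
  n1 <- normalize_trace(tr)
  n2 <- normalize_trace(n1)
  expect_equal(n2$signal, n1$signal, tolerance = 1e-12)
  no_base <- fluorescence_trace(seq(0, 100), rep(1, 101))
  expect_error(normalize_trace(no_base), "baseline")
})

test_that("lamp reference is divided out before normalization", {
  t <- seq(-20, 100)
  lamp <- 1 + 0.2 * sin(t / 7)
  true_sig <- ifelse(t < 0, 1, 0.3 + 0.7 * exp(-0.02 * t))
  tr <- fluorescence_trace(t, true_sig * lamp, lamp_ref = lamp)
  expect_equal(tr$signal, true_sig, tolerance = 1e-12)
})

test_that("noiseless exponential fit is an exact round-trip", {
  tr <- gen_trace(0.013, 0.2, 60, 500, noise_model(0, 0, 1))
  fit <- fit_exponential(normalize_trace(tr))
  expect_true(fit$detected)
  expect_equal(fit$rate, 0.013, tolerance = 1e-6)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(fit$tau, 1 / fit$rate, tolerance = 1e-12)
})

test_that("a fast water-like trace is recovered at realistic noise", {
  # bench rate 13e-3 1/s with ~1% lamp noise; late-time level ~20%
  tr <- gen_trace(0.013, 0.2, 60, 500, noise_model(0.01, 0, 42))
  ntr <- normalize_trace(tr)
  late <- ntr$signal[ntr$time_s > 400]
  expect_equal(mean(late), 0.2, tolerance = 0.05)
  fit <- fit_exponential(ntr)
  expect_equal(fit$rate, 0.013, tolerance = 0.1)
  expect_gt(fit$r_squared, 0.99)
})

test_that("rate recovery is unbiased at 1% noise over many replicates", {
  rates <- vapply(1:200, function(i) {
    tr <- gen_trace(0.010, 0.2, 60, 500, noise_model(0.01, 0, 1000 + i))
    fit_exponential(normalize_trace(tr))$rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.010) / 0.010, 0.01)   # bias < 1%
  expect_lt(stats::sd(rates) / 0.010, 0.10)
})

test_that("flat traces yield a no-loading result, not a spurious rate", {
  # the high-pH analogue: no quench, only instrument noise
  tr <- gen_trace(0, 1, 60, 500, noise_model(0.01, 0, 9))
  fit <- fit_exponential(normalize_trace(tr))
  expect_false(fit$detected)
  expect_true(is.na(fit$rate))
  exact_flat <- fluorescence_trace(seq(-10, 200), rep(1, 211))
  expect_false(fit_exponential(exact_flat)$detected)
})

test_that("mixing dead time can be absorbed by the optional lag parameter", {
  t <- seq(-30, 400)
  lag <- 4
  sig <- ifelse(t < lag, 1, 0.25 + 0.75 * exp(-0.02 * (t - lag)))
  tr <- fluorescence_trace(t, sig)
  fit <- fit_exponential(tr, t_lag_max = 10)
  expect_equal(fit$rate, 0.02, tolerance = 1e-3)
  expect_equal(fit$t_lag, lag, tolerance = 0.05)
})

test_that("tau_diff obeys its exact algebraic identities", {
  p <- transport_params(d_ex = 3.9e-10, radius_nm = 26.5,
                        density_eff_mg_cm3 = 2)
  t1 <- tau_diff(5e-3, p)
  expect_equal(tau_diff(1e-2, p), t1 / 2)             # c^-1 scaling, exact
  p2 <- transport_params(3.9e-10, radius_nm = 53, density_eff_mg_cm3 = 2)
  expect_equal(tau_diff(5e-3, p2), 4 * t1)            # r^2 scaling, exact
  cg <- 10^seq(-4, 0, length.out = 9)
  expect_equal(tau_diff(cg, p) * cg, rep(t1 * 5e-3, 9))
  # direct substitution oracle: pi r^2 (rho/c) / (18 D)
  expect_equal(t1, pi * (26.5e-9)^2 * (2 / 5e-3) / (18 * 3.9e-10),
               tolerance = 1e-12)
  expect_error(tau_diff(0, p), "diverges")
})

test_that("capture model fit recovers A and tau0", {
  cs <- c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05)
  fit <- fit_capture_model(cs, 0.3 / cs + 60)
  expect_equal(fit$prefactor_a, 0.3, tolerance = 1e-9)
  expect_equal(fit$tau0, 60, tolerance = 1e-9)
  # constant tau: no concentration dependence left
  fit2 <- fit_capture_model(cs, rep(80, 6))
  expect_equal(fit2$prefactor_a, 0, tolerance = 1e-9)
  expect_equal(fit2$tau0, 80, tolerance = 1e-9)
  expect_error(fit_capture_model(cs[1:2], c(1, 2)), "3 concentrations")
  # noisy tau values never push tau0 below its physical floor
  set.seed(4)
  fit3 <- fit_capture_model(cs, 0.05 / cs + 0.01 + rnorm(6, 0, 2))
  expect_gte(fit3$tau0, 0)
})

test_that("capture-model residuals are structureless under the true model", {
  cs <- 10^seq(-3, -1.3, length.out = 8)
  pvals <- vapply(1:50, function(i) {
    set.seed(300 + i)
    tau <- 0.3 / cs + 60 + rnorm(8, 0, 3)
    fit <- fit_capture_model(cs, tau)
    res <- tau - (fit$prefactor_a / cs + fit$tau0)
    suppressWarnings(stats::cor.test(res, cs, method = "spearman")$p.value)
  }, numeric(1))
  # at alpha = 0.05 about 5% false positives are expected
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("intraparticle diffusion constant estimate has the right order", {
  d <- d_intra_estimate(25, 60)
  expect_equal(d, (25e-9)^2 / 60, tolerance = 1e-12)
  expect_equal(floor(log10(d)), -17)                  # order 1e-17 m^2/s
  expect_equal(floor(log10(3.9e-10 / d)), 7)          # ~1e7-fold hindrance
  expect_lt(d_intra_estimate(25, 1e12), 1e-27)        # -> 0 as tau0 -> inf
  expect_error(d_intra_estimate(-25, 60), "> 0")
})

test_that("trace CSV round-trips, including the lamp-reference column", {
  dir <- withr::local_tempdir()
  tr <- gen_trace(0.01, 0.3, 60, 200, noise_model(0.01, 0, 6))
  f <- file.path(dir, "tr.csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  # with a lamp_ref column the signal comes back referenced
  df <- data.frame(time_s = seq(-5, 30), signal = 2 * exp(-0.1 * seq(-5, 30)),
                   lamp_ref = rep(2, 36))
  f2 <- file.path(dir, "tr2.csv")
  write.csv(df, f2, row.names = FALSE)
  back2 <- read_trace_csv(f2)
  expect_equal(back2$signal, exp(-0.1 * seq(-5, 30)), tolerance = 1e-12)
})
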