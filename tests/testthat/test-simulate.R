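test_that("state-path occupancy matches the analytic stationary distribution", {
  cfg <- sim_config(kci = kci_fixed(0.3), k_ic = 0.4, k_io = 0.3, k_oi = 0.3,
                    duration = 4000, seed = 101)
  path <- simulate_state_path(cfg)
  ends <- c(path$times[-1], path$duration)
  dw <- ends - path$times
  occ <- tapply(dw, factor(path$states, levels = c("C", "I", "O")), sum)
  occ <- occ / sum(occ)
  pi <- stationary_distribution(cfg)
  # Monte-Carlo error from block variability of the occupancy fraction
  blocks <- cut(path$times, breaks = seq(0, 4000, length.out = 11),
                include.lowest = TRUE)
  for (s in c("C", "I", "O")) {
    bo <- tapply(dw * (path$states == s), blocks, sum) /
      tapply(dw, blocks, sum)
    se <- sd(bo) / sqrt(length(bo))
    expect_lt(abs(occ[[s]] - pi[[s]]), 3 * se + 1e-12)
  }
})

test_that("symmetric two-state chain spends half its time unwound", {
  cfg <- sim_config(kci = kci_fixed(1), k_ic = 1, k_io = 0, k_oi = 0,
                    duration = 5000, seed = 7)
  path <- simulate_state_path(cfg)
  ends <- c(path$times[-1], path$duration)
  frac_i <- sum((ends - path$times)[path$states == "I"]) / path$duration
  expect_lt(abs(frac_i - 0.5), 0.03)
})

test_that("closed-state dwells follow the hyperbolic law at 4 nM", {
  cfg <- sim_config(kci = kci_hyperbolic(0.06, 10), k_ic = 0.2,
                    k_io = 0.1, k_oi = 0.1, duration = 40000, seed = 21)
  path <- simulate_state_path(cfg)
  ends <- c(path$times[-1], path$duration)
  dw <- ends - path$times
  # drop the final (censored) dwell
  keep <- path$states == "C" & seq_along(dw) < length(dw)
  expect_gte(sum(keep), 500)
  expected <- 1 / kci_rate(cfg$kci, 4)            # (10 + 4) / (0.06 * 4)
  mc_se <- expected / sqrt(sum(keep))
  expect_lt(abs(mean(dw[keep]) - expected), 3 * mc_se)
})

test_that("zero duration gives the initial state only and an empty trace", {
  cfg <- sim_config(duration = 0, seed = 1)
  path <- simulate_state_path(cfg)
  expect_identical(path$states, "C")
  expect_identical(path$times, 0)
  expect_length(simulate_trace(path, cfg)$theta, 0L)
})

test_that("hyperbolic law halves at Kd and the linear law vanishes at zero", {
  hyp <- kci_hyperbolic(kopen = 0.06, kd_init = 10)
  expect_equal(kci_rate(hyp, 10), 0.03)
  lin <- kci_linear(0.15)
  expect_equal(kci_rate(lin, 0), 0)
  cfg <- sim_config(kci = lin, rnp_conc = 0, duration = 500, seed = 3)
  path <- simulate_state_path(cfg)
  expect_identical(path$states, "C")   # no capture events without RNP
})

test_that("saturating concentrations drive closed dwells to 1/kopen", {
  cfg <- sim_config(kci = kci_hyperbolic(0.06, 10), rnp_conc = 1e4,
                    k_ic = 0.2, duration = 30000, seed = 31)
  path <- simulate_state_path(cfg)
  ends <- c(path$times[-1], path$duration)
  dw <- ends - path$times
  keep <- path$states == "C" & seq_along(dw) < length(dw)
  expect_rel(mean(dw[keep]), 1 / 0.06, 0.1)
})

test_that("OU observation reproduces stationary variance and AR(1) autocorrelation", {
  cfg <- sim_config(kci = kci_fixed(0), ou_kappa = 200, ou_sigma = 1.5,
                    sample_rate = 5000, duration = 200, seed = 11)
  tr <- simulate_twist_trace(cfg)
  expect_length(tr$theta, 1e6)
  expect_rel(var(tr$theta), 1.5^2, 0.05)
  a_expected <- exp(-200 / 5000)
  n <- length(tr$theta)
  a_hat <- cor(tr$theta[-n], tr$theta[-1])
  expect_lt(abs(a_hat - a_expected), 0.005)
})

test_that("noiseless traces equal the state-level step function exactly", {
  cfg <- sim_config(kci = kci_fixed(0.5), k_ic = 0.5, k_io = 0.3, k_oi = 0.3,
                    ou_sigma = 0, duration = 100, seed = 13)
  tr <- simulate_twist_trace(cfg)
  path <- attr(tr, "path")
  idx <- findInterval(tr$time, path$times)
  expect_identical(tr$theta, unname(cfg$levels_bp[path$states[idx]]))
})

test_that("the Langmuir baseline shift offsets every sample additively", {
  cfg <- sim_config(kci = kci_fixed(0), ou_sigma = 0, duration = 10,
                    rnp_conc = 14, baseline_shift = langmuir_shift(3.7, 14),
                    seed = 2)
  tr <- simulate_twist_trace(cfg)
  expect_equal(unique(tr$theta), 3.7 / 2)  # half-saturation at [RNP] = Kd
})

test_that("fixing the seed fixes every simulated output bit for bit", {
  cfg <- sim_config(kci = kci_fixed(0.3), k_ic = 0.3, duration = 30,
                    seed = 99)
  t1 <- simulate_twist_trace(cfg)
  t2 <- simulate_twist_trace(cfg)
  expect_identical(t1$theta, t2$theta)
  expect_identical(attr(t1, "path"), attr(t2, "path"))
  s1 <- simulate_concentration_series(cfg_series <- sim_config(
    kci = kci_hyperbolic(0.06, 10), duration = 20, seed = 5), c(1, 10))
  s2 <- simulate_concentration_series(cfg_series, c(1, 10))
  expect_identical(lapply(s1, `[[`, "theta"), lapply(s2, `[[`, "theta"))
})

test_that("concentration series validates inputs and records metadata", {
  cfg <- sim_config(kci = kci_hyperbolic(0.06, 10), duration = 5, seed = 1)
  expect_error(simulate_concentration_series(cfg, c(-1, 5)), "concentrations")
  cfg_fixed <- sim_config(kci = kci_fixed(0.1), duration = 5)
  expect_error(simulate_concentration_series(cfg_fixed, c(1, 2)),
               "linear or hyperbolic")
  out <- simulate_concentration_series(cfg, c(1, 50))
  expect_equal(vapply(out, function(t) t$metadata$conc_nM, numeric(1)),
               c(1, 50))
})

test_that("sub-sample dwells trigger the aliasing warning", {
  cfg <- sim_config(kci = kci_fixed(5000), k_ic = 5000, sample_rate = 500,
                    duration = 2, seed = 4)
  path <- simulate_state_path(cfg)
  expect_warning(simulate_trace(path, cfg), "aliased")
})

test_that("noiseless bulk datasets obey their closed forms", {
  iso <- simulate_binding_isotherm(14, delta_theta_sat = 3.7, kd_eff = 14)
  expect_equal(iso$shift_bp, 3.7 / 2)
  cl <- simulate_cleavage_course(times = c(0, 1, 1e6), a_fast = 0.6,
                                 k_fast = 2, a_slow = 0.3, k_slow = 0.05)
  expect_equal(cl$y[3], 0.9, tolerance = 1e-12)   # t -> Inf: Afast + Aslow
  expect_equal(cl$y[1], 0)
  ap <- simulate_2ap_course(times = c(0, 1e6), y0 = 100, ymax = 50,
                            kobs = 0.9)
  expect_equal(ap$y, c(100, 150))
  expect_error(simulate_cleavage_course(0:10, a_fast = 0.8, k_fast = 1,
                                        a_slow = 0.4, k_slow = 0.1),
               "amplitudes")
})

test_that("droplet-count simulation recovers the true break fraction", {
  counts <- simulate_droplet_counts(f_dsb = 0.3, lambda = 2e5, seed = 8)
  est <- pct_dsb(counts[["n_target"]], counts[["n_reference"]])
  # Poisson error on 100 * (1 - Nt/Nref) at lambda counts
  se <- 100 * sqrt(0.7 * (1 + 0.7) / 2e5)
  expect_lt(abs(est - 30), 3 * se)
})
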