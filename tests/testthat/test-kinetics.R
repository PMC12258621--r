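test_that("rate constants follow the count-over-occupancy definition", {
  # 30 C->I transitions with 1000 s of closed occupancy after the first event
  labels <- c("I", rep(c("C", "I"), 30))
  dwells <- c(1, rep(c(1000 / 30, 2), 30))
  rs <- estimate_rates(seq_from(labels, dwells))
  kci <- get_rate(rs, "C", "I")
  expect_equal(kci$rate, 0.03, tolerance = 1e-12)
  expect_equal(kci$se, sqrt(30) / 1000, tolerance = 1e-12)
  expect_equal(kci$n, 30)
})

test_that("sequences without O visits report undefined O rates only", {
  rs <- estimate_rates(seq_from(c("C", "I", "C", "I", "C"), rep(2, 5)))
  expect_true(is.na(get_rate(rs, "O", "I")$rate))
  # after dropping the first state: I,C,I,C -> one C->I, two I->C
  expect_equal(get_rate(rs, "C", "I")$rate, 1 / 4)
  expect_equal(get_rate(rs, "I", "C")$rate, 2 / 4)
  # unobserved transitions from an occupied state report 0 with SE 1/T
  expect_equal(get_rate(rs, "C", "O")$rate, 0)
  expect_equal(get_rate(rs, "C", "O")$se, 1 / 4)
})

test_that("rate counting agrees with a brute-force transition counter", {
  set.seed(60)
  for (rep in 1:20) {
    m <- sample(4:30, 1)
    labels <- character(m)
    labels[1] <- sample(c("C", "I", "O"), 1)
    for (i in 2:m)
      labels[i] <- sample(setdiff(c("C", "I", "O"), labels[i - 1]), 1)
    dwells <- round(runif(m, 0.1, 5), 3)
    rs <- estimate_rates(seq_from(labels, dwells))
    # oracle: loop over the sequence, skipping the first state
    lab2 <- labels[-1]; dw2 <- dwells[-1]
    for (from in c("C", "I", "O")) for (to in c("C", "I", "O")) {
      if (from == to) next
      n_oracle <- 0
      for (i in seq_len(length(lab2) - 1))
        if (lab2[i] == from && lab2[i + 1] == to) n_oracle <- n_oracle + 1
      t_oracle <- sum(dw2[lab2 == from])
      got <- get_rate(rs, from, to)
      expect_equal(got$n, n_oracle)
      if (t_oracle > 0) expect_equal(got$rate, n_oracle / t_oracle)
      else expect_true(is.na(got$rate))
    }
  }
})

test_that("rates from a simulated hour-long path sit within 3 SE of truth", {
  cfg <- sim_config(kci = kci_fixed(0.05), k_ic = 0.2, k_io = 0.1,
                    k_oi = 0.1, duration = 3600, seed = 70)
  rs <- estimate_rates(seq_from_path(simulate_state_path(cfg)))
  truth <- c(CI = 0.05, IC = 0.2, IO = 0.1, OI = 0.1)
  for (nm in names(truth)) {
    got <- get_rate(rs, substr(nm, 1, 1), substr(nm, 2, 2))
    expect_lt(abs(got$rate - truth[[nm]]), 3 * got$se)
  }
})

test_that("rates rescale exactly under a uniform change of time units", {
  labels <- c("C", "I", "C", "I", "O", "I", "C")
  dwells <- c(3, 1, 4, 1.5, 2, 1, 5)
  r1 <- estimate_rates(seq_from(labels, dwells))
  r60 <- estimate_rates(seq_from(labels, dwells * 60))
  expect_equal(r60$rates$rate, r1$rates$rate / 60, tolerance = 1e-12)
})

test_that("noiseless linear series give the exact effective on-rate", {
  conc <- c(1, 2, 5, 10, 20)
  pts <- data.frame(conc_nM = conc, k = 0.15 * conc, se = 0.001)
  fit <- fit_capture_model(pts, model = "auto")
  expect_equal(fit$model, "linear")
  expect_equal(coef(fit)[["kon_eff"]], 0.15, tolerance = 1e-9)
})

test_that("noiseless hyperbolic series give the exact two-step parameters", {
  conc <- c(1, 2, 5, 10, 20, 50, 100)
  pts <- data.frame(conc_nM = conc, k = 0.06 * conc / (10 + conc),
                    se = 0.001)
  fit <- fit_capture_model(pts, model = "auto")
  expect_equal(fit$model, "hyperbolic")
  expect_equal(coef(fit)[["kopen"]], 0.06, tolerance = 1e-7)
  expect_equal(coef(fit)[["kd_init"]], 10, tolerance = 1e-5)
  expect_equal(fit$kon_eff_low_conc, 0.006, tolerance = 1e-7)
})

test_that("noisy hyperbolic series recover truth within 2 SE and beat a grid oracle", {
  set.seed(80)
  conc <- c(1, 2, 5, 10, 20, 50, 100)
  k_true <- 0.06 * conc / (10 + conc)
  pts <- data.frame(conc_nM = conc, k = k_true * (1 + rnorm(7, sd = 0.05)),
                    se = 0.05 * k_true)
  fit <- fit_capture_model(pts, model = "hyperbolic")
  expect_lt(abs(coef(fit)[["kopen"]] - 0.06), 2 * fit$se[["kopen"]])
  expect_lt(abs(coef(fit)[["kd_init"]] - 10), 2 * fit$se[["kd_init"]])
  w <- 1 / pts$se^2
  rss <- function(kopen, kd)
    sum(w * (pts$k - kopen * pts$conc_nM / (kd + pts$conc_nM))^2)
  grid <- expand.grid(kopen = seq(0.03, 0.12, length.out = 120),
                      kd = seq(2, 40, length.out = 120))
  expect_lte(fit$rss, min(mapply(rss, grid$kopen, grid$kd)) + 1e-9)
})

test_that("far-from-saturation data flag the fit and pin only the slope", {
  conc <- c(0.5, 1, 2, 4, 8)
  pts <- data.frame(conc_nM = conc, k = 0.006 * conc, se = 1e-4)
  fit <- fit_capture_model(pts, model = "hyperbolic")
  expect_true(any(grepl("saturation not observed", fit$flags)))
  expect_equal(fit$kon_eff_low_conc, 0.006, tolerance = 0.01)
})

test_that("the two-step interpretation composes the printed constants", {
  pts <- data.frame(conc_nM = c(1, 2, 5, 10, 20, 50, 100))
  pts$k <- 0.06 * pts$conc_nM / (10 + pts$conc_nM)
  fit <- fit_capture_model(pts, model = "hyperbolic")
  ts <- two_step_interpret(fit, kon_init = 0.1)
  expect_equal(ts$koff_init, 1, tolerance = 1e-5)        # 0.1 /nM/s * 10 nM
  expect_equal(ts$kon_eff_low_conc, 0.006, tolerance = 1e-6)
  # re-simulating the lumped law reproduces the fitted curve identically
  expect_equal(predict(ts, pts), predict(fit, pts), tolerance = 1e-12)
  lin <- fit_capture_model(data.frame(conc_nM = c(1, 5), k = c(0.15, 0.75)),
                           model = "linear")
  expect_error(two_step_interpret(lin), "hyperbolic")
})

test_that("contract checks on capture-model inputs", {
  expect_error(fit_capture_model(data.frame(conc_nM = 1, k = 0.1)),
               "at least 2")
  expect_error(fit_capture_model(data.frame(conc_nM = c(1, 1, 2),
                                            k = c(0.1, 0.11, 0.2))),
               "distinct")
  expect_error(fit_capture_model(data.frame(conc_nM = c(1, 2),
                                            k = c(0.1, 0.2)),
                                 model = "hyperbolic"), "at least 3")
})

test_that("noiseless Langmuir isotherms are fitted exactly", {
  conc <- c(2, 5, 10, 25, 50, 100)
  pts <- data.frame(conc_nM = conc, shift_bp = 3.7 * conc / (14 + conc))
  fit <- langmuir_fit(pts)
  expect_equal(coef(fit)[["delta_theta_sat"]], 3.7, tolerance = 1e-7)
  expect_equal(coef(fit)[["kd"]], 14, tolerance = 1e-5)
  expect_error(langmuir_fit(data.frame(conc_nM = c(5, 5), shift_bp = c(1, 1))),
               "3 distinct")
  flat <- langmuir_fit(data.frame(conc_nM = conc, shift_bp = rep(0, 6)))
  expect_true(any(grepl("unidentifiable", flat$flags)))
})

test_that("noisy Langmuir recovery stays within 2 SE and matches a grid oracle", {
  set.seed(90)
  iso <- simulate_binding_isotherm(c(2, 5, 10, 25, 50, 100), 3.7, 14,
                                   sd = 0.3, n_tethers = 5, seed = 91)
  fit <- langmuir_fit(data.frame(conc_nM = iso$conc_nM,
                                 shift_bp = iso$shift_bp))
  expect_lt(abs(coef(fit)[["delta_theta_sat"]] - 3.7),
            2.5 * fit$se[["delta_theta_sat"]])
  expect_lt(abs(coef(fit)[["kd"]] - 14), 2.5 * fit$se[["kd"]])
  rss <- function(sat, kd)
    sum((iso$shift_bp - sat * iso$conc_nM / (kd + iso$conc_nM))^2)
  grid <- expand.grid(sat = seq(3, 4.5, length.out = 100),
                      kd = seq(8, 22, length.out = 100))
  expect_lte(fit$rss, min(mapply(rss, grid$sat, grid$kd)) + 1e-9)
})

test_that("hyperbolic fits of truly linear data reduce to the linear slope", {
  conc <- c(0.5, 1, 2, 3, 5)           # all well below any Kd of interest
  pts <- data.frame(conc_nM = conc, k = 0.02 * conc)
  hyp <- fit_capture_model(pts, model = "hyperbolic")
  expect_rel(hyp$kon_eff_low_conc, 0.02, 0.02)
})
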