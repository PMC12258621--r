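test_that("equilibrium constants are ratios with exact reciprocals", {
  k <- c(CI = 0.03, IC = 0.006, IO = 0.1, OI = 0.1)
  K <- equilibrium_constants(k)
  expect_equal(K[["CI"]], 5)
  expect_equal(K[["IC"]], 1 / 5)
  expect_equal(K[["IO"]], 1)
  expect_equal(K[["CI"]] * K[["IC"]], 1)
  expect_warning(equilibrium_constants(c(CI = 0.03, IC = 0)), "undefined")
})

test_that("free energies follow -ln K and reject nonpositive constants", {
  expect_equal(free_energy(1), 0)
  expect_equal(free_energy(exp(1)), -1)
  expect_equal(free_energy(c(CI = 5)), c(CI = -log(5)))
  expect_error(free_energy(0), "> 0")
  expect_error(free_energy(-2), "> 0")
})

test_that("antisymmetry of pairwise free energies holds to machine precision", {
  k <- c(CI = 0.0412, IC = 0.187, IO = 0.093, OI = 0.121)
  K <- equilibrium_constants(k)
  g <- free_energy(K)
  expect_equal(g[["CI"]], -g[["IC"]], tolerance = 1e-14)
  expect_equal(g[["IO"]], -g[["OI"]], tolerance = 1e-14)
})

test_that("equilibrium constants close the loop on a detailed-balance generator", {
  # K_CI * K_IO * K_OC = 1 by construction: 2 * 2 * 0.25
  kci <- 0.2; kic <- 0.1; kio <- 0.2; koi <- 0.1; kco <- 0.2; koc <- 0.05
  K_exact <- (kci / kic) * (kio / koi) * (koc / kco)
  expect_equal(K_exact, 1)
  cfg <- sim_config(kci = kci_fixed(kci), k_ic = kic, k_io = kio,
                    k_oi = koi, k_co = kco, k_oc = koc,
                    duration = 20000, seed = 111)
  rs <- estimate_rates(seq_from_path(simulate_state_path(cfg)))
  K <- suppressWarnings(equilibrium_constants(rs))
  loop <- K[["CI"]] * K[["IO"]] * K[["OC"]]
  expect_lt(abs(log(loop)), 0.2)   # ~ >1200 events per rate at this duration
})

test_that("the printed fold-differences compose to about 8 kBT", {
  ddg <- delta_delta_g(fold_kopen = 50 / 0.06, fold_kic = 5)
  expect_equal(ddg, log(833.33) + log(5), tolerance = 1e-3)
  expect_equal(ddg, 8.3, tolerance = 0.05)
  expect_equal(round(ddg), 8)
})

test_that("landscape wells accumulate -ln K along the capture path", {
  ls <- build_landscape(kd_init = 10, kopen = 0.06, k_ic = 0.2,
                        k_io = 0.1, k_oi = 0.1, conc_nM = 100)
  e <- function(nm) landscape_energy(ls, nm)
  expect_equal(e("Cfree"), 0)
  expect_equal(e("Cbound"), -log(100 / 10))
  expect_equal(e("I") - e("Cbound"), -log(0.06 / 0.2))
  expect_equal(e("O") - e("I"), -log(0.1 / 0.1))
  # barriers sit -ln(k_forward) + C above the preceding well
  expect_equal(e("Cbound-I") - e("Cbound"), -log(0.06) + 7)
  expect_equal(e("Cfree-Cbound"), -log(0.1 * 100) + 7)
})

test_that("doubling the concentration lowers only the binding step by ln 2", {
  l1 <- build_landscape(kd_init = 10, kopen = 0.06, k_ic = 0.2,
                        k_io = 0.1, k_oi = 0.1, conc_nM = 100)
  l2 <- build_landscape(kd_init = 10, kopen = 0.06, k_ic = 0.2,
                        k_io = 0.1, k_oi = 0.1, conc_nM = 200)
  d_bind <- (landscape_energy(l2, "Cbound") - landscape_energy(l2, "Cfree")) -
    (landscape_energy(l1, "Cbound") - landscape_energy(l1, "Cfree"))
  expect_equal(d_bind, -log(2))
  expect_equal(landscape_energy(l2, "I") - landscape_energy(l2, "Cbound"),
               landscape_energy(l1, "I") - landscape_energy(l1, "Cbound"))
  expect_equal(landscape_energy(l2, "O") - landscape_energy(l2, "I"),
               landscape_energy(l1, "O") - landscape_energy(l1, "I"))
})

test_that("well spacing is invariant under uniform rate rescaling", {
  base <- build_landscape(kd_init = 10, kopen = 0.06, k_ic = 0.2,
                          k_io = 0.1, k_oi = 0.1)
  scl <- build_landscape(kd_init = 10, kopen = 0.6, k_ic = 2,
                         k_io = 1, k_oi = 1)
  for (pair in list(c("Cbound", "I"), c("I", "O")))
    expect_equal(landscape_energy(scl, pair[2]) -
                   landscape_energy(scl, pair[1]),
                 landscape_energy(base, pair[2]) -
                   landscape_energy(base, pair[1]))
  # C-referenced barriers shift by exactly -log(scale)
  expect_equal((landscape_energy(scl, "Cbound-I") -
                  landscape_energy(scl, "Cbound")) -
                 (landscape_energy(base, "Cbound-I") -
                    landscape_energy(base, "Cbound")),
               -log(10))
})

test_that("two parameter regimes order the wells as expected", {
  trapped <- build_landscape(kd_init = 10, kopen = 0.06, k_ic = 0.2,
                             k_io = 0.1, k_oi = 0.1, conc_nM = 100)
  fast <- build_landscape(kd_init = 1000, kopen = 50, k_ic = 0.04,
                          k_io = 0.1, k_oi = 0.1, conc_nM = 100)
  # the trapped enzyme binds deeper and faces a higher unwinding barrier
  expect_lt(landscape_energy(trapped, "Cbound"),
            landscape_energy(fast, "Cbound"))
  gap_trapped <- landscape_energy(trapped, "I") -
    landscape_energy(trapped, "Cbound")
  gap_fast <- landscape_energy(fast, "I") - landscape_energy(fast, "Cbound")
  expect_equal(gap_trapped - gap_fast, log(50 / 0.06) + log(0.2 / 0.04))
  expect_equal(gap_trapped - gap_fast, 8.3, tolerance = 0.05)
})

test_that("missing landscape parameters are reported by name", {
  expect_error(build_landscape(kd_init = 10, kopen = 0.06),
               "k_ic.*k_io.*k_oi")
  expect_error(build_landscape(kd_init = -1, kopen = 0.06, k_ic = 0.2,
                               k_io = 0.1, k_oi = 0.1), "> 0")
})

test_that("a symmetric scheme at matched concentration is flat across wells", {
  ls <- build_landscape(kd_init = 50, kopen = 0.1, k_ic = 0.1,
                        k_io = 0.1, k_oi = 0.1, conc_nM = 50)
  wells <- ls$table[ls$table$kind == "well", "energy_kBT"]
  expect_equal(wells, rep(0, 4))
})
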