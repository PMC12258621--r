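#' Concentration laws for the closed-to-intermediate rate
#'
#' The rate at which a relaxed (closed) target is converted into the R-loop
#' intermediate depends on the free RNP concentration. Three laws are
#' supported: `kci_linear()` for enzymes far from binding saturation
#' (rate = kon_eff * [RNP]), `kci_hyperbolic()` for enzymes whose initial
#' binding saturates (rate = kopen * [RNP] / (Kd_init + [RNP])), and
#' `kci_fixed()` for a concentration-independent rate.
#'
#' @param kon_eff effective bimolecular capture rate, per nM per s.
#' @param kopen maximal unwinding rate at binding saturation, per s.
#' @param kd_init dissociation constant of the initial binding complex, nM.
#' @param k fixed closed-to-intermediate rate, per s.
#' @return an object of class `kci_law`.
#' @seealso [kci_rate()] to evaluate a law at a concentration.
#' @export
kci_linear <- function(kon_eff) {
  stopifnot(is.numeric(kon_eff), length(kon_eff) == 1L, kon_eff >= 0)
  structure(list(type = "linear", kon_eff = kon_eff), class = "kci_law")
}

#' @rdname kci_linear
#' @export
kci_hyperbolic <- function(kopen, kd_init) {
  stopifnot(is.numeric(kopen), kopen >= 0, is.numeric(kd_init), kd_init > 0)
  structure(list(type = "hyperbolic", kopen = kopen, kd_init = kd_init),
            class = "kci_law")
}

#' @rdname kci_linear
#' @export
kci_fixed <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  structure(list(type = "fixed", k = k), class = "kci_law")
}

#' Evaluate a closed-to-intermediate rate law at a concentration
#'
#' @param law a [kci_linear()], [kci_hyperbolic()] or [kci_fixed()] object.
#' @param conc_nM RNP concentration in nM (vectorised).
#' @return rate(s) in s^-1.
#' @export
kci_rate <- function(law, conc_nM) {
  stopifnot(inherits(law, "kci_law"), all(conc_nM >= 0))
  switch(law$type,
    linear     = law$kon_eff * conc_nM,
    hyperbolic = law$kopen * conc_nM / (law$kd_init + conc_nM),
    fixed      = rep(law$k, length(conc_nM))
  )
}

#' Langmuir baseline shift for non-specific binding
#'
#' Prolonged non-specific binding manifests as a constant additive offset of
#' the twist baseline whose magnitude follows a Langmuir isotherm in RNP
#' concentration: shift = delta_theta_sat * [RNP] / (Kd_eff + [RNP]).
#'
#' @param delta_theta_sat saturating baseline shift, bp unwound.
#' @param kd_eff effective dissociation constant, nM.
#' @return an object of class `langmuir_shift`.
#' @export
langmuir_shift <- function(delta_theta_sat, kd_eff) {
  stopifnot(is.numeric(delta_theta_sat), is.numeric(kd_eff), kd_eff > 0)
  structure(list(delta_theta_sat = delta_theta_sat, kd_eff = kd_eff),
            class = "langmuir_shift")
}

#' Simulation configuration for synthetic rotor-bead twist traces
#'
#' Describes a three-state (closed C / intermediate I / open O) continuous-time
#' Markov chain over DNA unwinding levels, observed through an
#' Ornstein-Uhlenbeck angular noise process. Defaults follow the reference
#' experimental conditions: states at 0 / 10 / 20 bp unwound, helicity
#' 10.5 bp/turn, and analysis-rate sampling at 500 Hz.
#'
#' @param kci law for the closed-to-intermediate rate (see [kci_linear()]).
#' @param k_ic,k_io,k_oi,k_co,k_oc remaining transition rates, per s. Direct
#'   closed/open exchange (`k_co`, `k_oc`) defaults to 0 because such
#'   transitions are rare.
#' @param levels_bp named numeric vector of unwinding levels per state, bp;
#'   the closed level must be 0.
#' @param helicity DNA helicity, bp per turn.
#' @param ou_kappa angular mean-reversion rate of the noise process, per s.
#' @param ou_sigma stationary SD of the observed twist signal, bp.
#' @param sample_rate sampling rate, Hz.
#' @param duration trace duration, s.
#' @param rnp_conc RNP concentration, nM.
#' @param baseline_shift optional [langmuir_shift()] modelling non-specific
#'   binding as a constant additive offset, or `NULL`.
#' @param enzyme free-text enzyme label carried into trace metadata.
#' @param seed integer seed making every simulated output reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(kci = kci_hyperbolic(0.06, 10),
                       k_ic = 0.2, k_io = 0.1, k_oi = 0.1,
                       k_co = 0, k_oc = 0,
                       levels_bp = c(C = 0, I = 10, O = 20),
                       helicity = 10.5,
                       ou_kappa = 800, ou_sigma = 1.5,
                       sample_rate = 500,
                       duration = 60,
                       rnp_conc = 4,
                       baseline_shift = NULL,
                       enzyme = "synthetic",
                       seed = NULL) {
  rates <- c(k_ic = k_ic, k_io = k_io, k_oi = k_oi, k_co = k_co, k_oc = k_oc)
  if (any(rates < 0)) stop("all transition rates must be >= 0")
  if (!inherits(kci, "kci_law")) stop("'kci' must be a kci_law object")
  stopifnot(helicity > 0, sample_rate > 0, ou_kappa > 0, ou_sigma >= 0,
            duration >= 0, rnp_conc >= 0)
  if (!all(c("C", "I", "O") %in% names(levels_bp)))
    stop("levels_bp must name states C, I and O")
  if (levels_bp[["C"]] != 0) stop("the closed level must be 0 bp")
  if (!is.null(baseline_shift) && !inherits(baseline_shift, "langmuir_shift"))
    stop("'baseline_shift' must be a langmuir_shift object or NULL")
  structure(list(kci = kci, k_ic = k_ic, k_io = k_io, k_oi = k_oi,
                 k_co = k_co, k_oc = k_oc,
                 levels_bp = levels_bp[c("C", "I", "O")], helicity = helicity,
                 ou_kappa = ou_kappa, ou_sigma = ou_sigma,
                 sample_rate = sample_rate, duration = duration,
                 rnp_conc = rnp_conc, baseline_shift = baseline_shift,
                 enzyme = enzyme, seed = seed),
            class = "sim_config")
}

#' Generator matrix of the three-state chain at the configured concentration
#'
#' @param config a [sim_config()].
#' @return 3x3 rate matrix (rows: from-state; off-diagonal entries k_ij,
#'   diagonal minus the exit rate).
#' @export
generator_matrix <- function(config) {
  kci <- kci_rate(config$kci, config$rnp_conc)
  Q <- matrix(0, 3, 3, dimnames = list(c("C", "I", "O"), c("C", "I", "O")))
  Q["C", "I"] <- kci;         Q["C", "O"] <- config$k_co
  Q["I", "C"] <- config$k_ic; Q["I", "O"] <- config$k_io
  Q["O", "I"] <- config$k_oi; Q["O", "C"] <- config$k_oc
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the three-state chain
#'
#' Solved by linear algebra from the generator matrix; used as the analytic
#' reference for occupancy checks on long simulated paths.
#'
#' @param config a [sim_config()].
#' @return named probability vector over C, I, O.
#' @export
stationary_distribution <- function(config) {
  Q <- generator_matrix(config)
  A <- rbind(t(Q), rep(1, 3))
  pi <- qr.solve(A, c(0, 0, 0, 1))
  names(pi) <- rownames(Q)
  pi
}

#' Simulate the latent state path of the three-state chain
#'
#' Gillespie simulation: exponential waiting times with the total exit rate of
#' the current state, successor chosen proportionally to the outgoing rates.
#' The chain starts in the closed state, matching experiments where RNP is
#' flowed onto relaxed DNA. A state with zero exit rate is absorbing and ends
#' event generation.
#'
#' @param config a [sim_config()].
#' @param seed optional seed; defaults to the config seed.
#' @return an object of class `state_path` with entry times (first = 0),
#'   state labels and the total duration.
#' @export
simulate_state_path <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  Q <- generator_matrix(config)
  labels <- rownames(Q)
  state <- 1L  # closed
  times <- 0
  states <- labels[state]
  t <- 0
  repeat {
    out <- Q[state, ]
    out[state] <- 0
    exit <- sum(out)
    if (exit <= 0) break          # absorbing state
    t <- t + stats::rexp(1, exit)
    if (t >= config$duration) break
    state <- sample.int(3L, 1L, prob = out)
    times <- c(times, t)
    states <- c(states, labels[state])
  }
  structure(list(times = times, states = states, duration = config$duration),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat("State path:", length(x$states), "states over", x$duration, "s\n")
  cat("  visits:", paste(names(table(x$states)), table(x$states),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Observe a state path through Ornstein-Uhlenbeck angular noise
#'
#' The observed twist signal relaxes toward the unwinding level of the active
#' state with rate `ou_kappa` and stationary SD `ou_sigma`. Discretisation is
#' the exact AR(1) form
#' theta[n+1] = mu + (theta[n] - mu) * exp(-kappa dt)
#'            + sigma * sqrt(1 - exp(-2 kappa dt)) * eps[n],
#' so there is no Euler error at any sampling rate. Any Langmuir baseline
#' shift in the config is added as a constant offset. Units are bp unwound
#' (positive = unwinding).
#'
#' @param path a [simulate_state_path()] result.
#' @param config the same [sim_config()] used to generate the path.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @return a [twist_trace()].
#' @export
simulate_trace <- function(path, config, seed = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(config, "sim_config"))
  if (!isTRUE(all.equal(path$duration, config$duration)))
    stop("path and config must share the same duration")
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate
  dt <- 1 / fs
  n <- round(config$duration * fs)
  offset <- baseline_offset(config)
  if (n == 0L) {
    return(twist_trace(theta = numeric(0), sample_rate = fs,
                       metadata = trace_metadata(config)))
  }
  tt <- (seq_len(n) - 1) * dt
  if (length(path$times) > 1L) {
    dwells <- diff(c(path$times, path$duration))
    # exponential dwells occasionally dip below dt even for slow kinetics;
    # flag only configurations whose typical dwell is unresolvable
    if (mean(dwells) < 10 * dt || mean(dwells < dt) > 0.01)
      warning("state dwells comparable to the sampling interval; ",
              "fast events will be aliased")
  }
  idx <- findInterval(tt, path$times)
  mu <- unname(config$levels_bp[path$states[idx]]) + offset
  if (config$ou_sigma == 0) {
    theta <- mu
  } else {
    a <- exp(-config$ou_kappa * dt)
    sig_e <- config$ou_sigma * sqrt(1 - a^2)
    eps <- stats::rnorm(n)
    theta1 <- mu[1] + config$ou_sigma * eps[1]  # stationary start
    if (n > 1L) {
      innov <- (1 - a) * mu[-1] + sig_e * eps[-1]
      theta <- c(theta1,
                 as.numeric(stats::filter(innov, a, method = "recursive",
                                          init = theta1)))
    } else theta <- theta1
  }
  twist_trace(theta = theta, sample_rate = fs, time = tt,
              metadata = trace_metadata(config))
}

#' Simulate a complete twist trace (path plus observation) from a config
#'
#' Seeds the generator once from `config$seed` so that the latent path and the
#' observation noise come from a single reproducible stream.
#'
#' @param config a [sim_config()].
#' @return a [twist_trace()] with the latent path attached as attribute
#'   `"path"`.
#' @export
simulate_twist_trace <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  path <- simulate_state_path(config, seed = NULL)
  trace <- simulate_trace(path, config, seed = NULL)
  attr(trace, "path") <- path
  trace
}

baseline_offset <- function(config) {
  if (is.null(config$baseline_shift)) return(0)
  bs <- config$baseline_shift
  bs$delta_theta_sat * config$rnp_conc / (bs$kd_eff + config$rnp_conc)
}

trace_metadata <- function(config) {
  list(enzyme = config$enzyme, conc_nM = config$rnp_conc,
       sample_rate = config$sample_rate, seed = config$seed)
}

#' Simulate a concentration series of twist traces
#'
#' One trace per concentration, with the closed-to-intermediate rate evaluated
#' from the configured linear or hyperbolic law at that concentration. Each
#' trace records its concentration in the metadata; per-trace seeds are
#' derived from the config seed.
#'
#' @param config a [sim_config()] whose `kci` law is linear or hyperbolic.
#' @param concentrations RNP concentrations, nM.
#' @return list of [twist_trace()] objects.
#' @export
simulate_concentration_series <- function(config, concentrations) {
  stopifnot(inherits(config, "sim_config"))
  if (config$kci$type == "fixed")
    stop("a concentration series needs a linear or hyperbolic rate law")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  lapply(seq_along(concentrations), function(i) {
    cfg <- config
    cfg$rnp_conc <- concentrations[i]
    if (!is.null(config$seed)) cfg$seed <- config$seed + i
    simulate_twist_trace(cfg)
  })
}

## ---- bulk-assay generative twins -------------------------------------------

#' Simulate bulk-assay datasets
#'
#' Generative twins of the bulk quantifications: cleavage time courses
#' (`"cleavage"`), 2-aminopurine fluorescence courses (`"twoap"`), twist
#' baseline-shift binding isotherms (`"binding"`), droplet digital PCR counts
#' (`"droplets"`) and footprinting gel lanes (`"gel"`). The noiseless
#' expectation obeys the corresponding closed form exactly; noise is additive
#' Gaussian for tabular data and Poisson for droplet counts.
#'
#' @param kind one of `"cleavage"`, `"twoap"`, `"binding"`, `"droplets"`,
#'   `"gel"`.
#' @param params named list of parameters passed to the matching
#'   `simulate_*` function.
#' @param seed optional integer seed.
#' @return a data frame (or named counts for `"droplets"`).
#' @export
simulate_bulk <- function(kind = c("cleavage", "twoap", "binding",
                                   "droplets", "gel"),
                          params, seed = NULL) {
  kind <- match.arg(kind)
  fun <- switch(kind,
    cleavage = simulate_cleavage_course,
    twoap    = simulate_2ap_course,
    binding  = simulate_binding_isotherm,
    droplets = simulate_droplet_counts,
    gel      = simulate_gel_lanes)
  do.call(fun, c(params, list(seed = seed)))
}

#' @describeIn simulate_bulk fraction-cleaved time course
#'   y = a_fast (1 - exp(-k_fast t)) + a_slow (1 - exp(-k_slow t)).
#' @param times sampling times (minutes for cleavage, seconds for 2AP).
#' @param a_fast,k_fast,a_slow,k_slow amplitudes (fractions) and rate
#'   constants of the two phases.
#' @param sd Gaussian noise SD.
#' @export
simulate_cleavage_course <- function(times, a_fast, k_fast,
                                     a_slow = 0, k_slow = 0,
                                     sd = 0, seed = NULL) {
  if (a_fast < 0 || a_fast > 1 || a_slow < 0 || a_slow > 1 ||
      a_fast + a_slow > 1)
    stop("amplitudes of a fraction-cleaved curve must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  y <- a_fast * (1 - exp(-k_fast * times)) +
       a_slow * (1 - exp(-k_slow * times))
  if (sd > 0) y <- y + stats::rnorm(length(times), sd = sd)
  data.frame(t = times, y = y)
}

#' @describeIn simulate_bulk 2-aminopurine fluorescence course
#'   y = y0 + ymax (1 - exp(-kobs t)).
#' @param y0,ymax,kobs control-level intercept, fitted amplitude and observed
#'   rate constant of the fluorescence rise.
#' @export
simulate_2ap_course <- function(times, y0, ymax, kobs, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- y0 + ymax * (1 - exp(-kobs * times))
  if (sd > 0) y <- y + stats::rnorm(length(times), sd = sd)
  data.frame(t = times, y = y)
}

#' @describeIn simulate_bulk per-tether baseline-shift isotherm
#'   shift = delta_theta_sat [RNP] / (kd_eff + [RNP]) + noise.
#' @param concentrations RNP concentrations, nM.
#' @param delta_theta_sat,kd_eff Langmuir parameters (bp, nM).
#' @param n_tethers tethers measured per concentration.
#' @export
simulate_binding_isotherm <- function(concentrations, delta_theta_sat, kd_eff,
                                      sd = 0, n_tethers = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(concentrations, each = n_tethers)
  shift <- delta_theta_sat * conc / (kd_eff + conc)
  if (sd > 0) shift <- shift + stats::rnorm(length(conc), sd = sd)
  data.frame(conc_nM = conc,
             tether = rep(seq_len(n_tethers), times = length(concentrations)),
             shift_bp = shift)
}

#' @describeIn simulate_bulk droplet counts for double-strand-break
#'   quantification. Reference droplets are Poisson with mean `lambda`; target
#'   droplets are Poisson with mean `lambda * (1 - f_dsb)` (a cut allele does
#'   not amplify the target amplicon).
#' @param f_dsb true fraction of broken alleles.
#' @param lambda expected reference droplet count.
#' @export
simulate_droplet_counts <- function(f_dsb, lambda, seed = NULL) {
  stopifnot(f_dsb >= 0, f_dsb <= 1, lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  c(n_target = stats::rpois(1, lambda * (1 - f_dsb)),
    n_reference = stats::rpois(1, lambda))
}

#' @describeIn simulate_bulk footprinting gel band volumes. Builds a
#'   permanganate-treated and a control lane whose per-band cleavage
#'   probabilities differ by `p_ox`; volumes are probabilities scaled to
#'   `total_volume` with additive Gaussian noise, truncated at zero.
#' @param p_cleave_minus control-lane cleavage probabilities (sum to 1).
#' @param p_ox per-band oxidation probabilities (sum to 0 across bands).
#' @param total_volume total lane volume in densitometry units.
#' @export
simulate_gel_lanes <- function(p_cleave_minus, p_ox, total_volume = 1e4,
                               sd = 0, seed = NULL) {
  stopifnot(length(p_ox) == length(p_cleave_minus),
            abs(sum(p_cleave_minus) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  plus <- p_cleave_minus + p_ox
  if (any(plus < 0)) stop("p_cleave_minus + p_ox must be nonnegative")
  noisy <- function(p) pmax(0, p * total_volume +
                              if (sd > 0) stats::rnorm(length(p), sd = sd)
                              else 0)
  data.frame(band = seq_along(p_ox),
             volume_plus_pm = noisy(plus),
             volume_minus_pm = noisy(p_cleave_minus))
}
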