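#' Reference simulation configurations for the two enzymes
#'
#' Bundled generative parameter sets used throughout the examples and the
#' reproduction runs. The dSpRY set uses the hyperbolic capture law
#' (kopen 0.06 /s, Kd_init 10 nM) with a Langmuir non-specific baseline
#' shift (3.7 bp saturating, Kd_eff 14 nM); the dCas9 set uses the linear
#' law (kon_eff 0.15 /nM/s) and five-fold slower intermediate collapse. The
#' intermediate/open exchange rates (0.1 /s each way) and the collapse rates
#' are package choices on the seconds scale of the observed intermediate
#' kinetics; see the methods vignette.
#'
#' @param enzyme `"dSpRY"` or `"dCas9"`.
#' @param ... overrides passed on to [sim_config()].
#' @return a [sim_config()].
#' @export
reference_config <- function(enzyme = c("dSpRY", "dCas9"), ...) {
  enzyme <- match.arg(enzyme)
  defaults <- if (enzyme == "dSpRY") {
    list(kci = kci_hyperbolic(kopen = 0.06, kd_init = 10),
         k_ic = 0.2, k_io = 0.1, k_oi = 0.1,
         baseline_shift = langmuir_shift(3.7, 14),
         rnp_conc = 4, enzyme = "dSpRY")
  } else {
    list(kci = kci_linear(kon_eff = 0.15),
         k_ic = 0.04, k_io = 0.1, k_oi = 0.1,
         rnp_conc = 0.8, enzyme = "dCas9")
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Full-chain analysis of a simulated concentration series
#'
#' Runs the complete single-molecule pipeline: simulate a twist trace per
#' concentration, calibrate the OU noise model on an RNP-free baseline
#' trace, segment each trace by change-point analysis, cluster the levels
#' into C/I/O states, re-zero to the predominant closed state (recording the
#' subtracted offset, i.e. the non-specific baseline shift), re-cluster,
#' estimate transition rates, and fit the concentration dependence of k_CI.
#'
#' @param config a [sim_config()] with a linear or hyperbolic capture law.
#' @param concentrations RNP concentrations, nM.
#' @param duration trace duration per concentration, s.
#' @param seed integer seed for the whole run.
#' @param model capture-model choice passed to [fit_capture_model()].
#' @param boundaries C/I/O cluster boundaries, bp.
#' @param control a [seg_control()].
#' @param baseline_duration RNP-free baseline length for OU calibration, s.
#' @return an object of class `capture_series`: per-concentration rate
#'   table, baseline offsets, the OU calibration, the capture fit and the
#'   per-concentration rate sets.
#' @export
run_capture_series <- function(config, concentrations,
                               duration = 1800, seed = 1,
                               model = "auto",
                               boundaries = c(4, 15),
                               control = seg_control(),
                               baseline_duration = 60) {
  stopifnot(inherits(config, "sim_config"))
  base_cfg <- config
  base_cfg$kci <- kci_fixed(0)
  base_cfg$baseline_shift <- NULL
  base_cfg$duration <- baseline_duration
  base_cfg$seed <- seed
  ou <- calibrate_ou(simulate_twist_trace(base_cfg))
  rows <- list()
  rate_sets <- list()
  offsets <- numeric(length(concentrations))
  for (i in seq_along(concentrations)) {
    cfg <- config
    cfg$rnp_conc <- concentrations[i]
    cfg$duration <- duration
    cfg$seed <- seed + i
    trace <- simulate_twist_trace(cfg)
    seg <- segment_trace(trace, ou, control)
    states0 <- cluster_cio(seg, boundaries)
    seg <- rezero(seg, states0)
    offsets[i] <- attr(seg, "offset")
    states <- cluster_cio(seg, boundaries)
    rs <- estimate_rates(states)
    rs$metadata <- list(enzyme = cfg$enzyme, conc_nM = concentrations[i])
    rate_sets[[i]] <- rs
    kci <- get_rate(rs, "C", "I")
    rows[[i]] <- data.frame(conc_nM = concentrations[i], k = kci$rate,
                            se = kci$se, n = kci$n,
                            occupancy_s = kci$occupancy_s,
                            baseline_offset_bp = offsets[i])
  }
  tab <- do.call(rbind, rows)
  fit <- fit_capture_model(tab[, c("conc_nM", "k", "se")], model = model)
  structure(list(rates_table = tab, fit = fit, ou = ou,
                 rate_sets = rate_sets, boundaries = boundaries,
                 seed = seed, duration = duration, config = config),
            class = "capture_series")
}

#' @export
print.capture_series <- function(x, ...) {
  cat(sprintf(
    "Capture concentration series: %d concentrations, %g s each (seed %d)\n",
    nrow(x$rates_table), x$duration, x$seed))
  print(x$rates_table, row.names = FALSE, digits = 4)
  print(x$fit)
  invisible(x)
}

#' Run the staged analysis pipeline from a declarative configuration
#'
#' Orchestrates simulate -> segment -> states -> rates -> fit -> landscape as
#' configured, with one global seed propagated to all stochastic stages.
#' When `out_dir` is set, stage outputs are written as delimited tables and a
#' manifest records every file with its MD5 content hash; re-running with
#' the same configuration reproduces the hashes bit for bit.
#'
#' @param config a list with elements:
#'   `stages` (character subset of simulate, segment, states, rates, fit,
#'   landscape, in pipeline order), `seed`, optional `out_dir`, and optional
#'   per-stage blocks: `simulate` (`config`, `concentrations`, `duration`,
#'   `baseline_duration`), `segment` (`control`), `states` (`boundaries`),
#'   `fit` (`model`), `landscape` (`conc_nM`, `kon_init`, `barrier_offset`).
#' @return a `pipeline_run`: stage results plus a manifest of parameters,
#'   seed, package version and output-file hashes.
#' @export
run_pipeline <- function(config) {
  known <- c("simulate", "segment", "states", "rates", "fit", "landscape")
  stages <- config$stages %||% known
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  seed <- config$seed %||% 1L
  sim <- config$simulate %||% list()
  sim_cfg <- sim$config %||% reference_config("dSpRY")
  conc <- sim$concentrations %||% c(1, 2, 5, 10, 20, 50, 100)
  need_chain <- any(c("segment", "states", "rates", "fit") %in% stages)
  res <- list()
  if (need_chain) {
    series <- run_capture_series(
      sim_cfg, conc,
      duration = sim$duration %||% 300,
      seed = seed,
      model = (config$fit %||% list())$model %||% "auto",
      boundaries = (config$states %||% list())$boundaries %||% c(4, 15),
      control = (config$segment %||% list())$control %||% seg_control(),
      baseline_duration = sim$baseline_duration %||% 60)
    res$series <- series
  } else if ("simulate" %in% stages) {
    res$traces <- simulate_concentration_series(sim_cfg, conc)
  }
  if ("landscape" %in% stages) {
    ls_cfg <- config$landscape %||% list()
    fit <- res$series$fit
    if (!is.null(fit) && fit$model == "hyperbolic") {
      rs <- res$series$rate_sets[[length(res$series$rate_sets)]]
      res$landscape <- build_landscape(
        kd_init = fit$coefficients[["kd_init"]],
        kopen = fit$coefficients[["kopen"]],
        k_ic = get_rate(rs, "I", "C")$rate,
        k_io = get_rate(rs, "I", "O")$rate,
        k_oi = get_rate(rs, "O", "I")$rate,
        kon_init = ls_cfg$kon_init %||% 0.1,
        conc_nM = ls_cfg$conc_nM %||% 100,
        barrier_offset = ls_cfg$barrier_offset %||% 7)
    }
  }
  manifest <- list(stages = stages, seed = seed,
                  package_version = as.character(utils::packageVersion("rloopkin")),
                  parameters = list(concentrations = conc,
                                    enzyme = sim_cfg$enzyme),
                  files = data.frame(path = character(0),
                                     md5 = character(0)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (!is.null(res$series)) {
      p <- file.path(config$out_dir, "rates_by_concentration.tsv")
      utils::write.table(res$series$rates_table, p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(res$landscape)) {
      p <- file.path(config$out_dir, "landscape.tsv")
      write_landscape(res$landscape, p)
      paths <- c(paths, p)
    }
    if (length(paths))
      manifest$files <- data.frame(path = paths,
                                   md5 = unname(tools::md5sum(paths)))
  }
  structure(c(res, list(manifest = manifest)), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (stages:",
      paste(x$manifest$stages, collapse = ", "), ")\n")
  if (!is.null(x$series)) print(x$series)
  if (!is.null(x$landscape)) print(x$landscape)
  if (nrow(x$manifest$files)) {
    cat("Outputs:\n")
    print(x$manifest$files, row.names = FALSE)
  }
  invisible(x)
}

#' Seeded fixture set covering every analysis surface
#'
#' Small deterministic datasets for demonstration and testing: a short
#' three-state twist trace with its generative path, an RNP-free baseline, a
#' binding isotherm, cleavage and 2AP time courses, footprinting gel lanes
#' and droplet counts.
#'
#' @param seed integer seed (default 42).
#' @return named list of fixtures.
#' @export
make_fixtures <- function(seed = 42L) {
  fast <- reference_config("dSpRY", kci = kci_fixed(0.3), k_ic = 0.4,
                           k_io = 0.3, k_oi = 0.3, baseline_shift = NULL,
                           duration = 60, seed = seed)
  baseline <- reference_config("dSpRY", kci = kci_fixed(0),
                               baseline_shift = NULL, duration = 30,
                               seed = seed + 1L)
  list(trace = simulate_twist_trace(fast),
       baseline = simulate_twist_trace(baseline),
       isotherm = simulate_binding_isotherm(c(2, 5, 10, 25, 50, 100),
                                            delta_theta_sat = 3.7,
                                            kd_eff = 14, sd = 0.3,
                                            n_tethers = 5, seed = seed + 2L),
       cleavage = simulate_cleavage_course(
         times = c(0.25, 0.5, 1, 2, 3, 5, 7.5, 10, 15, 20, 30, 60),
         a_fast = 0.7, k_fast = 1.4, a_slow = 0.2, k_slow = 0.02,
         sd = 0.02, seed = seed + 3L),
       twoap = simulate_2ap_course(times = seq(0, 600, by = 20), y0 = 100,
                                   ymax = 50, kobs = 0.01, sd = 0.5,
                                   seed = seed + 4L),
       gel = simulate_gel_lanes(p_cleave_minus = c(0.1, 0.1, 0.1, 0.7),
                                p_ox = c(0.05, 0.02, -0.02, -0.05),
                                sd = 20, seed = seed + 5L),
       droplets = simulate_droplet_counts(f_dsb = 0.3, lambda = 5000,
                                          seed = seed + 6L))
}
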