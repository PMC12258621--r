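#' Estimate transition rate constants from a state sequence
#'
#' For each ordered state pair (i, j), the rate constant is the number of
#' observed i -> j transitions divided by the total time spent in state i,
#' with Poisson standard errors sqrt(N_ij) / T_i. Counting starts after the
#' first transition event (the first state of the sequence is discarded), so
#' the pre-binding waiting period does not dilute the closed-state occupancy.
#' Pairs with no observed transitions report rate 0 with a one-sided
#' standard error of 1 / T_i. States outside `states` (e.g. overwound) are
#' excluded from both counts and occupancy.
#'
#' @param seq a `state_sequence`.
#' @param states labels entering the kinetic scheme (default C, I, O).
#' @return an object of class `rate_set`: transition count matrix, occupancy
#'   vector, and a rates data frame (from, to, n, occupancy_s, rate, se).
#' @export
estimate_rates <- function(seq, states = c("C", "I", "O")) {
  stopifnot(inherits(seq, "state_sequence"))
  if (nrow(seq) < 3L)
    stop("need at least 2 transitions to estimate rates (have ",
         max(0L, nrow(seq) - 1L), ")")
  seq2 <- seq[-1L, , drop = FALSE]   # count from the first transition onward
  keep <- seq2$label %in% states
  occ <- tapply(seq2$dwell[keep], factor(seq2$label[keep], levels = states),
                sum, default = 0)
  occ[is.na(occ)] <- 0
  m <- nrow(seq2)
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  if (m >= 2L) {
    from <- seq2$label[-m]
    to <- seq2$label[-1L]
    ok <- from %in% states & to %in% states
    if (any(ok)) {
      tab <- table(factor(from[ok], levels = states),
                   factor(to[ok], levels = states))
      counts <- counts + unclass(tab)
    }
  }
  pairs <- expand.grid(from = states, to = states, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  rates <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$from[r]; j <- pairs$to[r]
    Ti <- occ[[i]]
    nij <- counts[i, j]
    data.frame(from = i, to = j, n = nij, occupancy_s = Ti,
               rate = if (Ti > 0) nij / Ti else NA_real_,
               se = if (Ti > 0) (if (nij > 0) sqrt(nij) / Ti else 1 / Ti)
                    else NA_real_)
  }))
  rownames(rates) <- NULL
  structure(list(counts = counts, occupancy = occ, rates = rates,
                 metadata = attr(seq, "metadata")),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Transition rate constants (per s, Poisson SE):\n")
  shown <- x$rates[x$rates$occupancy_s > 0, ]
  for (r in seq_len(nrow(shown)))
    cat(sprintf("  k_%s>%s = %.4g +/- %.2g  (N = %d over %.1f s)\n",
                shown$from[r], shown$to[r], shown$rate[r], shown$se[r],
                shown$n[r], shown$occupancy_s[r]))
  invisible(x)
}

#' Look up one rate from a rate set
#'
#' @param rates a `rate_set`.
#' @param from,to state labels.
#' @return named list with `rate`, `se`, `n`, `occupancy_s`.
#' @export
get_rate <- function(rates, from, to) {
  stopifnot(inherits(rates, "rate_set"))
  r <- rates$rates[rates$rates$from == from & rates$rates$to == to, ]
  if (nrow(r) != 1L) stop("no such transition: ", from, " -> ", to)
  as.list(r[1, c("rate", "se", "n", "occupancy_s")])
}

#' Fit the concentration dependence of the closed-to-intermediate rate
#'
#' Weighted least-squares fit of k_CI versus [RNP] under either a linear law
#' k = kon_eff * c (capture far from binding saturation) or a hyperbolic
#' saturation law k = kopen * c / (Kd_init + c) (two-step capture with
#' saturable initial binding). Weights are 1/se^2 when standard errors are
#' supplied. In `"auto"` mode the hyperbolic model is retained only when an
#' extra-sum-of-squares F-test against the linear model is significant at
#' `alpha`.
#'
#' A hyperbolic fit whose Kd_init exceeds 10x the largest concentration is
#' flagged: saturation was not observed, only the low-concentration slope
#' kon_eff = kopen / Kd_init is identifiable and kopen is a lower bound.
#'
#' @param points data frame with columns `conc_nM`, `k` (per s) and
#'   optionally `se`.
#' @param model `"linear"`, `"hyperbolic"` or `"auto"`.
#' @param alpha F-test level for auto selection (default 0.05).
#' @return an object of class `capture_fit` with coefficients, standard
#'   errors, covariance, fitted values, RSS and flags.
#' @export
fit_capture_model <- function(points, model = c("auto", "linear",
                                                "hyperbolic"),
                              alpha = 0.05) {
  model <- match.arg(model)
  stopifnot(all(c("conc_nM", "k") %in% names(points)))
  points <- as.data.frame(points)
  if (anyDuplicated(points$conc_nM))
    stop("concentrations must be distinct")
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 concentrations")
  w <- if ("se" %in% names(points) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else rep(1, n)
  lin <- fit_capture_linear(points, w)
  hyp <- NULL
  if (model != "linear") {
    if (n < 3L) {
      if (model == "hyperbolic")
        stop("need at least 3 concentrations for the hyperbolic model")
    } else hyp <- fit_capture_hyperbolic(points, w)
  }
  chosen <- switch(model,
    linear = "linear",
    hyperbolic = "hyperbolic",
    auto = {
      if (is.null(hyp)) "linear"
      else {
        f <- (lin$rss - hyp$rss) / max(hyp$rss / (n - 2), 1e-300)
        p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
        if (is.finite(p) && p < alpha) "hyperbolic" else "linear"
      }
    })
  fit <- if (chosen == "linear") lin else hyp
  flags <- character(0)
  if (chosen == "hyperbolic" &&
      fit$coefficients[["kd_init"]] > 10 * max(points$conc_nM))
    flags <- c(flags,
               "saturation not observed; only kon_eff identifiable, kopen is a lower bound")
  structure(c(fit, list(model = chosen, points = points, weights = w,
                        flags = flags,
                        alternatives = list(linear = lin, hyperbolic = hyp))),
            class = "capture_fit")
}

fit_capture_linear <- function(points, w) {
  c0 <- points$conc_nM; k <- points$k
  kon <- sum(w * c0 * k) / sum(w * c0^2)
  res <- k - kon * c0
  rss <- sum(w * res^2)
  sigma2 <- rss / max(1, length(k) - 1)
  se <- sqrt(sigma2 / sum(w * c0^2))
  list(coefficients = c(kon_eff = kon), se = c(kon_eff = se),
       vcov = matrix(se^2, 1, 1, dimnames = list("kon_eff", "kon_eff")),
       fitted = kon * c0, rss = rss, df_residual = length(k) - 1L)
}

## weighted Levenberg-Marquardt with multistart; returns par, weighted rss
## and a covariance from the Jacobian at the optimum (NA on a singular,
## i.e. unidentifiable, ridge)
lm_multistart <- function(resid_fun, starts, lower) {
  best <- NULL
  for (s in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun, lower = lower,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(out = out, rss = rss)
  }
  if (is.null(best)) stop("nonlinear least-squares fit failed to converge")
  n <- length(best$out$fvec)
  p <- length(best$out$par)
  sigma2 <- best$rss / max(1, n - p)
  vc <- tryCatch(sigma2 * solve(best$out$hessian),
                 error = function(e) matrix(NA_real_, p, p))
  list(par = best$out$par, rss = best$rss, vcov = vc,
       se = sqrt(pmax(diag(vc), 0)))
}

fit_capture_hyperbolic <- function(points, w) {
  conc <- points$conc_nM; k <- points$k; sw <- sqrt(w)
  resid_fun <- function(par) sw * (k - par[1] * conc / (par[2] + conc))
  kmax <- max(k)
  slope <- max(k / conc)
  kd_big <- 30 * max(conc)
  starts <- c(lapply(expand.grid(ko = kmax * c(1, 1.5, 3),
                                 kd = stats::median(conc) * c(0.3, 1, 3))
                     |> asplit(1), as.numeric),
              list(c(slope * kd_big, kd_big)))
  fit <- lm_multistart(resid_fun, starts, lower = c(1e-12, 1e-9))
  list(coefficients = c(kopen = fit$par[1], kd_init = fit$par[2]),
       se = c(kopen = fit$se[1], kd_init = fit$se[2]),
       vcov = fit$vcov,
       fitted = fit$par[1] * conc / (fit$par[2] + conc), rss = fit$rss,
       df_residual = length(k) - 2L,
       kon_eff_low_conc = fit$par[1] / fit$par[2])
}

#' @export
coef.capture_fit <- function(object, ...) object$coefficients

#' @export
print.capture_fit <- function(x, ...) {
  cat("Capture-model fit (", x$model, " law):\n", sep = "")
  cf <- x$coefficients
  se <- x$se
  if (x$model == "linear") {
    cat(sprintf("  k_CI = kon_eff * [RNP];  kon_eff = %.4g +/- %.2g /nM/s\n",
                cf[["kon_eff"]], se[["kon_eff"]]))
  } else {
    cat(sprintf(
      "  k_CI = kopen [RNP] / (Kd_init + [RNP]);  kopen = %.4g +/- %.2g /s, Kd_init = %.4g +/- %.2g nM\n",
      cf[["kopen"]], se[["kopen"]], cf[["kd_init"]], se[["kd_init"]]))
    cat(sprintf("  low-concentration slope kopen/Kd_init = %.4g /nM/s\n",
                x$kon_eff_low_conc))
  }
  cat(sprintf("  weighted RSS %.4g on %d residual df\n", x$rss,
              x$df_residual))
  for (f in x$flags) cat("  flag: ", f, "\n", sep = "")
  invisible(x)
}

#' @export
summary.capture_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
predict.capture_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$points$conc_nM else newdata$conc_nM
  cf <- object$coefficients
  if (object$model == "linear") cf[["kon_eff"]] * conc
  else cf[["kopen"]] * conc / (cf[["kd_init"]] + conc)
}

#' Interpret a hyperbolic capture fit as a two-step binding/unwinding model
#'
#' Under a rapid-equilibrium first step (Cfree <-> Cbound with dissociation
#' constant Kd_init), the observed closed-to-intermediate rate is
#' k_CI([RNP]) = kopen * [RNP] / (Kd_init + [RNP]). Given an assumed
#' association rate kon_init, the implied dissociation rate is
#' koff_init = kon_init * Kd_init and the low-concentration effective on-rate
#' is kopen / Kd_init.
#'
#' @param fit a hyperbolic [fit_capture_model()] result.
#' @param kon_init assumed association rate of the initial binding step,
#'   per nM per s (default 0.1).
#' @return an object of class `two_step_model`.
#' @export
two_step_interpret <- function(fit, kon_init = 0.1) {
  stopifnot(inherits(fit, "capture_fit"))
  if (fit$model != "hyperbolic")
    stop("two-step interpretation requires a hyperbolic fit")
  kd <- fit$coefficients[["kd_init"]]
  kopen <- fit$coefficients[["kopen"]]
  structure(list(kd_init = kd, kopen = kopen, kon_init = kon_init,
                 koff_init = kon_init * kd,
                 kon_eff_low_conc = kopen / kd,
                 assumption = "rapid equilibrium of the initial binding step"),
            class = "two_step_model")
}

#' @export
print.two_step_model <- function(x, ...) {
  cat("Two-step capture model (Cfree <-> Cbound <-> I):\n")
  cat(sprintf("  Kd_init = %.4g nM (kon_init %.3g /nM/s assumed => koff_init %.4g /s)\n",
              x$kd_init, x$kon_init, x$koff_init))
  cat(sprintf("  kopen = %.4g /s; low-[RNP] slope kopen/Kd_init = %.4g /nM/s\n",
              x$kopen, x$kon_eff_low_conc))
  cat("  assumes", x$assumption, "\n")
  invisible(x)
}

#' Predicted lumped k_CI from a two-step model
#'
#' @param object a `two_step_model`.
#' @param newdata data frame with `conc_nM`.
#' @param ... unused.
#' @return k_CI at the requested concentrations, per s.
#' @export
predict.two_step_model <- function(object, newdata, ...) {
  object$kopen * newdata$conc_nM / (object$kd_init + newdata$conc_nM)
}

#' Langmuir fit of concentration-dependent baseline twist shifts
#'
#' Weighted nonlinear least-squares fit of the binding isotherm
#' shift([RNP]) = delta_theta_sat * [RNP] / (KD + [RNP]), yielding the
#' saturating shift and the effective dissociation constant of non-specific
#' binding.
#'
#' @param points data frame with columns `conc_nM`, `shift_bp` and
#'   optionally `se`.
#' @return an object of class `langmuir_fit` with coefficients
#'   `delta_theta_sat` (bp) and `kd` (nM), standard errors and flags.
#' @export
langmuir_fit <- function(points) {
  stopifnot(all(c("conc_nM", "shift_bp") %in% names(points)))
  points <- as.data.frame(points)
  if (length(unique(points$conc_nM)) < 3L)
    stop("need at least 3 distinct concentrations")
  w <- if ("se" %in% names(points) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else rep(1, nrow(points))
  flags <- character(0)
  if (max(abs(points$shift_bp)) < 1e-8) {
    flags <- c(flags, "all shifts ~ 0; KD unidentifiable")
    return(structure(list(coefficients = c(delta_theta_sat = 0,
                                           kd = NA_real_),
                          se = c(delta_theta_sat = NA_real_, kd = NA_real_),
                          vcov = matrix(NA_real_, 2, 2), rss = 0,
                          points = points, flags = flags),
                     class = "langmuir_fit"))
  }
  conc <- points$conc_nM; y <- points$shift_bp; sw <- sqrt(w)
  resid_fun <- function(par) sw * (y - par[1] * conc / (par[2] + conc))
  ymax <- max(abs(y)) * sign(y[which.max(abs(y))])
  starts <- c(lapply(expand.grid(sat = ymax * c(1, 1.5),
                                 kd = stats::median(conc) * c(0.3, 1, 3))
                     |> asplit(1), as.numeric),
              list(c(ymax, 30 * max(conc))))
  fit <- lm_multistart(resid_fun, starts, lower = c(-Inf, 1e-9))
  structure(list(coefficients = c(delta_theta_sat = fit$par[1],
                                  kd = fit$par[2]),
                 se = c(delta_theta_sat = fit$se[1], kd = fit$se[2]),
                 vcov = fit$vcov, rss = fit$rss, points = points,
                 flags = flags),
            class = "langmuir_fit")
}

#' @export
coef.langmuir_fit <- function(object, ...) object$coefficients

#' @export
print.langmuir_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "Langmuir isotherm fit: delta_theta_sat = %.4g +/- %.2g bp, KD = %.4g +/- %.2g nM\n",
    cf[["delta_theta_sat"]], x$se[["delta_theta_sat"]], cf[["kd"]],
    x$se[["kd"]]))
  for (f in x$flags) cat("  flag: ", f, "\n", sep = "")
  invisible(x)
}

#' @export
predict.langmuir_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$points$conc_nM else newdata$conc_nM
  cf <- object$coefficients
  cf[["delta_theta_sat"]] * conc / (cf[["kd"]] + conc)
}
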