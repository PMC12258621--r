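#' Calibrate Ornstein-Uhlenbeck noise parameters from a baseline trace
#'
#' The angular noise around a constant twist level is modelled as an
#' Ornstein-Uhlenbeck process, which at a fixed sampling interval dt is an
#' AR(1) process with coefficient a = exp(-kappa dt) and stationary SD
#' sigma_stat. Both parameters are fixed globally from a baseline portion of
#' the trace recorded before any RNP is introduced: kappa from the lag-1
#' autocorrelation (kappa = -log(a)/dt) and sigma_stat from the sample SD.
#'
#' @param baseline a single-level [twist_trace()] (no binding events);
#'   10^4 samples or more recommended.
#' @param kappa_cap upper bound on the reported kappa (per s); a near-zero
#'   autocorrelation (white-noise limit) hits the cap with a warning.
#' @return an object of class `ou_params` with fields `kappa`, `sigma_stat`,
#'   `dt`, `a` and standard errors.
#' @export
calibrate_ou <- function(baseline, kappa_cap = 10 / (1 / baseline$sample_rate)) {
  stopifnot(inherits(baseline, "twist_trace"))
  x <- baseline$theta
  n <- length(x)
  if (n < 100L) stop("baseline too short to calibrate (need >= 100 samples)")
  dt <- 1 / baseline$sample_rate
  s <- stats::sd(x)
  if (s == 0) stop("constant baseline: sigma_stat = 0, model misfit")
  a <- stats::cor(x[-n], x[-1])
  if (a >= 1) stop("lag-1 autocorrelation >= 1: model misfit")
  if (a <= 2 / sqrt(n)) {
    # indistinguishable from white noise at this sampling rate
    warning("lag-1 autocorrelation not significantly positive; noise is ",
            "white at this sampling rate, kappa capped at ",
            signif(kappa_cap, 3), " /s")
    a <- exp(-kappa_cap * dt)
  }
  kappa <- min(-log(a) / dt, kappa_cap)
  se_a <- sqrt((1 - a^2) / n)
  se_kappa <- se_a / (a * dt)          # delta method on -log(a)/dt
  n_eff <- n * (1 - a) / (1 + a)
  se_sigma <- s / sqrt(2 * max(n_eff, 2))
  structure(list(kappa = kappa, sigma_stat = s, dt = dt, a = a,
                 se_kappa = se_kappa, se_sigma = se_sigma, n = n),
            class = "ou_params")
}

#' Construct OU parameters directly
#'
#' @param kappa mean-reversion rate, per s.
#' @param sigma_stat stationary SD, bp.
#' @param dt sampling interval, s.
#' @return an `ou_params` object.
#' @export
ou_params <- function(kappa, sigma_stat, dt) {
  stopifnot(kappa > 0, sigma_stat >= 0, dt > 0)
  structure(list(kappa = kappa, sigma_stat = sigma_stat, dt = dt,
                 a = exp(-kappa * dt), se_kappa = NA_real_,
                 se_sigma = NA_real_, n = NA_integer_),
            class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf(
    "OU noise: kappa %.4g /s (a = %.4f at dt %.4g s), sigma_stat %.4g bp\n",
    x$kappa, x$a, x$dt, x$sigma_stat))
  if (is.finite(x$se_kappa))
    cat(sprintf("  SE(kappa) %.3g /s, SE(sigma) %.3g bp, n = %d\n",
                x$se_kappa, x$se_sigma, x$n))
  invisible(x)
}

#' Segmentation control parameters
#'
#' @param fp_per_100s calibration target: expected false change points per
#'   100 s of pure-noise trace (default 0.1).
#' @param min_len minimum segment length in samples (default 5; 10 ms at
#'   500 Hz, well below the 100-ms dwell censor used downstream).
#' @param threshold optional fixed generalized-likelihood-ratio threshold;
#'   when `NULL` it is calibrated by Monte Carlo (see
#'   [calibrate_threshold()]).
#' @param nsim null simulations used for threshold calibration.
#' @param calib_seed seed for the calibration simulations (kept separate from
#'   analysis seeds so cached thresholds are reproducible).
#' @return an object of class `seg_control`.
#' @export
seg_control <- function(fp_per_100s = 0.1, min_len = 5L, threshold = NULL,
                        nsim = 1000L, calib_seed = 20131L) {
  stopifnot(fp_per_100s > 0, min_len >= 2L, nsim >= 10L)
  structure(list(fp_per_100s = fp_per_100s, min_len = as.integer(min_len),
                 threshold = threshold, nsim = as.integer(nsim),
                 calib_seed = calib_seed),
            class = "seg_control")
}

## residual sum of squares of centred AR(1) innovations over index ranges
## given cumulative sums; range p..q (1-based into d), length m = q - p + 1
range_rss <- function(cs, cs2, p, q) {
  m <- q - p + 1
  s1 <- cs[q + 1] - cs[p]
  s2 <- cs2[q + 1] - cs2[p]
  pmax(0, s2 - s1^2 / m)
}

## GLR scan over all admissible split points of segment x[i..j].
## dv[k] = x[k+1] - a x[k] (k = 1..n-1) is the innovation into sample k+1;
## segment [i, j] uses innovations k = i..j-1 under the null and, under a
## split at s (last sample of the left part), k = i..s-1 plus k = s+1..j-1
## (each sub-segment conditions on its own first sample, so the crossing
## innovation k = s drops out of the alternative).
glr_scan <- function(cs, cs2, i, j, min_len, sig_e2) {
  s_lo <- i + min_len - 1L
  s_hi <- j - min_len
  if (s_hi < s_lo) return(NULL)
  s <- s_lo:s_hi
  rss0 <- range_rss(cs, cs2, i, j - 1L)
  rss_l <- range_rss(cs, cs2, i, s - 1L)
  rss_r <- range_rss(cs, cs2, s + 1L, j - 1L)
  gain <- rss0 - rss_l - rss_r
  # the cumulative-sum recurrences cancel catastrophically on near-constant
  # data; gains at the round-off floor of the segment's second moment are not
  # evidence of a change point
  floor_gain <- 64 * .Machine$double.eps * (cs2[j] - cs2[i] + 1)
  gain[gain <= floor_gain] <- 0
  list(s = s, stat = gain / sig_e2)
}

#' Monte-Carlo calibration of the change-point acceptance threshold
#'
#' Simulates pure AR(1) noise with the calibrated OU parameters and records
#' the maximum generalized-likelihood-ratio statistic of a single-split scan
#' over blocks of `block_s` seconds. The threshold is the null quantile at
#' which the expected number of falsely accepted splits matches
#' `fp_per_100s`. Results are cached per (block length, AR coefficient,
#' min_len, fp target).
#'
#' @param ou an [ou_params()] object.
#' @param control a [seg_control()].
#' @param block_s calibration block length, s (default 100).
#' @return the calibrated threshold (scalar).
#' @export
calibrate_threshold <- function(ou, control = seg_control(), block_s = 100) {
  stopifnot(inherits(ou, "ou_params"))
  if (!is.null(control$threshold)) return(control$threshold)
  n <- max(4L * control$min_len, as.integer(round(block_s / ou$dt)))
  key <- paste(n, round(ou$a, 4), control$min_len, control$fp_per_100s,
               control$nsim, sep = "|")
  cached <- .threshold_cache[[key]]
  if (!is.null(cached)) return(cached)
  a <- ou$a
  maxstat <- numeric(control$nsim)
  rng <- preserve_rng()
  on.exit(restore_rng(rng))
  set.seed(control$calib_seed)
  for (b in seq_len(control$nsim)) {
    eps <- stats::rnorm(n)
    x <- as.numeric(stats::filter(sqrt(1 - a^2) * eps[-1], a,
                                  method = "recursive", init = eps[1]))
    x <- c(eps[1], x)  # unit stationary variance; scale cancels in the GLR
    d <- x[-1] - a * x[-n]
    cs <- c(0, cumsum(d))
    cs2 <- c(0, cumsum(d^2))
    sc <- glr_scan(cs, cs2, 1L, n, control$min_len, 1 - a^2)
    maxstat[b] <- max(sc$stat)
  }
  # rare-event matching: P(false split per block) = fp target scaled to block
  p_block <- min(0.5, control$fp_per_100s * (n * ou$dt) / 100)
  thr <- stats::quantile(maxstat, probs = 1 - p_block, names = FALSE,
                         type = 8)
  .threshold_cache[[key]] <- thr
  thr
}

.threshold_cache <- new.env(parent = emptyenv())

preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Segment a twist trace into constant-mean levels under OU noise
#'
#' Models the trace as a piecewise-constant-mean AR(1) process with globally
#' fixed noise parameters; the only free parameters are the per-segment mean
#' level and the change-point times (level slopes are fixed to zero). Change
#' points are placed by recursive binary splitting: each candidate split's
#' generalized likelihood-ratio statistic is compared against a threshold
#' calibrated by Monte Carlo on the null OU model, and accepted splits are
#' recursed into. Per-segment means are their conditional maximum-likelihood
#' estimates. The likelihood conditions on the first sample of each segment,
#' removing any dependence on pre-segment history.
#'
#' @param trace a [twist_trace()] at the analysis rate.
#' @param ou [ou_params()] calibrated at the same sampling rate.
#' @param control a [seg_control()].
#' @return an object of class `segmented_trace`: change times, a segment
#'   table (start_s, end_s, n, duration, mean_bp) and the model
#'   log-likelihood.
#' @export
segment_trace <- function(trace, ou, control = seg_control()) {
  stopifnot(inherits(trace, "twist_trace"), inherits(ou, "ou_params"),
            inherits(control, "seg_control"))
  if (abs(ou$dt - 1 / trace$sample_rate) > 1e-9 * ou$dt)
    stop("OU parameters were calibrated at a different sampling rate")
  x <- trace$theta
  n <- length(x)
  a <- ou$a
  sig_e2 <- max(ou$sigma_stat^2 * (1 - a^2), .Machine$double.xmin)
  min_len <- control$min_len
  splits <- integer(0)
  if (n >= 2L * min_len) {
    thr <- calibrate_threshold(ou, control,
                               block_s = min(100, n * ou$dt))
    d <- x[-1] - a * x[-n]
    cs <- c(0, cumsum(d))
    cs2 <- c(0, cumsum(d^2))
    stack <- list(c(1L, n))
    while (length(stack)) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      sc <- glr_scan(cs, cs2, seg[1], seg[2], min_len, sig_e2)
      if (is.null(sc)) next
      k <- which.max(sc$stat)
      if (sc$stat[k] > thr) {
        s <- sc$s[k]
        splits <- c(splits, s)
        stack <- c(stack, list(c(seg[1], s)), list(c(s + 1L, seg[2])))
      }
    }
    splits <- sort(splits)
  }
  starts <- c(1L, splits + 1L)  # each split index = last sample on the left
  ends <- c(splits, n)
  means <- numeric(length(starts))
  loglik <- 0
  for (g in seq_along(starts)) {
    i <- starts[g]; j <- ends[g]
    if (j > i) {
      dseg <- x[(i + 1L):j] - a * x[i:(j - 1L)]
      means[g] <- mean(dseg) / (1 - a)
      r <- dseg - mean(dseg)
      loglik <- loglik - 0.5 * (sum(r^2) / sig_e2 +
                                  length(r) * log(2 * pi * sig_e2))
    } else means[g] <- x[i]
  }
  seg_tab <- data.frame(start_s = trace$time[starts],
                        end_s = trace$time[ends] + 1 / trace$sample_rate,
                        n = ends - starts + 1L,
                        duration = (ends - starts + 1L) / trace$sample_rate,
                        mean_bp = means)
  structure(list(change_times = if (length(starts) > 1L)
                   trace$time[starts[-1L]] else numeric(0),
                 segments = seg_tab, loglik = loglik,
                 ou = ou, control = control,
                 sample_rate = trace$sample_rate,
                 metadata = trace$metadata),
            class = "segmented_trace")
}

#' @export
print.segmented_trace <- function(x, ...) {
  cat(sprintf("Segmented trace: %d segments, %d change points, logLik %.1f\n",
              nrow(x$segments), length(x$change_times), x$loglik))
  print(utils::head(x$segments, 10))
  if (nrow(x$segments) > 10) cat("...\n")
  invisible(x)
}

#' Idealized (piecewise-constant) trace from a segmentation
#'
#' @param seg a `segmented_trace`.
#' @param trace the trace it was scored on (for the time base).
#' @return a [twist_trace()] holding the fitted level at each sample.
#' @export
idealized_trace <- function(seg, trace) {
  stopifnot(inherits(seg, "segmented_trace"), inherits(trace, "twist_trace"))
  idx <- findInterval(trace$time, seg$segments$start_s)
  twist_trace(theta = seg$segments$mean_bp[idx],
              sample_rate = trace$sample_rate, time = trace$time,
              unit = trace$unit, metadata = trace$metadata)
}

#' Exact single-change-point scan by brute force
#'
#' Reference implementation used as an oracle: for every admissible split
#' position the AR(1) profile likelihood is computed directly (per-segment
#' mean re-estimated by `mean()` over the innovations), without the
#' cumulative-sum recurrences of [segment_trace()].
#'
#' @param x numeric trace samples.
#' @param ou an [ou_params()].
#' @param min_len minimum segment length in samples.
#' @return list with the brute-force best split index (last sample of the
#'   left segment) and the statistic profile.
#' @export
brute_force_scan <- function(x, ou, min_len = 5L) {
  n <- length(x)
  a <- ou$a
  sig_e2 <- ou$sigma_stat^2 * (1 - a^2)
  rss <- function(i, j) {           # innovations of x[i..j], conditioning on x[i]
    if (j <= i) return(0)
    dseg <- x[(i + 1):j] - a * x[i:(j - 1)]
    sum((dseg - mean(dseg))^2)
  }
  s <- (min_len):(n - min_len)
  stat <- vapply(s, function(si)
    (rss(1, n) - rss(1, si) - rss(si + 1, n)) / sig_e2, numeric(1))
  list(s = s, stat = stat, best = s[which.max(stat)])
}

#' Write segments as a delimited table
#'
#' @param seg a `segmented_trace`.
#' @param path output file path (tab-separated: start_s, end_s, mean_bp).
#' @return the path, invisibly.
#' @export
write_segments <- function(seg, path) {
  utils::write.table(seg$segments[, c("start_s", "end_s", "mean_bp")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
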