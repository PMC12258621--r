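#' State sequence container
#'
#' A merged, labelled sequence of biophysical states. Each row carries the
#' cluster label, the lifetime-weighted mean unwinding delta_theta0 (bp), the
#' total dwell (s) and the start/end times of the merged state.
#'
#' @param label character labels.
#' @param delta_theta0 mean unwinding per state, bp.
#' @param dwell dwell time per state, s.
#' @param start,end state start and end times, s.
#' @return an object of class `state_sequence` (also a data frame).
#' @export
state_sequence <- function(label, delta_theta0, dwell, start, end) {
  df <- data.frame(label = as.character(label),
                   delta_theta0 = delta_theta0, dwell = dwell,
                   start = start, end = end)
  stopifnot(all(df$dwell > 0))
  class(df) <- c("state_sequence", "data.frame")
  df
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("State sequence: %d merged states over %.1f s\n",
              nrow(x), sum(x$dwell)))
  occ <- tapply(x$dwell, x$label, sum)
  cat("  occupancy:",
      paste(sprintf("%s %.1f s", names(occ), occ), collapse = ", "), "\n")
  NextMethod()
}

#' @export
plot.state_sequence <- function(x, ...) {
  graphics::plot(x$dwell, x$delta_theta0, log = "x",
                 xlab = "dwell (s)", ylab = expression(Delta * theta[0] ~ (bp)),
                 col = as.factor(x$label), ...)
  graphics::legend("topright", legend = levels(as.factor(x$label)),
                   col = seq_along(levels(as.factor(x$label))), pch = 1)
  invisible(x)
}

## merge runs of identical labels: dwell-weighted mean level, summed dwell
merge_states <- function(df) {
  if (nrow(df) == 0L) return(df)
  run <- cumsum(c(TRUE, df$label[-1] != df$label[-nrow(df)]))
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), run), function(i) {
    data.frame(label = df$label[i[1]],
               delta_theta0 = stats::weighted.mean(df$delta_theta0[i],
                                                   df$dwell[i]),
               dwell = sum(df$dwell[i]),
               start = df$start[i[1]],
               end = df$end[i[length(i)]])
  }))
  rownames(out) <- NULL
  class(out) <- c("state_sequence", "data.frame")
  out
}

segments_to_df <- function(seg) {
  stopifnot(inherits(seg, "segmented_trace"))
  data.frame(delta_theta0 = seg$segments$mean_bp,
             dwell = seg$segments$duration,
             start = seg$segments$start_s,
             end = seg$segments$end_s)
}

#' Classify segments from short-match experiments as closed / unwound
#'
#' For experiments with only a few matching guide bases, the DNA is labelled
#' "unwound" when the mean rotor-bead position of a segment exceeds the
#' threshold (default 1 bp), "overwound" when it is below minus the
#' threshold, and "closed" otherwise. Consecutive same-label segments are
#' merged; the merged unwinding is the lifetime-weighted mean of contributing
#' segments and the merged dwell their sum.
#'
#' @param seg a `segmented_trace` re-zeroed to the closed baseline (or any
#'   `state_sequence`).
#' @param threshold classification threshold, bp (default 1).
#' @return a `state_sequence` with labels closed / unwound / overwound.
#' @export
classify_short_match <- function(seg, threshold = 1.0) {
  df <- if (inherits(seg, "segmented_trace")) segments_to_df(seg)
        else seg[, c("delta_theta0", "dwell", "start", "end")]
  df$label <- ifelse(df$delta_theta0 > threshold, "unwound",
                     ifelse(df$delta_theta0 < -threshold, "overwound",
                            "closed"))
  merge_states(df[, c("label", "delta_theta0", "dwell", "start", "end")])
}

#' Cluster segments into closed / intermediate / open states
#'
#' Labels each level by its unwinding: C when delta_theta0 <= b1, I when
#' b1 < delta_theta0 <= b2, O above b2 (ties go to the lower cluster).
#' Segments overwound past `overwound_below` are labelled "overwound" and are
#' excluded from C/I/O kinetics downstream. Consecutive same-label segments
#' are merged as in [classify_short_match()].
#'
#' Default boundaries (4, 15) bp sit midway between the observed level
#' clusters at 0, ~8-10 and ~20-21 bp unwound.
#'
#' @param seg a `segmented_trace` with re-zeroed levels.
#' @param boundaries numeric `(b1, b2)` cluster boundaries, bp.
#' @param overwound_below levels below this (bp) are kept as a separate
#'   "overwound" label (default -1).
#' @return a `state_sequence` with labels C / I / O (and possibly overwound).
#' @export
cluster_cio <- function(seg, boundaries = c(4, 15), overwound_below = -1) {
  if (boundaries[1] >= boundaries[2])
    stop("boundaries must satisfy b1 < b2")
  df <- if (inherits(seg, "segmented_trace")) segments_to_df(seg)
        else seg[, c("delta_theta0", "dwell", "start", "end")]
  lvl <- df$delta_theta0
  df$label <- ifelse(lvl < overwound_below, "overwound",
                     ifelse(lvl <= boundaries[1], "C",
                            ifelse(lvl <= boundaries[2], "I", "O")))
  merge_states(df[, c("label", "delta_theta0", "dwell", "start", "end")])
}

#' Lifetime-weighted population histogram of state levels
#'
#' Bins the merged states by their unwinding and reports the dwell fraction
#' per bin (fractions sum to 1).
#'
#' @param seq a `state_sequence`.
#' @param bin bin width, bp (default 0.5).
#' @return data frame with bin midpoints (`bin_mid`) and dwell fractions
#'   (`fraction`).
#' @export
population_histogram <- function(seq, bin = 0.5) {
  stopifnot(inherits(seq, "state_sequence"), bin > 0)
  if (nrow(seq) == 0L)
    return(data.frame(bin_mid = numeric(0), fraction = numeric(0)))
  idx <- floor(seq$delta_theta0 / bin)
  w <- tapply(seq$dwell, idx, sum)
  data.frame(bin_mid = (as.numeric(names(w)) + 0.5) * bin,
             fraction = as.numeric(w) / sum(seq$dwell))
}

#' Left-censored exponential-mixture dwell-time fit
#'
#' Maximum-likelihood fit of dwell times to a one- or two-component
#' exponential mixture, left-censored at `tmin` (events shorter than the
#' censor are unresolvable and are excluded; the likelihood uses the density
#' conditioned on t >= tmin). The two-component likelihood is maximised by
#' multistart quasi-Newton optimisation over (logit p, log k1, log k2); a
#' mixture pinned to the boundary (p -> 0 or 1) collapses to one component
#' with a message.
#'
#' @param dwells dwell times, s.
#' @param tmin left-censoring time, s (default 0.1, i.e. 100 ms).
#' @param components 1 or 2.
#' @return an object of class `dwell_fit`: `p_fast`, `k_fast`, `k_slow`
#'   (per s; equal for a single component), `censor_tmin`, `loglik`, `n`.
#' @export
dwell_mle <- function(dwells, tmin = 0.1, components = 2L) {
  stopifnot(components %in% c(1L, 2L))
  t <- dwells[dwells >= tmin]
  if (length(t) < 10L)
    stop("need at least 10 dwells above the censor to fit (have ",
         length(t), ")")
  if (components == 1L) {
    k <- 1 / (mean(t) - tmin)       # closed-form censored-exponential MLE
    ll <- sum(log(k) - k * (t - tmin))
    return(structure(list(p_fast = 1, k_fast = k, k_slow = k,
                          censor_tmin = tmin, loglik = ll,
                          n = length(t), components = 1L),
                     class = "dwell_fit"))
  }
  nll <- function(par) {
    p <- stats::plogis(par[1]); k1 <- exp(par[2]); k2 <- exp(par[3])
    f <- p * k1 * exp(-k1 * t) + (1 - p) * k2 * exp(-k2 * t)
    S <- p * exp(-k1 * tmin) + (1 - p) * exp(-k2 * tmin)
    -sum(log(pmax(f, 1e-300))) + length(t) * log(max(S, 1e-300))
  }
  k0 <- 1 / (mean(t) - tmin)
  starts <- list(c(0, log(k0 * 5), log(k0 / 5)),
                 c(1, log(k0 * 10), log(k0 / 2)),
                 c(-1, log(k0 * 2), log(k0 / 10)),
                 c(0, log(k0 * 3), log(k0)),
                 c(0.5, log(k0 * 20), log(k0 / 3)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, nll, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("dwell-time optimisation failed to converge")
  p <- stats::plogis(best$par[1])
  k1 <- exp(best$par[2]); k2 <- exp(best$par[3])
  if (k1 < k2) { tmp <- k1; k1 <- k2; k2 <- tmp; p <- 1 - p }
  # a component decayed to ~0 by the censor time never contributes an
  # observable dwell, so its rate (and weight) are unidentifiable
  fast_unobservable <- tmin > 0 && k1 * tmin > 7
  if (p < 0.01 || p > 0.99 || fast_unobservable) {
    message("mixture component pinned at a boundary or unobservable past ",
            "the censor; collapsing to a single exponential")
    return(dwell_mle(dwells, tmin, components = 1L))
  }
  structure(list(p_fast = p, k_fast = k1, k_slow = k2,
                 censor_tmin = tmin, loglik = -best$value,
                 n = length(t), components = 2L),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  if (x$components == 1L) {
    cat(sprintf("Censored exponential dwell fit: k = %.4g /s (n = %d, censor %g s)\n",
                x$k_fast, x$n, x$censor_tmin))
  } else {
    cat(sprintf(
      "Censored double-exponential dwell fit (n = %d, censor %g s):\n",
      x$n, x$censor_tmin))
    cat(sprintf("  p_fast %.3f, k_fast %.4g /s, k_slow %.4g /s\n",
                x$p_fast, x$k_fast, x$k_slow))
  }
  cat(sprintf("  logLik %.2f\n", x$loglik))
  invisible(x)
}

#' @export
coef.dwell_fit <- function(object, ...) {
  c(p_fast = object$p_fast, k_fast = object$k_fast, k_slow = object$k_slow)
}

#' Simulate dwell times from a fitted (or specified) exponential mixture
#'
#' @param object a `dwell_fit`.
#' @param nsim number of dwells.
#' @param seed optional seed.
#' @param ... unused.
#' @return numeric dwell times (uncensored).
#' @export
simulate.dwell_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fast <- stats::runif(nsim) < object$p_fast
  stats::rexp(nsim, ifelse(fast, object$k_fast, object$k_slow))
}

#' Write a state table as delimited text
#'
#' @param seq a `state_sequence`.
#' @param path output path (tab-separated: start_s, end_s, label,
#'   delta_theta0_bp, dwell_s).
#' @return the path, invisibly.
#' @export
write_states <- function(seq, path) {
  out <- data.frame(start_s = seq$start, end_s = seq$end, label = seq$label,
                    delta_theta0_bp = seq$delta_theta0, dwell_s = seq$dwell)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
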