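#' Twist trace container
#'
#' A uniformly sampled rotor-bead twist series. `theta` is stored in bp
#' unwound by convention (positive = unwinding); traces fresh from
#' [xy_to_angle()] are in turns until converted with [angle_to_bp()], with the
#' unit recorded in the metadata.
#'
#' @param theta twist samples.
#' @param sample_rate sampling rate, Hz.
#' @param time optional time stamps, s; regenerated from the sample rate when
#'   omitted.
#' @param zero_reference total offset (bp) already subtracted from the trace.
#' @param unit `"bp"` or `"turns"`.
#' @param metadata named list (enzyme, conc_nM, seed, ...).
#' @return an object of class `twist_trace`.
#' @export
twist_trace <- function(theta, sample_rate, time = NULL, zero_reference = 0,
                        unit = "bp", metadata = list()) {
  stopifnot(is.numeric(theta), sample_rate > 0, all(is.finite(theta)))
  if (is.null(time)) time <- (seq_along(theta) - 1) / sample_rate
  stopifnot(length(time) == length(theta))
  structure(list(time = time, theta = theta, sample_rate = sample_rate,
                 zero_reference = zero_reference, unit = unit,
                 metadata = metadata),
            class = "twist_trace")
}

#' @export
print.twist_trace <- function(x, ...) {
  cat(sprintf("Twist trace: %d samples at %g Hz (%.3f s), unit %s\n",
              length(x$theta), x$sample_rate,
              length(x$theta) / x$sample_rate, x$unit))
  if (length(x$theta))
    cat(sprintf("  mean %.3f, sd %.3f, zero reference %.3f\n",
                mean(x$theta), stats::sd(x$theta), x$zero_reference))
  if (!is.null(x$metadata$conc_nM))
    cat(sprintf("  enzyme %s at %g nM\n",
                x$metadata$enzyme %||% "?", x$metadata$conc_nM))
  invisible(x)
}

#' @export
plot.twist_trace <- function(x, downsample = 1L, ...) {
  i <- seq(1L, length(x$theta), by = max(1L, as.integer(downsample)))
  graphics::plot(x$time[i], x$theta[i], type = "l", xlab = "time (s)",
                 ylab = paste0("twist (", x$unit, " unwound)"), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raw bead trajectory container
#'
#' @param time time stamps, s (uniform).
#' @param x,y detector-plane bead positions.
#' @return an object of class `xy_trajectory`.
#' @export
xy_trajectory <- function(time, x, y) {
  stopifnot(length(time) == length(x), length(x) == length(y),
            !anyNA(time), !anyNA(x), !anyNA(y))
  if (length(time) > 2) {
    dt <- diff(time)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("trajectory must be uniformly sampled with no missing samples")
  }
  structure(list(time = time, x = x, y = y), class = "xy_trajectory")
}

#' @export
print.xy_trajectory <- function(x, ...) {
  cat(sprintf("Bead trajectory: %d samples over %.3f s\n",
              length(x$time), diff(range(x$time))))
  invisible(x)
}

## conic (ellipse) centre by algebraic least squares; circle / centroid
## fallbacks for degenerate windows
fit_window_center <- function(x, y) {
  n <- length(x)
  if (n < 5L) return(NULL)
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  S <- crossprod(D)
  v <- tryCatch(eigen(S, symmetric = TRUE)$vectors[, 6L],
                error = function(e) NULL)
  if (!is.null(v)) {
    a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]; e <- v[5]
    disc <- b^2 - 4 * a * cc
    if (is.finite(disc) && disc < -1e-12 * (a^2 + b^2 + cc^2)) {
      ctr <- tryCatch(solve(matrix(c(2 * a, b, b, 2 * cc), 2, 2), -c(d, e)),
                      error = function(e) NULL)
      if (!is.null(ctr) && all(is.finite(ctr)))
        return(c(mx + ctr[1], my + ctr[2]))
    }
  }
  # circle fallback (Kasa fit): x^2 + y^2 + D x + E y + F = 0
  A <- cbind(xs, ys, 1)
  rhs <- -(xs^2 + ys^2)
  co <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (!is.null(co) && all(is.finite(co)))
    return(c(mx - co[1] / 2, my - co[2] / 2))
  NULL
}

#' Per-window drift correction of a bead trajectory
#'
#' Slow drift of the rotation centre is removed by fitting an ellipse
#' (algebraic least squares, with a circle fallback when the conic is
#' ill-determined) to each window of the x-y trajectory and subtracting the
#' fitted centre from that window's points. Windows too small or degenerate
#' for a conic fit fall back to the window centroid with a warning.
#'
#' @param traj an [xy_trajectory()].
#' @param window window length, s (default 1).
#' @return a drift-corrected [xy_trajectory()] of the same length.
#' @export
drift_correct <- function(traj, window = 1.0) {
  stopifnot(inherits(traj, "xy_trajectory"), window > 0)
  t0 <- traj$time - traj$time[1]
  win <- floor(t0 / window)
  # fold a trailing sliver (e.g. the single sample at an exact end time)
  # into the last full window
  win <- pmin(win, max(0, ceiling(max(t0) / window) - 1))
  x <- traj$x; y <- traj$y
  fell_back <- FALSE
  for (w in unique(win)) {
    i <- which(win == w)
    ctr <- fit_window_center(traj$x[i], traj$y[i])
    if (is.null(ctr)) {
      ctr <- c(mean(traj$x[i]), mean(traj$y[i]))
      fell_back <- TRUE
    }
    x[i] <- x[i] - ctr[1]
    y[i] <- y[i] - ctr[2]
  }
  if (fell_back)
    warning("some windows were too small or degenerate for a conic fit; ",
            "centroid subtraction used there")
  xy_trajectory(traj$time, x, y)
}

#' Convert a drift-corrected trajectory to an unwrapped angle trace
#'
#' Four-quadrant inverse tangent of each (x, y) pair, unwrapped so that
#' successive samples never jump by more than half a turn. Samples at exactly
#' (0, 0) propagate the previous angle (with a message). The result is in
#' turns; convert to bp unwound with [angle_to_bp()].
#'
#' @param traj an [xy_trajectory()] (drift-corrected).
#' @return a [twist_trace()] with unit `"turns"`.
#' @export
xy_to_angle <- function(traj) {
  stopifnot(inherits(traj, "xy_trajectory"))
  zero <- traj$x == 0 & traj$y == 0
  ang <- atan2(traj$y, traj$x)
  if (any(zero)) {
    message(sum(zero), " sample(s) at the origin; previous angle propagated")
    if (zero[1]) ang[1] <- 0
    for (i in which(zero)) if (i > 1) ang[i] <- ang[i - 1]
  }
  dt <- 1 / stats::median(diff(traj$time))
  turns <- unwrap_angle(ang) / (2 * pi)
  twist_trace(theta = turns - turns[1], sample_rate = dt, time = traj$time,
              unit = "turns")
}

#' Unwrap a wrapped angle series (radians)
#'
#' Adds multiples of 2*pi so that successive samples never differ by more
#' than pi; for noise-free inputs the total excursion equals the winding
#' number of the underlying path.
#'
#' @param ang angles in radians.
#' @return unwrapped angles, radians.
#' @export
unwrap_angle <- function(ang) {
  if (length(ang) < 2L) return(ang)
  d <- diff(ang)
  d <- d - 2 * pi * round(d / (2 * pi))  # wrap each step into (-pi, pi]
  ang[1] + c(0, cumsum(d))
}

#' Convert between turns and bp unwound
#'
#' Unwinding reduces the twist stored in the tether, so the sign convention is
#' bp_unwound = -turns * helicity: positive values mean unwound DNA.
#'
#' @param turns,bp angle in turns / unwinding in bp.
#' @param helicity DNA helicity, bp per turn (default 10.5).
#' @return the converted numeric vector.
#' @export
turns_to_bp <- function(turns, helicity = 10.5) -turns * helicity

#' @rdname turns_to_bp
#' @export
bp_to_turns <- function(bp, helicity = 10.5) -bp / helicity

#' Convert an angle trace (turns) to bp unwound
#'
#' @param trace a [twist_trace()] with unit `"turns"`.
#' @param helicity DNA helicity, bp per turn.
#' @return the trace with `theta` in bp unwound and unit `"bp"`.
#' @export
angle_to_bp <- function(trace, helicity = 10.5) {
  stopifnot(inherits(trace, "twist_trace"))
  if (trace$unit != "turns") stop("trace is not in turns")
  trace$theta <- turns_to_bp(trace$theta, helicity)
  trace$unit <- "bp"
  trace$metadata$helicity <- helicity
  trace
}

#' Low-pass filter and decimate a twist trace
#'
#' Boxcar mean over non-overlapping blocks (e.g. 5 kHz to 500 Hz averages
#' blocks of 10 samples). The kernel preserves level means exactly, which is
#' what matters for piecewise-constant twist levels; trailing samples that do
#' not fill a block are dropped.
#'
#' @param trace a [twist_trace()].
#' @param target_rate output rate, Hz (default 500); must divide the sample
#'   rate.
#' @return the filtered [twist_trace()] at `target_rate`.
#' @export
filter_trace <- function(trace, target_rate = 500) {
  stopifnot(inherits(trace, "twist_trace"))
  if (target_rate > trace$sample_rate)
    stop("target_rate must not exceed the sample rate")
  fac <- trace$sample_rate / target_rate
  if (abs(fac - round(fac)) > 1e-8)
    stop("target_rate must divide the sample rate")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(trace)
  n <- (length(trace$theta) %/% fac) * fac
  m <- matrix(trace$theta[seq_len(n)], nrow = fac)
  theta <- colMeans(m)
  time <- colMeans(matrix(trace$time[seq_len(n)], nrow = fac))
  twist_trace(theta = theta, sample_rate = target_rate, time = time,
              zero_reference = trace$zero_reference, unit = trace$unit,
              metadata = trace$metadata)
}

#' Re-zero a trace (or its segments) to the predominant closed state
#'
#' Subtracts the lifetime-weighted mean level of the closed-cluster states so
#' that the predominant closed state sits at 0 bp. The subtracted offset is
#' recorded (attribute `"offset"` and the `zero_reference` field); it is
#' itself the non-specific baseline shift used by the binding analysis.
#'
#' @param x a [twist_trace()], `segmented_trace` or `state_sequence`.
#' @param states a `state_sequence` scored on the same trace, containing at
#'   least one closed-cluster state.
#' @param ... unused.
#' @return `x` shifted so the closed level is 0, with attribute `"offset"`.
#' @export
rezero <- function(x, states, ...) UseMethod("rezero")

closed_offset <- function(states) {
  stopifnot(inherits(states, "state_sequence"))
  i <- states$label %in% c("C", "closed")
  if (!any(i))
    stop("no closed-cluster state found; cannot re-zero ",
         "(labels present: ", paste(unique(states$label), collapse = ", "),
         ")")
  stats::weighted.mean(states$delta_theta0[i], states$dwell[i])
}

#' @export
rezero.twist_trace <- function(x, states, ...) {
  off <- closed_offset(states)
  x$theta <- x$theta - off
  x$zero_reference <- x$zero_reference + off
  attr(x, "offset") <- off
  x
}

#' @export
rezero.segmented_trace <- function(x, states, ...) {
  off <- closed_offset(states)
  x$segments$mean_bp <- x$segments$mean_bp - off
  attr(x, "offset") <- off
  x
}

#' @export
rezero.state_sequence <- function(x, states = x, ...) {
  off <- closed_offset(states)
  x$delta_theta0 <- x$delta_theta0 - off
  attr(x, "offset") <- off
  x
}

## ---- tabular I/O -----------------------------------------------------------

#' Read / write twist traces as two-column delimited text
#'
#' Traces are stored as tab-separated (time_s, theta_bp) with a sidecar
#' `<path>.meta` file of key=value metadata (enzyme, conc_nM, sample_rate,
#' seed, unit, zero_reference).
#'
#' @param trace a [twist_trace()].
#' @param path file path for the trace table.
#' @return `write_trace` returns the path invisibly; `read_trace` a
#'   [twist_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "twist_trace"))
  utils::write.table(data.frame(time_s = trace$time, theta = trace$theta),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- c(list(unit = trace$unit, sample_rate = trace$sample_rate,
                 zero_reference = trace$zero_reference),
            trace$metadata)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  writeLines(paste0(names(meta), "=",
                    vapply(meta, function(v) as.character(v)[1],
                           character(1))),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta_path <- paste0(path, ".meta")
  meta <- list()
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, function(p) {
      v <- paste(p[-1], collapse = "=")
      if (grepl("^-?[0-9.eE+-]+$", v)) as.numeric(v) else v
    }), vapply(kv, `[`, character(1), 1))
  }
  fs <- meta$sample_rate %||% (1 / stats::median(diff(tab$time_s)))
  twist_trace(theta = tab[[2]], sample_rate = fs, time = tab$time_s,
              zero_reference = meta$zero_reference %||% 0,
              unit = meta$unit %||% "bp",
              metadata = meta[setdiff(names(meta),
                                      c("unit", "sample_rate",
                                        "zero_reference"))])
}

#' Read a raw (time, x, y) bead trajectory from delimited text
#'
#' @param path file with columns time_s, x, y (tab- or whitespace-separated).
#' @return an [xy_trajectory()].
#' @export
read_xy_trajectory <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  xy_trajectory(tab[[1]], tab[[2]], tab[[3]])
}
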