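#' Apparent equilibrium constants from forward/reverse rate pairs
#'
#' K_ij = k_ij / k_ji for every ordered pair with both directions observed at
#' a positive rate; the reverse constant is the reciprocal. Pairs with a zero
#' or missing reverse rate are undefined and flagged with a warning.
#'
#' @param rates a `rate_set` from [estimate_rates()], or a named numeric
#'   vector of rates such as `c(CI = 0.03, IC = 0.006, IO = 0.1, OI = 0.1)`.
#' @return named numeric vector of equilibrium constants (names like
#'   `"CI"`), with undefined pairs dropped.
#' @export
equilibrium_constants <- function(rates) {
  k <- as_rate_vector(rates)
  pairs <- unique(t(apply(cbind(substr(names(k), 1, 1),
                                substr(names(k), 2, 2)), 1, sort)))
  out <- numeric(0)
  dropped <- character(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    fwd <- k[paste0(i, j)]; rev <- k[paste0(j, i)]
    if (is.na(fwd) || is.na(rev) || rev <= 0 || fwd <= 0) {
      dropped <- c(dropped, paste0(i, j))
      next
    }
    out[paste0(i, j)] <- unname(fwd / rev)
    out[paste0(j, i)] <- unname(rev / fwd)
  }
  if (length(dropped))
    warning("equilibrium constant undefined (zero or missing rate) for: ",
            paste(dropped, collapse = ", "))
  out
}

as_rate_vector <- function(rates) {
  if (inherits(rates, "rate_set")) {
    r <- rates$rates
    stats::setNames(r$rate, paste0(r$from, r$to))
  } else if (is.numeric(rates) && !is.null(names(rates))) {
    rates
  } else stop("'rates' must be a rate_set or a named numeric vector")
}

#' Free-energy difference from an equilibrium constant
#'
#' delta_G = -ln(K) in units of kB*T.
#'
#' @param K equilibrium constant(s), > 0.
#' @return free-energy difference(s), kBT.
#' @export
free_energy <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be finite and > 0")
  -log(K)
}

#' Piecewise free-energy landscape of two-step target capture
#'
#' Builds well and barrier energies (kBT) over the reaction coordinate
#' Cfree -> Cbound -> I -> O at a stated RNP concentration. Well energies
#' accumulate -ln(K) along the path, with the bimolecular first step
#' contributing -ln(kon_init * [RNP] / koff_init) = -ln([RNP] / Kd_init).
#' Barrier heights sit at -ln(k_forward) + C above the preceding well, with
#' the arbitrary offset constant C (default 7 kBT) absorbing the unknown
#' attempt frequency; the Cfree barrier uses the pseudo-first-order rate
#' kon_init * [RNP]. The Cfree well coordinate is illustrative only.
#'
#' @param kd_init initial-binding dissociation constant, nM.
#' @param kopen Cbound -> I unwinding rate, per s.
#' @param k_ic,k_io,k_oi remaining transition rates, per s.
#' @param kon_init assumed association rate, per nM per s (default 0.1).
#' @param conc_nM RNP concentration at which to draw the landscape (default
#'   100).
#' @param barrier_offset the constant C, kBT (default 7).
#' @param positions_bp well coordinates on the unwinding axis, bp.
#' @return an object of class `energy_landscape` with a table of wells and
#'   barriers (kind, name, coordinate_bp, energy_kBT) and the input
#'   parameters.
#' @export
build_landscape <- function(kd_init, kopen, k_ic, k_io, k_oi,
                            kon_init = 0.1, conc_nM = 100,
                            barrier_offset = 7,
                            positions_bp = c(Cfree = -5, Cbound = 0,
                                             I = 10, O = 20)) {
  need <- c(kd_init = missing(kd_init), kopen = missing(kopen),
            k_ic = missing(k_ic), k_io = missing(k_io),
            k_oi = missing(k_oi))
  if (any(need))
    stop("missing landscape parameters: ",
         paste(names(need)[need], collapse = ", "))
  vals <- c(kd_init, kopen, k_ic, k_io, k_oi, kon_init, conc_nM)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rates, constants and the concentration must be finite and > 0")
  koff_init <- kon_init * kd_init
  e_cfree <- 0
  e_cbound <- e_cfree - log(kon_init * conc_nM / koff_init)
  e_i <- e_cbound - log(kopen / k_ic)
  e_o <- e_i - log(k_io / k_oi)
  wells <- data.frame(kind = "well",
                      name = c("Cfree", "Cbound", "I", "O"),
                      coordinate_bp = unname(positions_bp[c("Cfree", "Cbound",
                                                            "I", "O")]),
                      energy_kBT = c(e_cfree, e_cbound, e_i, e_o))
  fwd <- c(kon_init * conc_nM, kopen, k_io)
  barriers <- data.frame(kind = "barrier",
                         name = c("Cfree-Cbound", "Cbound-I", "I-O"),
                         coordinate_bp = (wells$coordinate_bp[-4] +
                                            wells$coordinate_bp[-1]) / 2,
                         energy_kBT = wells$energy_kBT[-4] -
                           log(fwd) + barrier_offset)
  structure(list(table = rbind(wells, barriers),
                 params = list(kd_init = kd_init, kopen = kopen,
                               k_ic = k_ic, k_io = k_io, k_oi = k_oi,
                               kon_init = kon_init, conc_nM = conc_nM,
                               barrier_offset = barrier_offset)),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Free-energy landscape at [RNP] = %g nM (C = %g kBT):\n",
              x$params$conc_nM, x$params$barrier_offset))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.energy_landscape <- function(x, ...) {
  tab <- x$table[order(x$table$coordinate_bp), ]
  graphics::plot(tab$coordinate_bp, tab$energy_kBT, type = "b",
                 xlab = "bp unwound", ylab = expression(G ~ (k[B] * T)), ...)
  wells <- tab[tab$kind == "well", ]
  graphics::text(wells$coordinate_bp, wells$energy_kBT, wells$name,
                 pos = 1)
  invisible(x)
}

#' Energy of a named well or barrier
#'
#' @param landscape an `energy_landscape`.
#' @param name well or barrier name (e.g. `"Cbound"`, `"Cbound-I"`).
#' @return energy in kBT.
#' @export
landscape_energy <- function(landscape, name) {
  tab <- landscape$table
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) stop("no such well or barrier: ", name)
  row$energy_kBT
}

#' Between-enzyme difference in the Cbound -> I free-energy change
#'
#' Composes fold-differences in the forward (unwinding) and reverse
#' (collapse) rates of the Cbound <-> I step into an equilibrium-constant
#' ratio and applies delta_G = -ln(K): a fold_kopen-times slower unwinding
#' combined with fold_kic-times faster collapse raises the step free energy
#' by ln(fold_kopen) + ln(fold_kic) kBT.
#'
#' @param fold_kopen fold-reduction of the forward unwinding rate.
#' @param fold_kic fold-increase of the reverse collapse rate.
#' @return delta-delta-G in kBT.
#' @export
delta_delta_g <- function(fold_kopen, fold_kic) {
  stopifnot(fold_kopen > 0, fold_kic > 0)
  log(fold_kopen) + log(fold_kic)
}

#' Export a landscape as a delimited table
#'
#' @param landscape an `energy_landscape`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.table(landscape$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
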