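#' Shannon entropy of a population vector
#'
#' \eqn{S = -\sum_j p_j \ln p_j} in units of \eqn{k_B}, with the convention
#' \eqn{0 \ln 0 = 0}. The vector need not sum to 1: under irreversible
#' trapping the raw surviving population is used as-is (see
#' \code{\link{free_energy_series}}). Entries below a small negative clip
#' tolerance are an error; round-off negatives are treated as 0.
#'
#' @param p Nonnegative numeric vector.
#' @param clip Magnitude of negative round-off tolerated (default 1e-12).
#' @return Entropy in \eqn{k_B} units (multiply by \code{kB_cm1() * T} for
#'   the cm^-1 scale of \eqn{-T\Delta S}).
#' @export
shannon_entropy <- function(p, clip = 1e-12) {
  if (any(p < -clip)) stop("negative probability beyond clip tolerance: ", min(p))
  p <- pmax(p, 0)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Ensemble enthalpy of a population vector
#'
#' \eqn{H = \sum_j p_j E_j} over the state energies, in cm^-1. Reference-free;
#' differences relative to the initial condition are taken downstream.
#'
#' @param p Probability (or surviving-population) vector.
#' @param E State energies in cm^-1, same length.
#' @return Enthalpy in cm^-1.
#' @export
enthalpy <- function(p, E) {
  if (length(p) != length(E)) stop("length mismatch between populations and energies")
  sum(p * E)
}

#' Time-resolved free-energy decomposition
#'
#' Computes the entropy and enthalpy series of a population trajectory and
#' the free-energy change \eqn{\Delta G(t) = \Delta H(t) - T \Delta S(t)},
#' all relative to the initial condition. In \code{"raw"} mode (default) the
#' surviving excitonic populations enter \eqn{S} and \eqn{H} unnormalised:
#' as population absorbs into the RC traps the entropy rises and then falls
#' back toward 0, which defines the population contraction time. In
#' \code{"conditional"} mode populations are renormalised by the surviving
#' mass first (statistics conditioned on not yet being absorbed). Sinks are
#' excluded from \eqn{S} and \eqn{H} in both modes.
#'
#' @param traj A \code{\link{propagate}} result (single initial condition).
#' @param net The \code{kinetic_network} supplying state energies (or a
#'   numeric vector of energies in cm^-1).
#' @param temperature Temperature in K; defaults to the network's.
#' @param mode \code{"raw"} or \code{"conditional"}.
#' @return A \code{thermo_trajectory}: data.frame with columns
#'   \code{time_ps}, \code{S_kB}, \code{H_cm1}, \code{dH_cm1},
#'   \code{minus_TdS_cm1}, \code{dG_cm1}, plus attributes
#'   \code{normalization_mode} and \code{temperature}.
#' @export
free_energy_series <- function(traj, net, temperature = NULL,
                               mode = c("raw", "conditional")) {
  mode <- match.arg(mode)
  E <- if (inherits(net, "kinetic_network")) net$states$energy_cm1 else as.numeric(net)
  if (is.null(temperature)) {
    temperature <- if (inherits(net, "kinetic_network")) net$temperature else 300
  }
  P <- traj$populations
  if (length(dim(P)) == 3) stop("free_energy_series expects a single-IC trajectory")
  if (ncol(P) != length(E)) stop("energy vector does not match trajectory")
  nt <- nrow(P)
  S <- numeric(nt); H <- numeric(nt)
  for (k in seq_len(nt)) {
    p <- P[k, ]
    if (mode == "conditional") {
      m <- sum(p)
      p <- if (m > 0) p / m else p
    }
    S[k] <- shannon_entropy(p)
    H[k] <- enthalpy(p, E)
  }
  out <- data.frame(time_ps = traj$times, S_kB = S, H_cm1 = H,
                    dH_cm1 = H - H[1],
                    minus_TdS_cm1 = -temperature * .kB_cm1 * (S - S[1]))
  out$dG_cm1 <- out$dH_cm1 + out$minus_TdS_cm1
  attr(out, "normalization_mode") <- mode
  attr(out, "temperature") <- temperature
  class(out) <- c("thermo_trajectory", "data.frame")
  out
}

## Internal: golden-section maximization of f on [lo, hi] to within tol.
## Ties resolve toward the earlier time because the final interval midpoint
## is returned and f is evaluated deterministically.
golden_max <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol) {
    if (f1 >= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
  }
  (a + b) / 2
}

## Internal: value of the (raw or conditional) entropy or dH at an arbitrary
## time, by direct action of the propagator on the initial condition.
thermo_value_at <- function(gen, ic, t0, what, E, mode) {
  gen <- as_generator(gen)
  A <- extended_generator(gen)
  n <- ncol(gen$Q)
  z0 <- c(as.numeric(ic), numeric(4))
  function(t) {
    z <- if (t > 0) as.numeric(dense_expm(A * t) %*% z0) else z0
    p <- pmax(z[seq_len(n)], 0)
    if (mode == "conditional") { m <- sum(p); if (m > 0) p <- p / m }
    if (what == "S") shannon_entropy(p) else enthalpy(p, E) - enthalpy(pmax(z0[seq_len(n)], 0), E)
  }
}

## Internal: locate grid argmax (earliest on ties), then optionally refine.
peak_on_grid <- function(times, y, gen, ic, E, mode, what, refine_tol) {
  k <- which.max(y)                        # earliest global max
  if (k == length(y)) {
    stop("maximum at final grid point: extend time grid")
  }
  t_hat <- times[k]; y_hat <- y[k]
  if (k == 1) return(list(time = times[1], value = y_hat))
  lo <- times[k - 1]; hi <- times[k + 1]
  if (!is.null(gen) && !is.null(ic) && (hi - lo) > refine_tol) {
    f <- thermo_value_at(gen, ic, times[1], what, E, mode)
    t_hat <- golden_max(f, lo, hi, refine_tol)
    y_hat <- f(t_hat)
    if (y_hat < y[k]) { t_hat <- times[k]; y_hat <- y[k] }  # guard
  }
  list(time = t_hat, value = y_hat)
}

#' Population contraction time
#'
#' The time at which the Shannon entropy of the excitation distribution is
#' maximal: the switch from entropic spreading over the near-degenerate
#' antenna states to directed contraction toward the reaction-center traps.
#' The global maximum is located on the trajectory grid (earliest point on
#' ties) and, when the generator and initial condition are supplied, refined
#' by golden-section search on the continuously propagated entropy within
#' the bracketing grid interval. If the entropy is maximal at the first grid
#' point (monotone non-increasing series), the contraction time is 0; a
#' maximum at the final grid point raises an error asking for a longer grid.
#'
#' @param thermo A \code{\link{free_energy_series}} result.
#' @param gen,ic Optional generator and initial condition enabling
#'   continuous refinement.
#' @param refine_tol Refinement tolerance in ps (default 0.1).
#' @return List with \code{time_ps} and \code{entropy_max_kB}.
#' @export
contraction_time <- function(thermo, gen = NULL, ic = NULL, refine_tol = 0.1) {
  stopifnot(inherits(thermo, "thermo_trajectory"))
  mode <- attr(thermo, "normalization_mode")
  pk <- peak_on_grid(thermo$time_ps, thermo$S_kB, gen, ic, E = NULL,
                     mode = mode, what = "S", refine_tol = refine_tol)
  list(time_ps = pk$time, entropy_max_kB = pk$value)
}

#' Enthalpy peak time and value
#'
#' Locates the maximum of \eqn{\Delta H(t)}: the time before which the
#' ensemble on average transfers uphill in energy and after which transfer
#' follows the downhill gradient toward the RC. Same bracketing and
#' golden-section refinement as \code{\link{contraction_time}}. A purely
#' downhill relaxation peaks at \eqn{t = 0} with \eqn{\Delta H = 0}.
#'
#' @param thermo A \code{\link{free_energy_series}} result.
#' @param gen,ic Optional generator and initial condition for refinement.
#' @param E State energies (cm^-1); required when refining.
#' @param refine_tol Refinement tolerance in ps.
#' @return List with \code{time_ps} and \code{dH_peak_cm1}.
#' @export
enthalpy_peak <- function(thermo, gen = NULL, ic = NULL, E = NULL,
                          refine_tol = 0.1) {
  stopifnot(inherits(thermo, "thermo_trajectory"))
  if (!is.null(gen) && is.null(E)) {
    g <- as_generator(gen)
    if (!is.null(g$states)) E <- g$states$energy_cm1
    else stop("E required for refinement")
  }
  mode <- attr(thermo, "normalization_mode")
  pk <- peak_on_grid(thermo$time_ps, thermo$dH_cm1, gen, ic, E = E,
                     mode = mode, what = "H", refine_tol = refine_tol)
  list(time_ps = pk$time, dH_peak_cm1 = pk$value)
}

#' Summary of a thermodynamic trajectory
#'
#' Convenience wrapper extracting the contraction time, enthalpy peak and
#' entropy maximum in one call.
#'
#' @inheritParams enthalpy_peak
#' @return List with \code{contraction_time_ps}, \code{entropy_max_kB},
#'   \code{enthalpy_peak_ps}, \code{enthalpy_peak_cm1}.
#' @export
thermo_summary <- function(thermo, gen = NULL, ic = NULL, E = NULL,
                           refine_tol = 0.1) {
  ct <- contraction_time(thermo, gen, ic, refine_tol)
  hp <- enthalpy_peak(thermo, gen, ic, E, refine_tol)
  list(contraction_time_ps = ct$time_ps, entropy_max_kB = ct$entropy_max_kB,
       enthalpy_peak_ps = hp$time_ps, enthalpy_peak_cm1 = hp$dH_peak_cm1)
}

#' Write a thermodynamic trajectory to TSV
#'
#' Columns \code{time_ps, S_kB, H_cm1, dH_cm1, minus_TdS_cm1, dG_cm1}.
#'
#' @param thermo A \code{thermo_trajectory}.
#' @param path Output file.
#' @return Invisibly, the input.
#' @export
write_thermo <- function(thermo, path) {
  write.table(as.data.frame(thermo), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(thermo)
}
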