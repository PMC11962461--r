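#' Construct a kinetic EET network
#'
#' Bundles a per-state metadata table with an excitonic rate matrix into a
#' validated continuous-time Markov chain. The rate convention follows the
#' light-harvesting literature: \code{rates[i, j]} is the transfer rate
#' \eqn{k_{ij}} from state \eqn{j} to state \eqn{i} in ps\eqn{^{-1}}, so each
#' column collects the outflows of one source state. The diagonal is always
#' rebuilt internally as \eqn{-\sum_{i \ne j} k_{ij}} (generator convention);
#' input matrices may carry either a zero diagonal or a generator diagonal.
#'
#' @param states data.frame with one row per state. Required columns:
#'   \code{state_id} (unique character), \code{subunit}, \code{monomer}
#'   (1 or 2), \code{energy_cm1} (finite, cm^-1). Optional: \code{pigment},
#'   \code{x}, \code{y}, \code{z} (Angstrom), \code{dipole_sq}
#'   (relative squared transition dipole, >= 0), \code{is_chl_a} (logical).
#' @param rates N x N numeric matrix of rates, ps^-1; column j holds the
#'   outflows of state j. Off-diagonal entries must be nonnegative and finite.
#' @param temperature Bath temperature in K (default 300).
#' @return An object of class \code{kinetic_network}: a list with elements
#'   \code{states}, \code{rates} (generator convention), \code{temperature}.
#' @examples
#' st <- data.frame(state_id = c("a", "b"), subunit = "X", monomer = 1L,
#'                  energy_cm1 = c(0, 208.51))
#' k_up <- exp(-208.51 / (kB_cm1() * 300))
#' K <- matrix(c(0, k_up, 1, 0), 2, 2)
#' net <- kinetic_network(st, K)
#' @export
kinetic_network <- function(states, rates, temperature = 300) {
  stopifnot(is.data.frame(states))
  rates <- as.matrix(rates)
  n <- nrow(states)
  if (!all(dim(rates) == c(n, n))) {
    stop("dimension mismatch: state table has ", n, " rows but rate matrix is ",
         nrow(rates), " x ", ncol(rates))
  }
  req <- c("state_id", "subunit", "monomer", "energy_cm1")
  miss <- setdiff(req, names(states))
  if (length(miss)) stop("state table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(states$state_id)) {
    stop("duplicate state_id: ",
         paste(unique(states$state_id[duplicated(states$state_id)]), collapse = ", "))
  }
  states$state_id <- as.character(states$state_id)
  states$monomer <- as.integer(states$monomer)
  if (!all(states$monomer %in% c(1L, 2L))) stop("monomer must be 1 or 2")
  if (!all(is.finite(states$energy_cm1))) stop("non-finite state energy")
  if (!is.null(states$dipole_sq) && any(states$dipole_sq < 0, na.rm = TRUE)) {
    stop("dipole_sq must be >= 0")
  }
  if (temperature <= 0) stop("temperature must be > 0")
  if (any(!is.finite(rates[row(rates) != col(rates)]))) {
    stop("non-finite rate matrix entry")
  }
  off <- rates; diag(off) <- 0
  if (any(off < 0)) {
    bad <- which(off < 0, arr.ind = TRUE)[1, ]
    stop("negative rate at (", bad[1], ", ", bad[2], ")")
  }
  diag(off) <- -colSums(off)
  dimnames(off) <- list(states$state_id, states$state_id)
  structure(list(states = states, rates = off, temperature = temperature),
            class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat("<kinetic_network> ", nrow(x$states), " states, T = ", x$temperature, " K\n",
      sep = "")
  cat("  energy range: ", round(min(x$states$energy_cm1), 1), " .. ",
      round(max(x$states$energy_cm1), 1), " cm^-1\n", sep = "")
  cen <- table(x$states$subunit)
  cat("  subunits: ", paste(names(cen), cen, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of states in a kinetic network
#' @param net A \code{kinetic_network}.
#' @return Integer state count.
#' @export
n_states <- function(net) nrow(net$states)

#' Boltzmann equilibrium distribution of a network
#'
#' \eqn{\pi_i \propto \exp(-E_i / k_B T)} over the state energies, normalised
#' to 1. This is the stationary distribution of any rate matrix satisfying
#' detailed balance at the network temperature.
#'
#' @param net A \code{kinetic_network}.
#' @return Named probability vector of length N.
#' @export
boltzmann_equilibrium <- function(net) {
  stopifnot(inherits(net, "kinetic_network"))
  E <- net$states$energy_cm1
  w <- exp(-(E - min(E)) / (.kB_cm1 * net$temperature))
  setNames(w / sum(w), net$states$state_id)
}

#' Check detailed balance of a rate matrix
#'
#' Verifies the pairwise condition
#' \eqn{k_{ij}/k_{ji} = \exp(-(E_i - E_j)/k_B T)} for every pair with both
#' rates positive. One-sided pairs (one rate zero, the other positive) break
#' detailed balance by construction — legitimate only for designated
#' irreversible trap transitions — and are counted and reported rather than
#' failed, so a closed network is expected to report zero of them.
#'
#' @param net A \code{kinetic_network}.
#' @param tol Relative tolerance on the ratio test.
#' @return List with \code{pass} (logical over two-sided pairs),
#'   \code{worst_ratio} (max of |observed/expected - 1|), \code{worst_pair}
#'   (state ids), \code{n_onesided} (count of one-sided nonzero pairs).
#' @export
check_detailed_balance <- function(net, tol = 1e-9) {
  stopifnot(inherits(net, "kinetic_network"))
  if (net$temperature <= 0) stop("temperature must be > 0")
  K <- net$rates; diag(K) <- 0
  E <- net$states$energy_cm1
  beta <- 1 / (.kB_cm1 * net$temperature)
  idx <- which(upper.tri(K), arr.ind = TRUE)
  kij <- K[idx]                          # j -> i with i < j
  kji <- K[cbind(idx[, 2], idx[, 1])]    # i -> j
  both <- kij > 0 & kji > 0
  onesided <- xor(kij > 0, kji > 0)
  worst <- 0; worst_pair <- c(NA_character_, NA_character_)
  if (any(both)) {
    i <- idx[both, 1]; j <- idx[both, 2]
    expected <- exp(-(E[i] - E[j]) * beta)
    ratio <- kij[both] / kji[both] / expected
    dev <- pmax(abs(ratio - 1), abs(1 / ratio - 1))  # orientation-symmetric
    w <- which.max(dev)
    worst <- dev[w]
    worst_pair <- net$states$state_id[c(i[w], j[w])]
  }
  list(pass = worst <= tol, worst_ratio = worst, worst_pair = worst_pair,
       n_onesided = sum(onesided), tol = tol)
}

#' Disorder ensemble of kinetic networks
#'
#' A set of rate-matrix realizations sharing a single state list and
#' ordering, typically generated from independent draws of Gaussian
#' site-energy disorder (static inhomogeneous broadening).
#'
#' @param realizations List of \code{kinetic_network} objects with identical
#'   state ids in identical order.
#' @param seed Optional integer recorded for provenance.
#' @return Object of class \code{disorder_ensemble}.
#' @export
disorder_ensemble <- function(realizations, seed = NULL) {
  stopifnot(length(realizations) >= 1)
  ids <- realizations[[1]]$states$state_id
  for (r in realizations) {
    if (!inherits(r, "kinetic_network")) stop("all realizations must be kinetic_network")
    if (!identical(r$states$state_id, ids)) stop("mismatched state ordering across realizations")
  }
  structure(list(realizations = realizations,
                 n_realizations = length(realizations), seed = seed),
            class = "disorder_ensemble")
}

#' @export
print.disorder_ensemble <- function(x, ...) {
  cat("<disorder_ensemble> ", x$n_realizations, " realizations of ",
      nrow(x$realizations[[1]]$states), " states\n", sep = "")
  invisible(x)
}

#' Average the rate matrices of a disorder ensemble
#'
#' Element-wise mean of the off-diagonal rates over all realizations, with
#' the generator diagonal rebuilt. Ensemble observables computed from the
#' averaged matrix stand in for the average over per-realization dynamics,
#' the standard convention for disorder-averaged fluorescence kinetics.
#'
#' @param ens A \code{disorder_ensemble}.
#' @return A \code{kinetic_network} with the averaged rates and the shared
#'   state table of the first realization (energies averaged element-wise).
#' @export
average_rate_matrices <- function(ens) {
  stopifnot(inherits(ens, "disorder_ensemble"))
  nets <- ens$realizations
  K <- nets[[1]]$rates; diag(K) <- 0
  E <- nets[[1]]$states$energy_cm1
  if (length(nets) > 1) {
    for (r in nets[-1]) {
      Kr <- r$rates; diag(Kr) <- 0
      K <- K + Kr
      E <- E + r$states$energy_cm1
    }
    K <- K / length(nets)
    E <- E / length(nets)
  }
  st <- nets[[1]]$states
  st$energy_cm1 <- E
  kinetic_network(st, K, temperature = nets[[1]]$temperature)
}
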