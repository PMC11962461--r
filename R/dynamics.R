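## Internal: accept an eet_generator or a plain generator matrix (closed
## system) and return the canonical list form.
as_generator <- function(gen) {
  if (inherits(gen, "eet_generator")) return(gen)
  if (is.matrix(gen)) {
    n <- ncol(gen)
    return(structure(list(Q = gen,
                          sink_rates = matrix(0, 4, n,
                            dimnames = list(c("trap1", "trap2", "fluorescence",
                                              "nonradiative"), colnames(gen))),
                          states = NULL, temperature = NA_real_,
                          has_losses = FALSE, trap_donors = NULL),
                     class = "eet_generator"))
  }
  stop("gen must be an eet_generator or a square matrix")
}

## Internal: extended generator including the four sink rows/columns.
extended_generator <- function(gen) {
  n <- ncol(gen$Q)
  rbind(cbind(gen$Q, matrix(0, n, 4)),
        cbind(gen$sink_rates, matrix(0, 4, 4)))
}

dense_expm <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

#' Propagate the master equation
#'
#' Integrates \eqn{dP/dt = K P} directly, \eqn{P(t) = e^{Kt} P(0)}, on an
#' ascending time grid, tracking the four absorbing sinks explicitly so
#' total probability (kept states + sinks) is conserved. The propagator is
#' computed by Pade scaling-and-squaring per grid interval; several initial
#' conditions can be propagated at once by passing a matrix of columns.
#'
#' @param gen An \code{eet_generator} from \code{\link{build_generator}}, or
#'   a plain closed generator matrix.
#' @param ic Initial condition: probability vector of length N (see
#'   \code{\link{initial_condition_for_pigment}}), or an N x M matrix of M
#'   initial conditions.
#' @param times Ascending nonnegative time grid in ps
#'   (default \code{\link{default_times}()}).
#' @return A \code{population_trajectory}: list with \code{times},
#'   \code{populations} (T x N, or T x N x M array for matrix input),
#'   \code{sink_mass} (T x 4 or T x 4 x M). Populations in [-1e-12, 1];
#'   tiny negative round-off is clipped to 0.
#' @export
propagate <- function(gen, ic, times = default_times()) {
  gen <- as_generator(gen)
  if (any(!is.finite(gen$Q))) stop("non-finite generator entries")
  n <- ncol(gen$Q)
  if (is.null(dim(ic))) ic <- matrix(ic, ncol = 1)
  if (nrow(ic) != n) stop("initial condition length does not match generator")
  if (any(ic < 0) || any(abs(colSums(ic) - 1) > 1e-9)) {
    stop("each initial condition must be a probability vector")
  }
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("times must be nonnegative and strictly ascending")
  }
  m <- ncol(ic)
  A <- extended_generator(gen)
  Z <- rbind(ic, matrix(0, 4, m))
  nt <- length(times)
  pops <- array(0, c(nt, n, m))
  sinks <- array(0, c(nt, 4, m))
  t_prev <- 0
  for (k in seq_len(nt)) {
    dt <- times[k] - t_prev
    if (dt > 0) {
      Z <- dense_expm(A * dt) %*% Z
      ## columns of the exact propagator sum to 1; rescaling removes pure
      ## round-off drift of the total probability (kept + sinks)
      Z <- sweep(Z, 2, colSums(Z), "/")
    }
    t_prev <- times[k]
    P <- Z[seq_len(n), , drop = FALSE]
    neg <- P < 0
    if (any(neg)) {
      if (min(P) < -1e-12)
        warning("population ", format(min(P)), " below -1e-12 clipped to 0")
      P[neg] <- 0
    }
    pops[k, , ] <- P
    sinks[k, , ] <- Z[n + 1:4, , drop = FALSE]
  }
  if (m == 1) { dim(pops) <- c(nt, n); dim(sinks) <- c(nt, 4) }
  structure(list(times = times, populations = pops, sink_mass = sinks,
                 state_ids = if (!is.null(gen$states)) gen$states$state_id
                             else colnames(gen$Q)),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat("<population_trajectory> ", nt, " times in [",
      format(min(x$times)), ", ", format(max(x$times)), "] ps, ",
      if (length(dim(x$populations)) == 3) dim(x$populations)[2]
      else ncol(x$populations), " states\n", sep = "")
  invisible(x)
}

#' Initial condition localized in a named pigment
#'
#' In the exciton basis, "exciting Chl a 509 in CP43" means starting in the
#' exciton state most localized on that chlorophyll. Given a localization
#' map (rows = exciton states, columns = pigment sites, row entries = site
#' weights), this returns a delta distribution on the exciton state whose
#' weight on the named pigment is maximal. For site-basis networks (no map)
#' the pigment label is matched directly against the state metadata.
#'
#' @param net A \code{kinetic_network}.
#' @param pigment_label Pigment name to match (against the map's column
#'   names, or the \code{pigment} column, falling back to \code{state_id}).
#' @param localization_map Optional N x n_sites numeric matrix with column
#'   names; NULL for site-basis networks.
#' @return An \code{initial_condition}: probability vector of length N.
#' @export
initial_condition_for_pigment <- function(net, pigment_label,
                                          localization_map = NULL) {
  n <- n_states(net)
  if (is.null(localization_map)) {
    labels <- if (!is.null(net$states$pigment)) net$states$pigment
              else net$states$state_id
    hit <- which(labels == pigment_label)
    if (!length(hit)) hit <- which(net$states$state_id == pigment_label)
    if (!length(hit)) stop("pigment not found: ", pigment_label)
    idx <- hit
    w <- rep(1, length(hit))  # degenerate labels: treat as tie
  } else {
    if (nrow(localization_map) != n) stop("localization map/state mismatch")
    col <- match(pigment_label, colnames(localization_map))
    if (is.na(col)) stop("pigment not found in localization map: ", pigment_label)
    w <- localization_map[, col]
    idx <- seq_len(n)
  }
  best <- max(w)
  cand <- idx[w >= best - 1e-12]
  if (length(cand) > 1) {
    warning("ambiguous localization maximum for '", pigment_label,
            "'; choosing lowest state index")
  }
  ic <- numeric(n)
  ic[min(cand)] <- 1
  setNames(ic, net$states$state_id)
}

#' Uniform initial condition over all Chl a states
#'
#' Weight 1/N_a on every state flagged \code{is_chl_a}, the standard initial
#' condition for simulated fluorescence-decay experiments.
#'
#' @param net A \code{kinetic_network} whose state table has \code{is_chl_a}.
#' @return Probability vector of length N.
#' @export
initial_condition_chl_a <- function(net) {
  a <- net$states$is_chl_a
  if (is.null(a)) stop("state table has no is_chl_a column")
  a <- as.logical(a)
  ic <- ifelse(a, 1 / sum(a), 0)
  setNames(ic, net$states$state_id)
}

## Internal: solve (-Q) X = B on the transient block with a helpful error
## when some states cannot reach any sink.
solve_transient <- function(gen, B) {
  out <- tryCatch(solve(-gen$Q, B), error = function(e) e)
  if (inherits(out, "error")) {
    drained <- colSums(gen$sink_rates) > 0
    stop("singular transient block: no absorbing state reachable",
         if (!is.null(gen$states) && any(!drained))
           paste0(" (candidate stranded states: ",
                  paste(head(gen$states$state_id[!drained], 8), collapse = ", "), ")")
         else "")
  }
  out
}

#' Splitting probabilities into the absorbing sinks
#'
#' Probability of ultimate absorption into each sink (trap 1, trap 2,
#' fluorescence, nonradiative), computed by a committor-style linear solve
#' on the transient block: \eqn{p_s = r_s (-Q)^{-1} P(0)}, not by long-time
#' integration. With no losses the two trap probabilities sum to 1.
#'
#' @param gen An \code{eet_generator} with at least one reachable sink.
#' @param ic Initial probability vector.
#' @param monomer Optional monomer (1 or 2) of the initial excitation, used
#'   to report the same-monomer trapping fraction
#'   \eqn{p_{same}/(p_{trap1}+p_{trap2})}.
#' @return A \code{fate_summary}: list with \code{p_trap1}, \code{p_trap2},
#'   \code{p_fluor}, \code{p_nonrad}, \code{same_monomer_fraction} (NA when
#'   \code{monomer} not given).
#' @export
splitting_probabilities <- function(gen, ic, monomer = NULL) {
  gen <- as_generator(gen)
  if (all(gen$sink_rates == 0)) stop("no absorbing sink present")
  x <- solve_transient(gen, as.numeric(ic))
  p <- as.numeric(gen$sink_rates %*% x)
  names(p) <- rownames(gen$sink_rates)
  smf <- NA_real_
  if (!is.null(monomer)) {
    pt <- p["trap1"] + p["trap2"]
    if (pt > 0) smf <- unname(p[paste0("trap", monomer)] / pt)
  }
  structure(list(p_trap1 = unname(p["trap1"]), p_trap2 = unname(p["trap2"]),
                 p_fluor = unname(p["fluorescence"]),
                 p_nonrad = unname(p["nonradiative"]),
                 same_monomer_fraction = smf),
            class = "fate_summary")
}

#' @export
print.fate_summary <- function(x, ...) {
  cat(sprintf("<fate_summary> trap1 %.4f  trap2 %.4f  fluor %.4g  nonrad %.4g\n",
              x$p_trap1, x$p_trap2, x$p_fluor, x$p_nonrad))
  if (!is.na(x$same_monomer_fraction))
    cat(sprintf("  same-monomer trapping fraction: %.3f\n", x$same_monomer_fraction))
  invisible(x)
}

#' Mean first passage time to the reaction-center traps
#'
#' The trapping time: expected time for an initial excitation to first reach
#' any open trap, computed with loss channels disabled via the linear solve
#' \eqn{\tau = \mathbf{1}^T (-Q)^{-1} P(0)}. Equals the time integral of the
#' surviving probability \eqn{\int_0^\infty N(t)\,dt}.
#'
#' @param gen An \code{eet_generator} built without losses and with at least
#'   one open trap (an error is raised otherwise).
#' @param ic Initial probability vector.
#' @return MFPT in ps.
#' @export
mean_first_passage_time <- function(gen, ic) {
  gen <- as_generator(gen)
  if (gen$has_losses || any(gen$sink_rates[c("fluorescence", "nonradiative"), ] != 0)) {
    stop("mean_first_passage_time requires a generator without loss channels; ",
         "rebuild the scenario with losses = NULL")
  }
  if (all(gen$sink_rates[c("trap1", "trap2"), ] == 0)) stop("no open trap")
  tau <- sum(solve_transient(gen, as.numeric(ic)))
  if (tau <= 0) stop("nonpositive MFPT; check initial condition")
  tau
}

#' Excitation lifetime under loss channels
#'
#' Mean residence time of the excitation,
#' \eqn{\tau = \int_0^\infty N(t)\,dt} with \eqn{N(t)} the surviving
#' excitonic population, evaluated by the transient linear solve. A second
#' estimator — a single-exponential fit to the tail of \eqn{N(t)} over the
#' last decade of its decay — is reported alongside, since experimental
#' "fluorescence lifetimes" are often tail fits.
#'
#' @param gen An \code{eet_generator} with at least one absorbing sink.
#' @param ic Initial probability vector.
#' @param times Time grid used for the tail fit.
#' @return List with \code{mean_residence_ps} and \code{tail_fit_ps}.
#' @export
excitation_lifetime <- function(gen, ic, times = default_times()) {
  gen <- as_generator(gen)
  if (all(gen$sink_rates == 0)) stop("no sinks: lifetime integral diverges")
  tau <- sum(solve_transient(gen, as.numeric(ic)))
  traj <- propagate(gen, ic, times)
  Nsurv <- if (length(dim(traj$populations)) == 2) rowSums(traj$populations)
           else rowSums(traj$populations[, , 1])
  ok <- Nsurv > 1e-12 & traj$times > 0
  tail_fit <- NA_real_
  if (sum(ok) > 5) {
    tN <- traj$times[ok]; NN <- Nsurv[ok]
    sel <- tN >= max(tN) / 10
    if (sum(sel) > 3) {
      fit <- lm(log(NN[sel]) ~ tN[sel])
      rate <- -coef(fit)[2]
      if (is.finite(rate) && rate > 0) tail_fit <- unname(1 / rate)
    }
  }
  list(mean_residence_ps = tau, tail_fit_ps = tail_fit)
}

#' Kinetic Monte Carlo (Gillespie) simulation of the network
#'
#' Exact stochastic simulation of the continuous-time Markov chain defined
#' by the open-system generator: trajectories hop between states with
#' exponential waiting times until absorbed in one of the four sinks. Serves
#' as an independent oracle for the linear-solve splitting probabilities and
#' first-passage times.
#'
#' @param gen An \code{eet_generator} with at least one absorbing sink.
#' @param ic Initial probability vector.
#' @param n_traj Number of trajectories.
#' @param seed Integer seed (R RNG); identical seeds give identical counts.
#' @return List with \code{fate_counts} (named length-4), \code{fate_probs},
#'   \code{fate_se} (binomial standard errors), \code{mean_fp_ps},
#'   \code{se_fp_ps} (mean and SE of the absorption time over all
#'   trajectories), \code{n_traj}.
#' @export
gillespie_simulate <- function(gen, ic, n_traj, seed = 1L) {
  gen <- as_generator(gen)
  if (n_traj < 1) stop("n_traj must be >= 1")
  if (all(gen$sink_rates == 0)) stop("no absorbing sink: trajectories never end")
  n <- ncol(gen$Q)
  R <- gen$Q; diag(R) <- 0
  R <- rbind(R, gen$sink_rates)           # (n+4) x n jump rates
  exit <- colSums(R)
  if (any(exit <= 0)) stop("state with no outgoing rate")
  cumR <- apply(R, 2, cumsum)
  ic <- as.numeric(ic)
  set.seed(seed)
  res <- gillespie_run(cumR, exit, cumsum(ic), n, as.integer(n_traj))
  fates <- factor(res$fate, levels = 1:4,
                  labels = c("trap1", "trap2", "fluorescence", "nonradiative"))
  counts <- table(fates)
  probs <- as.numeric(counts) / n_traj
  se <- sqrt(probs * (1 - probs) / n_traj)
  list(fate_counts = setNames(as.integer(counts), names(counts)),
       fate_probs = setNames(probs, names(counts)),
       fate_se = setNames(se, names(counts)),
       mean_fp_ps = mean(res$time), se_fp_ps = sd(res$time) / sqrt(n_traj),
       n_traj = n_traj)
}
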