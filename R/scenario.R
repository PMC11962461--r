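#' Reaction-center trap specification
#'
#' One irreversible trap per monomer, fed by the lowest-energy RC state
#' (the charge-transfer state formed between Chl_D1 and Pheo_D1) unless
#' donor states are named explicitly. The trap rate is phenomenological:
#' a fast irreversible drain consistent with near-unity trapping yield.
#' Closing an RC (after a recent charge separation) sets that monomer's
#' trap rate to zero while its pigments keep participating in transfer.
#'
#' @param donor_state_ids Character vector of donor state ids (one or more
#'   per monomer), or NULL to auto-select the lowest-energy state of the
#'   "RC" subunit in each monomer.
#' @param trap_rate Trap drain rate in ps^-1 (default 1).
#' @param open Length-2 logical: is the monomer-1 / monomer-2 trap open?
#' @param trap_position Optional 3-vector (Angstrom), e.g. the midpoint
#'   between Pheo_D1 and Chl_D1; metadata only.
#' @return Object of class \code{trap_spec}.
#' @export
trap_spec <- function(donor_state_ids = NULL, trap_rate = 1,
                      open = c(TRUE, TRUE), trap_position = NULL) {
  if (trap_rate <= 0) stop("trap_rate must be > 0")
  open <- as.logical(open)
  if (length(open) != 2) stop("open must be length-2 (one flag per monomer)")
  structure(list(donor_state_ids = donor_state_ids, trap_rate = trap_rate,
                 open = open, trap_position = trap_position),
            class = "trap_spec")
}

#' Loss-channel specification
#'
#' Fluorescence and nonradiative decay of the excited states, parameterised
#' by mean lifetimes. The per-state fluorescence rate is proportional to the
#' squared transition dipole, rescaled so the state average equals
#' \code{1/mean_fl_lifetime_ns}; states lacking dipole metadata fall back to
#' the uniform mean rate. Nonradiative loss is uniform across states.
#'
#' @param mean_fl_lifetime_ns Mean fluorescence lifetime, ns (default 16,
#'   i.e. mean rate 6.25e-5 ps^-1).
#' @param nr_lifetime_ns Nonradiative lifetime, ns (default 2, i.e.
#'   5e-4 ps^-1).
#' @return Object of class \code{loss_spec}.
#' @export
loss_spec <- function(mean_fl_lifetime_ns = 16, nr_lifetime_ns = 2) {
  if (mean_fl_lifetime_ns <= 0 || nr_lifetime_ns <= 0) stop("lifetimes must be > 0")
  structure(list(mean_fl_rate = 1e-3 / mean_fl_lifetime_ns,   # ps^-1
                 nr_rate = 1e-3 / nr_lifetime_ns,             # ps^-1
                 mean_fl_lifetime_ns = mean_fl_lifetime_ns,
                 nr_lifetime_ns = nr_lifetime_ns),
            class = "loss_spec")
}

#' Experimental scenario acting on a network
#'
#' Combines a closed detailed-balanced network with the modifications that
#' make it an open system: RC traps, loss channels, and antenna-complement
#' edits (e.g. removing the M-LHCII trimers and CP24 to turn a C2S2M2-type
#' complex into C2S2).
#'
#' @param network A \code{\link{kinetic_network}}.
#' @param traps A \code{\link{trap_spec}} (or NULL for no traps).
#' @param losses A \code{\link{loss_spec}} or NULL.
#' @param removed_subunits Character vector of subunit names already removed
#'   (bookkeeping; use \code{\link{remove_subunits}} to remove).
#' @return Object of class \code{scenario}.
#' @export
scenario <- function(network, traps = trap_spec(), losses = NULL,
                     removed_subunits = character()) {
  stopifnot(inherits(network, "kinetic_network"))
  if (!is.null(traps)) stopifnot(inherits(traps, "trap_spec"))
  if (!is.null(losses)) stopifnot(inherits(losses, "loss_spec"))
  structure(list(network = network, traps = traps, losses = losses,
                 removed_subunits = removed_subunits),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> N =", n_states(x$network), "states;")
  if (is.null(x$traps)) cat(" no traps;") else
    cat(" traps", paste(ifelse(x$traps$open, "open", "closed"), collapse = "/"),
        "at", x$traps$trap_rate, "ps^-1;")
  if (is.null(x$losses)) cat(" no losses") else
    cat(" losses fl", x$losses$mean_fl_lifetime_ns, "ns / nr",
        x$losses$nr_lifetime_ns, "ns")
  if (length(x$removed_subunits))
    cat("; removed:", paste(x$removed_subunits, collapse = ", "))
  cat("\n")
  invisible(x)
}

## resolve trap donor states: lowest-energy RC state per monomer
resolve_trap_donors <- function(net, traps) {
  if (!is.null(traps$donor_state_ids)) {
    idx <- match(traps$donor_state_ids, net$states$state_id)
    if (anyNA(idx)) stop("unknown trap donor state id")
    return(split(idx, net$states$monomer[idx]))
  }
  rc <- which(net$states$subunit == "RC")
  if (!length(rc)) stop("no RC subunit in network and no explicit trap donors")
  out <- list()
  for (m in c(1L, 2L)) {
    rcm <- rc[net$states$monomer[rc] == m]
    if (length(rcm)) {
      out[[as.character(m)]] <- rcm[which.min(net$states$energy_cm1[rcm])]
    }
  }
  out
}

#' Build the open-system generator of a scenario
#'
#' Assembles the master-equation generator over the kept excitonic states,
#' together with explicit absorbing sinks \code{trap1}, \code{trap2},
#' \code{fluorescence}, \code{nonradiative}. The transient block \code{Q} is
#' the closed generator with each sink's drain subtracted on the diagonal;
#' \code{sink_rates} holds the 4 x N rates into the sinks, so total
#' probability over kept states plus sinks is conserved under propagation.
#'
#' @param sc A \code{\link{scenario}}.
#' @param require_absorbing If TRUE, error when no open trap and no losses
#'   are present (absorption statistics would be undefined).
#' @return Object of class \code{eet_generator}: list with \code{Q} (N x N),
#'   \code{sink_rates} (4 x N), \code{states}, \code{temperature},
#'   \code{has_losses}, \code{trap_donors}.
#' @export
build_generator <- function(sc, require_absorbing = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  net <- sc$network
  n <- n_states(net)
  Q <- net$rates
  sink_rates <- matrix(0, 4, n,
                       dimnames = list(c("trap1", "trap2", "fluorescence",
                                         "nonradiative"),
                                       net$states$state_id))
  trap_donors <- NULL
  any_trap <- FALSE
  if (!is.null(sc$traps)) {
    trap_donors <- resolve_trap_donors(net, sc$traps)
    for (m in names(trap_donors)) {
      if (sc$traps$open[as.integer(m)]) {
        sink_rates[paste0("trap", m), trap_donors[[m]]] <- sc$traps$trap_rate
        any_trap <- TRUE
      }
    }
  }
  if (!is.null(sc$losses)) {
    d <- net$states$dipole_sq
    if (is.null(d) || anyNA(d) || all(d == 0)) {
      fl <- rep(sc$losses$mean_fl_rate, n)
    } else {
      fl <- sc$losses$mean_fl_rate * d / mean(d)
    }
    sink_rates["fluorescence", ] <- fl
    sink_rates["nonradiative", ] <- sc$losses$nr_rate
  }
  if (require_absorbing && !any_trap && is.null(sc$losses)) {
    stop("no absorbing state: all traps closed and no losses")
  }
  diag(Q) <- diag(Q) - colSums(sink_rates)
  structure(list(Q = Q, sink_rates = sink_rates, states = net$states,
                 temperature = net$temperature, has_losses = !is.null(sc$losses),
                 trap_donors = trap_donors, scenario = sc),
            class = "eet_generator")
}

#' Close (or reopen) a reaction center
#'
#' Marks one monomer's RC trap as closed: its trap rate becomes zero so
#' excitations cannot be quenched there, but the RC states remain in the
#' network and keep transferring energy. This models an RC disabled by a
#' recent charge separation.
#'
#' @param sc A \code{\link{scenario}}.
#' @param monomer 1 or 2.
#' @param open Logical; FALSE (default) closes the trap.
#' @return The modified scenario.
#' @export
close_rc <- function(sc, monomer, open = FALSE) {
  stopifnot(inherits(sc, "scenario"), monomer %in% c(1, 2))
  if (is.null(sc$traps)) stop("scenario has no traps")
  sc$traps$open[monomer] <- open
  sc
}

#' Remove antenna subunits from a scenario
#'
#' Deletes all states belonging to the named subunits (rows and columns of
#' the rate matrix), rebuilds the generator diagonal, and records the edit.
#' Detailed balance of the remaining closed network is preserved, since
#' deleting states removes whole pairs. Warns if any remaining state loses
#' its connection to every open trap.
#'
#' @param sc A \code{\link{scenario}}.
#' @param names Character vector of subunit names present in the network.
#' @return The reduced scenario.
#' @export
remove_subunits <- function(sc, names) {
  stopifnot(inherits(sc, "scenario"))
  if (!length(names)) return(sc)
  net <- sc$network
  missing <- setdiff(names, unique(net$states$subunit))
  if (length(missing)) stop("subunits not in network: ", paste(missing, collapse = ", "))
  keep <- !(net$states$subunit %in% names)
  K <- net$rates[keep, keep, drop = FALSE]
  net2 <- kinetic_network(net$states[keep, , drop = FALSE], K,
                          temperature = net$temperature)
  sc$network <- net2
  sc$removed_subunits <- union(sc$removed_subunits, names)
  ## reachability warning: can every state reach an open trap donor?
  if (!is.null(sc$traps)) {
    donors <- tryCatch(resolve_trap_donors(net2, sc$traps), error = function(e) NULL)
    open_donors <- integer()
    for (m in names(donors)) {
      if (sc$traps$open[as.integer(m)]) open_donors <- c(open_donors, donors[[m]])
    }
    if (length(open_donors)) {
      adj <- t(net2$rates) > 0   # adj[i, j]: i can hop to j
      reached <- rep(FALSE, nrow(adj)); reached[open_donors] <- TRUE
      repeat {
        new <- reached | (adj %*% reached > 0)
        if (identical(new, reached)) break
        reached <- new
      }
      if (!all(reached)) {
        warning("states disconnected from all open traps: ",
                paste(net2$states$state_id[!reached], collapse = ", "))
      }
    }
  }
  sc
}
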