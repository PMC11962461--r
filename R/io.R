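#' Read a kinetic network from disk
#'
#' Loads a rate matrix plus its per-state metadata table and returns a
#' validated \code{\link{kinetic_network}} in generator convention. The rate
#' matrix may be a dense TSV/CSV (N rows by N columns, no header) or a Matrix
#' Market coordinate file (\code{.mtx}); the state table is a TSV with header
#' columns \code{state_id, subunit, monomer, pigment, energy_cm1, x, y, z,
#' dipole_sq, is_chl_a} (optional columns may be absent). Row/column order of
#' the matrix must match the state-table row order.
#'
#' The on-disk dense layout is declared column-source: column j holds the
#' outflows of state j (\code{K[i,j]} = rate j to i). Deposits using the
#' opposite (row-source) orientation are read with \code{transpose = TRUE}.
#' Files may carry a zero diagonal or a generator diagonal; the diagonal is
#' re-derived either way.
#'
#' @param rate_matrix_path Path to the dense TSV/CSV or \code{.mtx} matrix.
#' @param state_table_path Path to the state table TSV.
#' @param transpose If TRUE, transpose the matrix on read (row-source files).
#' @param temperature Bath temperature in K.
#' @param quiet Suppress the provenance message.
#' @return A \code{kinetic_network}.
#' @export
read_network <- function(rate_matrix_path, state_table_path, transpose = FALSE,
                         temperature = 300, quiet = FALSE) {
  states <- read.delim(state_table_path, sep = "\t", stringsAsFactors = FALSE)
  if (grepl("\\.mtx$", rate_matrix_path, ignore.case = TRUE)) {
    K <- as.matrix(Matrix::readMM(rate_matrix_path))
  } else {
    first <- readLines(rate_matrix_path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    K <- as.matrix(read.delim(rate_matrix_path, sep = sep, header = FALSE))
  }
  dimnames(K) <- NULL
  if (transpose) K <- t(K)
  net <- kinetic_network(states, K, temperature = temperature)
  if (!quiet) {
    message(sprintf("read_network: N=%d states from %s + %s; energies %.1f..%.1f cm^-1",
                    n_states(net), basename(rate_matrix_path),
                    basename(state_table_path),
                    min(states$energy_cm1), max(states$energy_cm1)))
  }
  net
}

#' Write a kinetic network to disk
#'
#' Emits the dense rate-matrix TSV (generator convention, column-source
#' layout) and the state-table TSV consumed by \code{\link{read_network}}.
#' Dense round-trips are bit-exact: rates are written with full precision
#' (\code{format(..., digits = 17)}).
#'
#' @param net A \code{kinetic_network}.
#' @param rate_matrix_path,state_table_path Output paths.
#' @return Invisibly, the network.
#' @export
write_network <- function(net, rate_matrix_path, state_table_path) {
  stopifnot(inherits(net, "kinetic_network"))
  K <- format(net$rates, digits = 17, scientific = TRUE, trim = TRUE)
  write.table(K, rate_matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(net$states, state_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(net)
}

#' Read a scenario configuration file
#'
#' Parses a YAML scenario description with keys \code{temperature_K},
#' \code{trap.rate_ps}, \code{trap.open} (two logicals), \code{trap.donors}
#' (optional state ids), \code{losses.mean_fl_lifetime_ns},
#' \code{losses.nr_lifetime_ns}, and \code{remove_subunits}, and applies it
#' to a network.
#'
#' @param path YAML file path.
#' @param net The \code{kinetic_network} the scenario acts on.
#' @return A \code{\link{scenario}}.
#' @export
read_scenario_config <- function(path, net) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$temperature_K)) net$temperature <- cfg$temperature_K
  tr <- trap_spec(
    donor_state_ids = cfg$trap$donors,
    trap_rate = if (!is.null(cfg$trap$rate_ps)) cfg$trap$rate_ps else 1,
    open = if (!is.null(cfg$trap$open)) as.logical(cfg$trap$open) else c(TRUE, TRUE)
  )
  lo <- NULL
  if (!is.null(cfg$losses)) {
    lo <- loss_spec(
      mean_fl_lifetime_ns = if (!is.null(cfg$losses$mean_fl_lifetime_ns))
        cfg$losses$mean_fl_lifetime_ns else 16,
      nr_lifetime_ns = if (!is.null(cfg$losses$nr_lifetime_ns))
        cfg$losses$nr_lifetime_ns else 2
    )
  }
  sc <- scenario(net, traps = tr, losses = lo)
  if (!is.null(cfg$remove_subunits) && length(cfg$remove_subunits)) {
    sc <- remove_subunits(sc, cfg$remove_subunits)
  }
  sc
}
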