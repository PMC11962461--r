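#' Default PSII-mimetic subunit layout
#'
#' One monomer of a C2S2M2-like supercomplex: an RC flanked by the CP43 /
#' CP26 / S-LHCII chain on the D1 side and the CP47 / CP29 / CP24 / M-LHCII
#' chain on the D2 side. All subunit mean energies sit near 15000 cm^-1
#' (Chl a Qy region) with the RC slightly lowest — the shallow-funnel /
#' flat landscape characteristic of PSII, in contrast to a purple-bacterial
#' style energy funnel.
#'
#' @return data.frame with columns \code{name}, \code{n_states},
#'   \code{mean_energy}, \code{side}, \code{x}, \code{y} (layout
#'   coordinates, Angstrom).
#' @export
default_subunit_layout <- function() {
  data.frame(
    name = c("RC", "CP43", "CP26", "S-LHCII-A", "S-LHCII-B", "S-LHCII-C",
             "CP47", "CP29", "CP24", "M-LHCII-A", "M-LHCII-B", "M-LHCII-C"),
    n_states = c(6L, 7L, 5L, 6L, 6L, 6L, 7L, 5L, 4L, 6L, 6L, 6L),
    mean_energy = c(14880, 14920, 14930, 14940, 14940, 14940,
                    14925, 14935, 14940, 14945, 14945, 14945),
    side = c("RC", "D1", "D1", "D1", "D1", "D1",
             "D2", "D2", "D2", "D2", "D2", "D2"),
    x = c(0, -25, -50, -80, -95, -70, 25, 50, 75, 100, 115, 90),
    y = c(0, 10, 15, 25, 45, 55, 10, 15, 25, 25, 45, 55),
    stringsAsFactors = FALSE
  )
}

## adjacency between subunits within a monomer (chains mirroring the PSII
## arrangement: RC-CP43-CP26-S-LHCII on D1; RC-CP47-CP29-CP24-M-LHCII on D2;
## S-LHCII-C packs against CP43)
default_intra_edges <- function() {
  rbind(c("RC", "CP43"), c("CP43", "CP26"), c("CP26", "S-LHCII-A"),
        c("S-LHCII-A", "S-LHCII-B"), c("S-LHCII-B", "S-LHCII-C"),
        c("S-LHCII-C", "CP43"),
        c("RC", "CP47"), c("CP47", "CP29"), c("CP29", "CP24"),
        c("CP24", "M-LHCII-A"), c("M-LHCII-A", "M-LHCII-B"),
        c("M-LHCII-B", "M-LHCII-C"))
}

## cross-monomer adjacencies (core interface + M-trimer bridge); pairs are
## (subunit in monomer 1, subunit in monomer 2) and are mirrored internally
default_inter_edges <- function() {
  rbind(c("CP47", "CP43"), c("M-LHCII-C", "S-LHCII-C"))
}

#' Specification of a PSII-mimetic synthetic network
#'
#' Parameters of the generator in \code{\link{generate_mimic}}: a dimeric,
#' modular network with fast all-to-all transfer inside subunit clusters,
#' slower transfer between adjacent subunits, Gaussian site-energy disorder,
#' and exact Boltzmann detailed balance at the bath temperature.
#'
#' @param subunit_layout Per-monomer layout table
#'   (\code{\link{default_subunit_layout}}).
#' @param intra_rate_scale Typical intra-subunit rate scale, ps^-1
#'   (default 2.0 — sub-ps intracomplex equilibration).
#' @param inter_rate_scale Inter-subunit rate scale, ps^-1 (default 0.1 —
#'   the ~10 ps intercomplex hops that dominate trapping kinetics).
#' @param intra_edges,inter_edges Subunit adjacency tables (two-column
#'   character matrices); defaults mirror the PSII arrangement.
#' @param disorder_sigma Site-energy disorder SD, cm^-1 (default 80, a
#'   typical inhomogeneous broadening width for Chl in protein).
#' @param chl_b_shift Energy offset of Chl b states above the subunit mean,
#'   cm^-1 (default 600); only LHCII subunits carry Chl b.
#' @param temperature Bath temperature, K.
#' @param dimer_symmetric If TRUE (default) monomer 2 is an exact mirror
#'   copy of monomer 1 (same energies and couplings, reflected coordinates).
#' @param seed Integer seed.
#' @return Object of class \code{mimic_spec}.
#' @export
mimic_spec <- function(subunit_layout = default_subunit_layout(),
                       intra_rate_scale = 2.0, inter_rate_scale = 0.1,
                       intra_edges = default_intra_edges(),
                       inter_edges = default_inter_edges(),
                       disorder_sigma = 80, chl_b_shift = 600,
                       temperature = 300, dimer_symmetric = TRUE,
                       seed = 1L) {
  stopifnot(intra_rate_scale > 0, inter_rate_scale > 0, disorder_sigma >= 0)
  if (sum(subunit_layout$name == "RC") != 1) {
    stop("layout must contain exactly one RC subunit per monomer")
  }
  structure(list(subunit_layout = subunit_layout,
                 intra_rate_scale = intra_rate_scale,
                 inter_rate_scale = inter_rate_scale,
                 intra_edges = intra_edges, inter_edges = inter_edges,
                 disorder_sigma = disorder_sigma, chl_b_shift = chl_b_shift,
                 temperature = temperature,
                 dimer_symmetric = isTRUE(dimer_symmetric),
                 seed = as.integer(seed)),
            class = "mimic_spec")
}

## build the shared skeleton: state table (without energies) and the
## symmetric coupling matrix C (ps^-1 scales, detailed balance applied later)
mimic_skeleton <- function(spec, rng_seed) {
  lay <- spec$subunit_layout
  npm <- sum(lay$n_states)                 # states per monomer
  sub <- rep(lay$name, lay$n_states)
  side <- rep(lay$side, lay$n_states)
  within_idx <- unlist(lapply(lay$n_states, seq_len))
  ## Chl b: last ~40% of states in LHCII subunits
  is_lhcii <- grepl("LHCII", sub)
  frac <- (within_idx - 1) / rep(lay$n_states, lay$n_states)
  is_chl_a <- !(is_lhcii & frac >= 0.6)
  set.seed(rng_seed)
  ## per-monomer coordinates: subunit center + jitter
  cx <- rep(lay$x, lay$n_states) + rnorm(npm, 0, 4)
  cy <- rep(lay$y, lay$n_states) + rnorm(npm, 0, 4)
  cz <- rnorm(npm, 0, 3)
  dip <- exp(rnorm(npm, 0, 0.15)) * ifelse(is_chl_a, 1.0, 0.75)

  subunit_of <- function(k) sub[k]
  ## symmetric coupling scales within one monomer
  C1 <- matrix(0, npm, npm)
  for (s in lay$name) {
    i <- which(sub == s)
    C1[i, i] <- spec$intra_rate_scale *
      exp(matrix(runif(length(i)^2, -log(3), log(3)), length(i)))
  }
  for (r in seq_len(nrow(spec$intra_edges))) {
    i <- which(sub == spec$intra_edges[r, 1])
    j <- which(sub == spec$intra_edges[r, 2])
    B <- spec$inter_rate_scale *
      exp(matrix(runif(length(i) * length(j), -log(3), log(3)), length(i)))
    C1[i, j] <- B
    C1[j, i] <- t(B)
  }
  C1 <- (C1 + t(C1)) / 2
  diag(C1) <- 0
  ## cross-monomer couplings, symmetric under the monomer swap
  X <- matrix(0, npm, npm)
  for (r in seq_len(nrow(spec$inter_edges))) {
    i <- which(sub == spec$inter_edges[r, 1])   # monomer 1 labels
    j <- which(sub == spec$inter_edges[r, 2])   # monomer 2 labels
    B <- spec$inter_rate_scale *
      exp(matrix(runif(length(i) * length(j), -log(3), log(3)), length(i)))
    X[i, j] <- B
    X[j, i] <- t(B)        # mirrored edge (monomer 1 j-subunit to monomer 2 i-subunit)
  }
  X <- (X + t(X)) / 2      # swap symmetry: coupling (1,a)-(2,b) = (1,b)-(2,a)
  C <- rbind(cbind(C1, X), cbind(X, C1))
  states <- data.frame(
    state_id = c(paste0("m1_", sub, "_", within_idx),
                 paste0("m2_", sub, "_", within_idx)),
    subunit = rep(sub, 2),
    monomer = rep(c(1L, 2L), each = npm),
    pigment = rep(ifelse(is_chl_a, paste0("Chl_a_", sub, "_", within_idx),
                         paste0("Chl_b_", sub, "_", within_idx)), 2),
    energy_cm1 = NA_real_,
    x = c(cx, -cx), y = c(cy, -cy), z = c(cz, cz),
    dipole_sq = rep(dip, 2),
    is_chl_a = rep(is_chl_a, 2),
    stringsAsFactors = FALSE
  )
  list(states = states, C = C, npm = npm, sub = sub, side = side)
}

## draw per-monomer site energies for a skeleton (mirrored onto monomer 2)
mimic_energies <- function(spec, skel) {
  lay <- spec$subunit_layout
  mean_e <- rep(lay$mean_energy, lay$n_states)
  e1 <- mean_e + ifelse(skel$states$is_chl_a[seq_len(skel$npm)], 0,
                        spec$chl_b_shift) +
        rnorm(skel$npm, 0, spec$disorder_sigma)
  if (spec$dimer_symmetric) c(e1, e1)
  else c(e1, mean_e + ifelse(skel$states$is_chl_a[seq_len(skel$npm)], 0,
                             spec$chl_b_shift) +
               rnorm(skel$npm, 0, spec$disorder_sigma))
}

## assemble detailed-balanced rates from couplings and energies:
## k_ij = C_ij * exp(-(E_i - E_j) / (2 kB T)); the symmetric split makes
## detailed balance exact by construction
rates_from_energies <- function(C, E, temperature) {
  b2 <- 1 / (2 * .kB_cm1 * temperature)
  K <- C * exp(-outer(E, E, "-") * b2)
  diag(K) <- 0
  K
}

## label the lowest-energy RC state of each monomer as the CT state
mark_ct_states <- function(states) {
  for (m in c(1L, 2L)) {
    rc <- which(states$subunit == "RC" & states$monomer == m)
    if (length(rc)) {
      ct <- rc[which.min(states$energy_cm1[rc])]
      states$pigment[ct] <- "CT"
      states$is_chl_a[ct] <- FALSE
    }
  }
  states
}

#' Generate a PSII-mimetic kinetic network
#'
#' Builds a dimeric modular network with the statistical structure the
#' analysis assumes: all-to-all fast transfer within subunits, slower
#' nearest-subunit transfer following the PSII adjacency, near-degenerate
#' subunit energies with Gaussian site disorder, and rates
#' \eqn{k_{ij} = c_{ij} \exp(-(E_i - E_j)/2k_BT)} with symmetric
#' \eqn{c_{ij}} drawn log-uniform around the rate scales — a construction
#' that satisfies detailed balance exactly. The lowest-energy RC state of
#' each monomer is labelled "CT" (the trap donor). With
#' \code{dimer_symmetric} the two monomers are exact mirror images, so the
#' monomer-swap permutation maps the rate matrix onto itself.
#'
#' @param spec A \code{\link{mimic_spec}}.
#' @return A \code{kinetic_network} (140 states under the default layout).
#' @export
generate_mimic <- function(spec = mimic_spec()) {
  stopifnot(inherits(spec, "mimic_spec"))
  skel <- mimic_skeleton(spec, rng_seed = spec$seed)
  set.seed(spec$seed + 1000L)
  E <- mimic_energies(spec, skel)
  K <- rates_from_energies(skel$C, E, spec$temperature)
  st <- skel$states
  st$energy_cm1 <- E
  st <- mark_ct_states(st)
  kinetic_network(st, K, temperature = spec$temperature)
}

#' Generate a disorder ensemble of mimics
#'
#' \code{n} networks sharing one topology and coupling draw, differing only
#' by independently re-drawn Gaussian site energies — the static
#' inhomogeneous-broadening ensemble whose element-wise
#' \code{\link{average_rate_matrices}} feeds the ensemble analysis.
#'
#' @param spec A \code{\link{mimic_spec}}.
#' @param n Number of realizations (the reference analysis uses 500).
#' @return A \code{\link{disorder_ensemble}}.
#' @export
generate_disorder_ensemble <- function(spec = mimic_spec(), n = 500) {
  stopifnot(n >= 1)
  skel <- mimic_skeleton(spec, rng_seed = spec$seed)
  set.seed(spec$seed + 1000L)
  nets <- vector("list", n)
  for (r in seq_len(n)) {
    E <- mimic_energies(spec, skel)
    K <- rates_from_energies(skel$C, E, spec$temperature)
    st <- skel$states
    st$energy_cm1 <- E
    st <- mark_ct_states(st)
    nets[[r]] <- kinetic_network(st, K, temperature = spec$temperature)
  }
  disorder_ensemble(nets, seed = spec$seed)
}

#' Generate a funnel or flat control landscape
#'
#' Single-monomer chain networks used as contrast cases: \code{"funnel"}
#' has strictly decreasing energies toward the trap-adjacent end (the
#' purple-bacterial design); \code{"flat"} has equal energies (pure-entropy
#' dynamics). Both use nearest-neighbour chain connectivity plus the same
#' symmetric-split detailed-balanced rates as \code{\link{generate_mimic}}.
#' The final chain state is labelled subunit "RC" so scenarios can attach a
#' trap to it.
#'
#' @param kind \code{"funnel"} or \code{"flat"}.
#' @param n_states Chain length (>= 3).
#' @param rate_scale Coupling scale, ps^-1.
#' @param energy_drop Total funnel depth, cm^-1 (ignored for flat).
#' @param temperature Bath temperature, K.
#' @param seed Integer seed.
#' @return A \code{kinetic_network}.
#' @export
generate_control_landscape <- function(kind = c("funnel", "flat"),
                                       n_states = 12, rate_scale = 1.0,
                                       energy_drop = 800, temperature = 300,
                                       seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_states >= 3)
  set.seed(seed)
  E0 <- 15000
  E <- if (kind == "funnel") E0 + seq(energy_drop, 0, length.out = n_states)
       else rep(E0, n_states)
  C <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states - 1)) {
    C[i, i + 1] <- C[i + 1, i] <- rate_scale * exp(runif(1, -log(3), log(3)))
  }
  K <- rates_from_energies(C, E, temperature)
  st <- data.frame(
    state_id = sprintf("s%02d", seq_len(n_states)),
    subunit = c(rep("chain", n_states - 1), "RC"),
    monomer = 1L,
    pigment = sprintf("site_%02d", seq_len(n_states)),
    energy_cm1 = E,
    x = seq_len(n_states) * 10, y = 0, z = 0,
    dipole_sq = 1, is_chl_a = TRUE,
    stringsAsFactors = FALSE
  )
  kinetic_network(st, K, temperature = temperature)
}

#' Mirror permutation of a dimeric network
#'
#' The index permutation swapping monomer 1 and monomer 2 states (identity
#' on the per-monomer ordering). For a symmetric dimer the rate matrix is
#' invariant under this permutation.
#'
#' @param net A dimeric \code{kinetic_network} whose monomers list states in
#'   the same order.
#' @return Integer permutation vector of length N.
#' @export
mirror_permutation <- function(net) {
  m <- net$states$monomer
  n1 <- sum(m == 1L); n2 <- sum(m == 2L)
  if (n1 != n2) stop("monomers have unequal state counts")
  perm <- integer(n1 + n2)
  perm[m == 1L] <- which(m == 2L)
  perm[m == 2L] <- which(m == 1L)
  perm
}
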