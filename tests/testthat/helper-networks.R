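## Shared fixtures: all built in code, no files.

kBT300 <- eetherm::kB_cm1() * 300   # 208.5105 cm^-1

## Two-state closed system: state 1 at E = 0, state 2 at E2; downhill rate
## (2 -> 1) k_down = 1 ps^-1, uphill rate fixed by detailed balance.
two_state_net <- function(E2 = 208.51, k_down = 1) {
  k_up <- k_down * exp(-E2 / kBT300)
  st <- data.frame(state_id = c("lo", "hi"), subunit = "X", monomer = 1L,
                   pigment = c("lo", "hi"), energy_cm1 = c(0, E2),
                   dipole_sq = 1, is_chl_a = TRUE)
  K <- matrix(c(0, k_up, k_down, 0), 2, 2)   # K[i,j] = rate j -> i
  kinetic_network(st, K)
}

## closed-form relaxation of the two-state system from a delta on state 1
two_state_p2 <- function(t, E2 = 208.51, k_down = 1) {
  k_up <- k_down * exp(-E2 / kBT300)
  pi2 <- k_up / (k_down + k_up)
  pi2 * (1 - exp(-(k_down + k_up) * t))
}

## Reduced PSII-mimic layout (7 subunits / monomer, 64 states total):
## keeps the D1 / D2 chain structure at desk-test size.
mini_layout <- function() {
  data.frame(
    name = c("RC", "CP43", "CP26", "S-LHCII-B", "CP47", "CP29", "M-LHCII-B"),
    n_states = c(4L, 5L, 4L, 5L, 5L, 4L, 5L),
    mean_energy = c(14880, 14920, 14930, 14940, 14925, 14935, 14945),
    side = c("RC", "D1", "D1", "D1", "D2", "D2", "D2"),
    x = c(0, -25, -50, -80, 25, 50, 80),
    y = c(0, 10, 15, 30, 10, 15, 30),
    stringsAsFactors = FALSE
  )
}

mini_spec <- function(seed = 1L, ...) {
  mimic_spec(
    subunit_layout = mini_layout(),
    intra_edges = rbind(c("RC", "CP43"), c("CP43", "CP26"),
                        c("CP26", "S-LHCII-B"), c("RC", "CP47"),
                        c("CP47", "CP29"), c("CP29", "M-LHCII-B")),
    inter_edges = rbind(c("CP47", "CP43"), c("M-LHCII-B", "M-LHCII-B")),
    seed = seed, ...
  )
}

## Random connected detailed-balanced network with an RC state in each
## monomer half (path backbone + random chords).
random_two_trap_net <- function(n, seed, p_edge = 0.25) {
  set.seed(seed)
  E <- rnorm(n, 15000, 120)
  C <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    C[i, i + 1] <- C[i + 1, i] <- exp(runif(1, log(0.2), log(2)))
  }
  up <- which(upper.tri(C), arr.ind = TRUE)
  pick <- up[runif(nrow(up)) < p_edge, , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    v <- exp(runif(1, log(0.2), log(2)))
    C[pick[r, 1], pick[r, 2]] <- C[pick[r, 2], pick[r, 1]] <- v
  }
  K <- C * exp(-outer(E, E, "-") / (2 * kBT300))
  half <- n %/% 2
  monomer <- rep(c(1L, 2L), c(half, n - half))
  subunit <- rep("ANT", n)
  subunit[1] <- "RC"; subunit[n] <- "RC"
  st <- data.frame(state_id = sprintf("s%02d", seq_len(n)), subunit = subunit,
                   monomer = monomer, pigment = sprintf("p%02d", seq_len(n)),
                   energy_cm1 = E, dipole_sq = exp(rnorm(n, 0, 0.2)),
                   is_chl_a = TRUE)
  kinetic_network(st, K)
}

## Independent oracle: MFPT / lifetime as the time integral of the surviving
## probability, by adaptive quadrature over fresh matrix exponentials.
survival_quadrature <- function(gen, ic, rel.tol = 1e-9) {
  Q <- gen$Q
  z0 <- as.numeric(ic)
  f <- function(ts) {
    vapply(ts, function(t) sum(eetherm:::dense_expm(Q * t) %*% z0), 0)
  }
  stats::integrate(f, 0, Inf, rel.tol = rel.tol)$value
}

## Independent oracle: entropy argmax by brute force on a dense linear grid
## of n points over [0, t_max], stepping a single fixed-dt propagator.
dense_grid_contraction <- function(gen, ic, t_max, n = 1e5) {
  gen <- eetherm:::as_generator(gen)
  A <- eetherm:::extended_generator(gen)
  ntr <- ncol(gen$Q)
  dt <- t_max / (n - 1)
  M <- eetherm:::dense_expm(A * dt)
  z <- c(as.numeric(ic), numeric(4))
  best_t <- 0
  best_s <- shannon_entropy(pmax(z[seq_len(ntr)], 0))
  for (k in seq_len(n - 1)) {
    z <- M %*% z
    p <- pmax(z[seq_len(ntr)], 0)
    s <- shannon_entropy(p)
    if (s > best_s) { best_s <- s; best_t <- k * dt }
  }
  list(time = best_t, entropy = best_s)
}
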