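# shared fixtures and independent oracles, built in code at test time

default_pots <- cgfrac::default_potentials()

# a two-block system bonded at separation r along x
make_pair_system <- function(r, species = "P", mass = 1e6) {
  sys <- cgfrac::build_hexagonal_lattice(2, 1, spacing = 9.17,
                                         species = species, mass = mass)
  sys$positions[2, 1] <- sys$positions[1, 1] + r
  sys
}

# brute-force nearest-neighbour enumeration: all pairs within tol of spacing
brute_force_bonds <- function(positions, spacing, tol = 1e-6) {
  n <- nrow(positions)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((positions[j, ] - positions[i, ])^2))
    if (abs(d - spacing) < tol) out <- rbind(out, c(i, j))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# direct-summation virial stress oracle: explicit loop over the bond list,
# independent of the package's vectorised/compiled paths
brute_force_stress <- function(system, pots) {
  pos <- system$positions
  A <- diff(range(pos[, 1])) * diff(range(pos[, 2]))
  w <- matrix(0, 2, 2)
  for (b in seq_len(nrow(system$bonds))) {
    i <- system$bonds[b, 1]; j <- system$bonds[b, 2]
    rv <- pos[j, ] - pos[i, ]
    r <- sqrt(sum(rv^2))
    pot <- cgfrac::resolve_potential(pots, system$species[i], system$species[j])
    if (r > pot$rc) next
    fscal <- -2 * pot$k * (r - pot$r0)   # positive = repulsive
    Fj <- fscal * rv / r
    w <- w + outer(rv, Fj)
  }
  for (i in which(!system$clamped)) {
    v <- system$velocities[i, ]
    w <- w + system$mass[i] * outer(v, v)
  }
  w / A
}

# sum of pair energies over the bond list (oracle for total PE)
brute_force_energy <- function(system, pots) {
  tot <- 0
  for (b in seq_len(nrow(system$bonds))) {
    i <- system$bonds[b, 1]; j <- system$bonds[b, 2]
    r <- sqrt(sum((system$positions[j, ] - system$positions[i, ])^2))
    pot <- cgfrac::resolve_potential(pots, system$species[i], system$species[j])
    tot <- tot + cgfrac::pair_energy(pot, r)
  }
  tot
}

# total energy (PE + KE) of a system, for conservation checks
total_energy <- function(system, pots) {
  ke <- 0.5 * sum(system$mass * rowSums(system$velocities^2))
  brute_force_energy(system, pots) + ke
}

interior_bond_mean <- function(system) {
  deg <- tabulate(c(system$bonds), nbins = nrow(system$positions))
  interior <- which(deg == 6L)
  len <- cgfrac::bond_lengths(system)
  both <- system$bonds[, 1] %in% interior & system$bonds[, 2] %in% interior
  mean(len[both])
}
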