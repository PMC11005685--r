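# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity with the plainest possible formulation (scalar
# or row-wise loops, no shared code with the package internals).

mi_oracle <- function(d, box) d - box * round(d / box)

# O(N^2) all-pairs minimum-image distance, row-wise
oracle_dist <- function(coords, box) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dx <- mi_oracle(coords[i, 1] - coords[, 1], box)
    dy <- mi_oracle(coords[i, 2] - coords[, 2], box)
    dz <- mi_oracle(coords[i, 3] - coords[, 3], box)
    d[i, ] <- sqrt(dx^2 + dy^2 + dz^2)
  }
  d
}

# brute-force intermolecular LJ + Coulomb sums
oracle_pair_energy <- function(state, ff) {
  b <- state$beads
  d <- oracle_dist(state$coords, state$box_edge)
  vdw <- 0; ele <- 0
  n <- nrow(b)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (b$molecule_id[i] == b$molecule_id[j]) next
    r <- d[i, j]
    if (!is.null(ff$cutoff) && r > ff$cutoff) next
    sij <- (b$lj_sigma[i] + b$lj_sigma[j]) / 2
    eij <- sqrt(b$lj_epsilon[i] * b$lj_epsilon[j])
    vdw <- vdw + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    ele <- ele + ff$coulomb_constant * b$charge[i] * b$charge[j] /
      (ff$dielectric * r)
  }
  list(vdw = vdw, ele = ele)
}

# brute-force per-molecule CTD neighbour counts (surface distance <= cutoff)
oracle_sat_counts <- function(state, cutoff) {
  b <- state$beads
  mols <- sort(unique(b$molecule_id))
  counts <- integer(length(mols))
  for (a in seq_along(mols)) {
    ia <- which(b$molecule_id == mols[a] & b$group == "CTD")
    for (bb in seq_along(mols)) {
      if (a == bb) next
      ib <- which(b$molecule_id == mols[bb] & b$group == "CTD")
      dmin <- Inf
      for (i in ia) for (j in ib) {
        dx <- mi_oracle(state$coords[i, 1] - state$coords[j, 1], state$box_edge)
        dy <- mi_oracle(state$coords[i, 2] - state$coords[j, 2], state$box_edge)
        dz <- mi_oracle(state$coords[i, 3] - state$coords[j, 3], state$box_edge)
        s <- sqrt(dx^2 + dy^2 + dz^2) - b$radius[i] - b$radius[j]
        dmin <- min(dmin, s)
      }
      if (dmin <= cutoff) counts[a] <- counts[a] + 1L
    }
  }
  counts
}

# BFS connected components over the full O(N^2) molecule contact matrix
oracle_clusters <- function(state, cutoff) {
  b <- state$beads
  mols <- sort(unique(b$molecule_id))
  nmol <- length(mols)
  d <- oracle_dist(state$coords, state$box_edge)
  contact <- matrix(FALSE, nmol, nmol)
  for (a in seq_len(nmol)) for (bb in seq_len(nmol)) {
    if (a == bb) next
    ia <- which(b$molecule_id == mols[a])
    ib <- which(b$molecule_id == mols[bb])
    surf <- d[ia, ib, drop = FALSE] -
      outer(b$radius[ia], b$radius[ib], "+")
    if (min(surf) <= cutoff) contact[a, bb] <- TRUE
  }
  labels <- integer(nmol)
  lab <- 0L
  for (start in seq_len(nmol)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (labels[v] != 0L) next
      labels[v] <- lab
      queue <- c(queue, which(contact[v, ] & labels == 0L))
    }
  }
  setNames(labels, mols)
}

# analytic accessible area of two intersecting equal-or-unequal spheres
# (inflated radii R1, R2 at centre distance d): total area minus the two
# spherical caps buried inside the other sphere
oracle_two_sphere_area <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  # cap heights from the sphere-sphere intersection plane
  x <- (d^2 - R2^2 + R1^2) / (2 * d)  # distance of plane from centre 1
  h1 <- R1 - x
  h2 <- R2 - (d - x)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

# random multi-molecule test frame with full physical parameters
make_random_state <- function(n_mol, n_bead, box = 30, seed = 1,
                              charge_frac = 0.3, spread = NULL) {
  set.seed(seed)
  n <- n_mol * n_bead
  beads <- data.frame(
    bead_id = seq_len(n),
    molecule_id = rep(seq_len(n_mol), each = n_bead),
    group = rep(c("CTD", rep("RESIDUE", n_bead - 1L)), n_mol),
    residue_code = rep(c("CHOL", rep("A", n_bead - 1L)), n_mol),
    charge = ifelse(runif(n) < charge_frac, 1, 0),
    lj_epsilon = rep(c(1.5, rep(0.2, n_bead - 1L)), n_mol),
    lj_sigma = rep(c(6.0, rep(4.5, n_bead - 1L)), n_mol),
    radius = rep(c(3.0, rep(2.25, n_bead - 1L)), n_mol),
    mass = rep(c(40, rep(10, n_bead - 1L)), n_mol),
    stringsAsFactors = FALSE
  )
  if (is.null(spread)) spread <- box
  # molecules as loose blobs so distances stay physical (> ~2 A)
  centers <- matrix(runif(3 * n_mol, 0, spread), n_mol, 3)
  coords <- centers[beads$molecule_id, ] +
    matrix(rnorm(3 * n, sd = 3), n, 3)
  # push apart any strongly overlapping pair (keeps forces well-scaled)
  repeat {
    d <- oracle_dist(coords, box)
    diag(d) <- Inf
    if (min(d) > 2.5) break
    i <- which(d == min(d), arr.ind = TRUE)[1, 1]
    coords[i, ] <- coords[i, ] + rnorm(3, sd = 2)
  }
  system_state(beads, coords, box)
}

# minimal two-bead state on different molecules at a given separation
two_bead_state <- function(r, box = 100, charge = c(0, 0), eps = c(1, 1),
                           sigma = c(4, 4), same_molecule = FALSE) {
  beads <- data.frame(
    bead_id = 1:2,
    molecule_id = if (same_molecule) c(1L, 1L) else c(1L, 2L),
    group = c("CTD", "CTD"),
    residue_code = c("CHOL", "CHOL"),
    charge = charge, lj_epsilon = eps, lj_sigma = sigma,
    radius = sigma / 2, mass = c(10, 10),
    stringsAsFactors = FALSE
  )
  system_state(beads, rbind(c(10, 10, 10), c(10 + r, 10, 10)), box)
}

# harmonic dimer (one molecule, two bonded beads), no charges
dimer_state <- function(r, box = 100) {
  beads <- data.frame(
    bead_id = 1:2, molecule_id = c(1L, 1L),
    group = c("CTD", "RESIDUE"), residue_code = c("CHOL", "A"),
    charge = c(0, 0), lj_epsilon = c(0.2, 0.2), lj_sigma = c(4, 4),
    radius = c(2, 2), mass = c(10, 10), stringsAsFactors = FALSE
  )
  system_state(beads, rbind(c(20, 20, 20), c(20 + r, 20, 20)), box)
}

# n independent single-bead molecules (ideal gas when eps = charge = 0)
gas_state <- function(n, box = 60, seed = 1, mass = 10) {
  set.seed(seed)
  beads <- data.frame(
    bead_id = seq_len(n), molecule_id = seq_len(n),
    group = "CTD", residue_code = "CHOL",
    charge = 0, lj_epsilon = 0, lj_sigma = 4, radius = 2, mass = mass,
    stringsAsFactors = FALSE
  )
  system_state(beads, matrix(runif(3 * n, 0, box), n, 3), box)
}

write_lib_file <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("name,sequence,modified", rows), path)
  path
}
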