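#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the bead model: each bead's sphere is inflated
#' by the probe radius and sampled with a deterministic Fibonacci-lattice
#' point set; a point is accessible when it lies outside every other bead's
#' inflated sphere. Per-bead area is
#' \eqn{4\pi(r+p)^2 \times n_{acc}/n_{points}}. Geometry is open-space:
#' callers keep molecules whole (the dynamics engine stores unwrapped
#' coordinates).
#'
#' @param state a \code{system_state}, or an N x 3 coordinate matrix.
#' @param radii per-bead radii in A (defaults to \code{beads$radius}).
#' @param probe probe radius, A (1.4 = water).
#' @param n_points quadrature points per sphere (>= 92; default 960).
#' @return list: \code{per_bead} (A^2 per bead) and \code{total} (A^2).
#' @export
sasa_shrake_rupley <- function(state, radii = NULL, probe = 1.4,
                               n_points = 960) {
  coords <- if (inherits(state, "system_state")) state$coords else
    as.matrix(state)
  if (is.null(radii)) {
    if (!inherits(state, "system_state") || is.null(state$beads$radius)) {
      stop("radii must be supplied when state carries no bead radii",
           call. = FALSE)
    }
    radii <- state$beads$radius
  }
  stopifnot(length(radii) == nrow(coords), all(radii > 0),
            probe >= 0, n_points >= 92)
  per_bead <- sasa_cpp(coords, radii, probe, as.integer(n_points))
  list(per_bead = as.numeric(per_bead), total = sum(per_bead))
}

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum m_i |x_i - x_{cm}|^2 / \sum m_i}} over the full
#' bead set, computed on the coordinates as stored (unwrapped, molecules
#' whole).
#'
#' @param state a \code{system_state} or coordinate matrix.
#' @param masses per-bead masses (defaults to \code{beads$mass}; unit
#'   masses when neither is available).
#' @return Rg in A.
#' @export
radius_of_gyration <- function(state, masses = NULL) {
  coords <- if (inherits(state, "system_state")) state$coords else
    as.matrix(state)
  if (is.null(masses)) {
    masses <- if (inherits(state, "system_state") &&
                  !is.null(state$beads$mass)) state$beads$mass else
      rep(1, nrow(coords))
  }
  stopifnot(length(masses) == nrow(coords), sum(masses) > 0)
  com <- colSums(coords * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2, com)^2)) / sum(masses))
}

#' Intermolecular vacuum potential energy decomposition
#'
#' Sums over inter-molecular bead pairs only, under the minimum-image
#' convention: \code{vdw} is the 12-6 Lennard-Jones sum with
#' Lorentz-Berthelot mixing, \code{ele} the screened Coulomb sum
#' \eqn{k_C q_i q_j/(\epsilon_r r)}. Full pairwise by default (no cutoff).
#' This is an independent, vectorised implementation used to cross-check
#' the simulator's internal energies.
#'
#' @param state a \code{system_state} with full bead parameters.
#' @param ff a \code{force_field_params}.
#' @return list with \code{vdw} and \code{ele}, kcal/mol.
#' @export
vacuum_energy <- function(state, ff = force_field_params()) {
  check_ff_state(state, ff)
  b <- state$beads
  n <- nrow(b)
  if (n < 2L) return(list(vdw = 0, ele = 0))
  co <- state$coords
  d <- cross_min_image_dist(co, co, state$box_edge)
  inter <- outer(b$molecule_id, b$molecule_id, "!=")
  upper <- upper.tri(d)
  sel <- inter & upper
  if (!is.null(ff$cutoff)) sel <- sel & (d <= ff$cutoff)
  if (!any(sel)) return(list(vdw = 0, ele = 0))
  r <- d[sel]
  if (any(r < 1e-6)) {
    stop("singularity: coincident beads in different molecules",
         call. = FALSE)
  }
  sij <- outer(b$lj_sigma, b$lj_sigma, "+")[sel] / 2
  eij <- sqrt(outer(b$lj_epsilon, b$lj_epsilon))[sel]
  qq <- outer(b$charge, b$charge)[sel]
  sr6 <- (sij / r)^6
  list(
    vdw = sum(4 * eij * (sr6^2 - sr6)),
    ele = sum(ff$coulomb_constant * qq / (ff$dielectric * r))
  )
}

# surface distance matrix between CTD groups of all molecules (min image);
# group-group distance = min over bead pairs of (centre dist - r_i - r_j)
ctd_surface_dist <- function(state) {
  b <- state$beads
  is_ctd <- b$group == "CTD"
  mols <- sort(unique(b$molecule_id))
  no_ctd <- vapply(mols, function(m) !any(is_ctd & b$molecule_id == m),
                   logical(1))
  if (any(no_ctd)) {
    stop(sprintf("molecule(s) without a CTD bead: %s",
                 paste(mols[no_ctd], collapse = ", ")), call. = FALSE)
  }
  idx <- which(is_ctd)
  d <- cross_min_image_dist(state$coords[idx, , drop = FALSE],
                            state$coords[idx, , drop = FALSE],
                            state$box_edge)
  surf <- d - outer(b$radius[idx], b$radius[idx], "+")
  mm <- b$molecule_id[idx]
  nmol <- length(mols)
  out <- matrix(Inf, nmol, nmol)
  for (a in seq_len(nmol)) {
    ia <- which(mm == mols[a])
    for (bb in seq_len(nmol)) {
      if (a == bb) next
      out[a, bb] <- min(surf[ia, mm == mols[bb], drop = FALSE])
    }
  }
  dimnames(out) <- list(mols, mols)
  out
}

#' Saturation number of the hydrophobic terminal domains
#'
#' For each molecule's CTD (cholesterol terminal domain) group, counts the
#' other molecules whose CTD group lies within \code{cutoff} of it, where
#' the group-group distance is the minimum bead-to-bead surface distance
#' (centre distance minus both radii) under the minimum-image convention.
#' The per-frame maximum and minimum over molecules mirror the
#' "max/min number of hydrophobic regions around the core" readout.
#'
#' @param state a \code{system_state}; every molecule must have a CTD bead.
#' @param cutoff surface-distance cutoff, A (default 3.0).
#' @return list: \code{counts} (per molecule, named by molecule id),
#'   \code{max}, \code{min}.
#' @export
saturation_number <- function(state, cutoff = 3.0) {
  stopifnot(cutoff > 0)
  surf <- ctd_surface_dist(state)
  counts <- rowSums(surf <= cutoff)
  list(counts = counts, max = max(counts), min = min(counts))
}

#' Per-frame metric series for a trajectory
#'
#' Computes the four screening observables (total SASA, Rg, intermolecular
#' VDW and ELE energies), the CTD saturation extremes and the
#' largest-cluster fraction, one row per frame.
#'
#' @param traj a \code{cg_trajectory} or list of \code{system_state}.
#' @param ff force-field parameters (for the energy terms).
#' @param probe,n_points SASA settings (see [sasa_shrake_rupley()]).
#' @param sat_cutoff saturation-number surface cutoff, A.
#' @param contact_cutoff clustering contact cutoff, A (see
#'   [cluster_molecules()]).
#' @return data.frame of class \code{metric_series}: columns \code{time},
#'   \code{sasa_total} (A^2), \code{rg} (A), \code{vdw}, \code{ele}
#'   (kcal/mol), \code{sat_max}, \code{sat_min},
#'   \code{largest_cluster_fraction}.
#' @export
compute_metrics <- function(traj, ff = force_field_params(), probe = 1.4,
                            n_points = 960, sat_cutoff = 3.0,
                            contact_cutoff = 4.5) {
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  stopifnot(length(frames) >= 1L)
  rows <- lapply(frames, function(st) {
    en <- vacuum_energy(st, ff)
    sat <- saturation_number(st, sat_cutoff)
    cl <- cluster_molecules(st, contact_cutoff)
    data.frame(
      time = st$time,
      sasa_total = sasa_shrake_rupley(st, probe = probe,
                                      n_points = n_points)$total,
      rg = radius_of_gyration(st),
      vdw = en$vdw, ele = en$ele,
      sat_max = sat$max, sat_min = sat$min,
      largest_cluster_fraction = max(tabulate(cl)) / length(cl)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_series", "data.frame")
  out
}

#' Mean and sample SD of metric series after burn-in
#'
#' Drops the first \code{floor(n * burn_in_fraction)} frames and reports
#' the arithmetic mean and sample standard deviation (n - 1 denominator)
#' of what remains, per metric.
#'
#' @param series a \code{metric_series} data.frame or a numeric vector.
#' @param burn_in_fraction fraction of initial frames to discard
#'   (default 0.5).
#' @return for a vector: list(mean, sd, n_frames, burn_in_fraction); for a
#'   data.frame: one row per metric column with those fields.
#' @export
summarize_metrics <- function(series, burn_in_fraction = 0.5) {
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  if (is.numeric(series) && is.null(dim(series))) {
    v <- drop_burn_in(series, burn_in_fraction)
    return(list(mean = mean(v), sd = sd(v), n_frames = length(v),
                burn_in_fraction = burn_in_fraction))
  }
  stopifnot(is.data.frame(series))
  cols <- setdiff(names(series)[vapply(series, is.numeric, logical(1))],
                  "time")
  out <- do.call(rbind, lapply(cols, function(cn) {
    v <- drop_burn_in(series[[cn]], burn_in_fraction)
    data.frame(metric = cn, mean = mean(v), sd = sd(v),
               n_frames = length(v), stringsAsFactors = FALSE)
  }))
  out$burn_in_fraction <- burn_in_fraction
  out
}

drop_burn_in <- function(v, burn_in_fraction) {
  n <- length(v)
  keep <- v[(floor(n * burn_in_fraction) + 1L):n]
  if (length(keep) < 2L) {
    stop(sprintf(
      "insufficient data: %d frame(s) remain after burn-in; need >= 2",
      length(keep)), call. = FALSE)
  }
  keep
}
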