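#' Cluster molecules by inter-molecular contact
#'
#' Two molecules are in contact when any inter-molecular bead pair has
#' minimum-image surface distance (centre distance minus both radii) at or
#' below \code{contact_cutoff}. Clusters are the connected components of
#' the contact graph; labels are canonicalised so that cluster 1 contains
#' the lowest molecule id, cluster 2 the lowest id not in cluster 1, and so
#' on.
#'
#' @param state a \code{system_state} with bead radii.
#' @param contact_cutoff surface-distance cutoff, A (default 4.5).
#' @return integer vector of cluster labels, one per molecule (ordered by
#'   molecule id), named by molecule id.
#' @export
cluster_molecules <- function(state, contact_cutoff = 4.5) {
  stopifnot(contact_cutoff > 0)
  b <- state$beads
  mols <- sort(unique(b$molecule_id))
  nmol <- length(mols)
  if (nmol == 1L) return(setNames(1L, mols))
  d <- cross_min_image_dist(state$coords, state$coords, state$box_edge)
  surf <- d - outer(b$radius, b$radius, "+")
  adj <- matrix(FALSE, nmol, nmol)
  for (a in seq_len(nmol - 1L)) {
    ia <- b$molecule_id == mols[a]
    for (bb in (a + 1L):nmol) {
      ib <- b$molecule_id == mols[bb]
      if (min(surf[ia, ib]) <= contact_cutoff) {
        adj[a, bb] <- adj[bb, a] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  # canonicalise: relabel components by their smallest molecule id
  first_of <- vapply(split(seq_len(nmol), memb), min, 0L)
  relabel <- match(memb, memb[sort(first_of)])
  setNames(as.integer(relabel), mols)
}

#' Relative shape anisotropy from the gyration tensor
#'
#' \eqn{\kappa^2 = 1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#' \lambda_3\lambda_1)/(\lambda_1+\lambda_2+\lambda_3)^2}, computed from
#' the mass-weighted gyration tensor eigenvalues. 0 for spherically
#' symmetric arrangements, 1 for collinear ones.
#'
#' @param coords n x 3 coordinate matrix.
#' @param masses per-point masses (unit by default).
#' @return kappa-squared in [0, 1]; 0 for a single point.
#' @export
shape_anisotropy <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (nrow(coords) < 2L) return(0)
  com <- colSums(coords * masses) / sum(masses)
  xc <- sweep(coords, 2, com)
  s <- crossprod(xc * masses, xc) / sum(masses)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(ev)
  if (tr <= 0) return(0)
  k2 <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / tr^2
  min(max(k2, 0), 1)
}

#' Aggregation timeline of a trajectory
#'
#' Per frame: the contact-cluster partition, the largest-cluster fraction
#' (largest cluster size over molecule count), the number of clusters and
#' the relative shape anisotropy of the largest cluster's beads (ties
#' broken toward the cluster containing the lowest molecule id, i.e.
#' cluster label 1's competitor set).
#'
#' @param traj a \code{cg_trajectory} or list of \code{system_state}
#'   (>= 2 frames).
#' @param contact_cutoff clustering cutoff, A.
#' @return data.frame of class \code{aggregation_timeline}: columns
#'   \code{time}, \code{largest_cluster_fraction}, \code{n_clusters},
#'   \code{kappa_sq}.
#' @export
build_timeline <- function(traj, contact_cutoff = 4.5) {
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  if (length(frames) < 2L) {
    stop("need at least 2 frames to build a timeline", call. = FALSE)
  }
  rows <- lapply(frames, function(st) {
    cl <- cluster_molecules(st, contact_cutoff)
    sizes <- tabulate(cl)
    big <- which.max(sizes)  # which.max takes the lowest label on ties
    big_mols <- as.integer(names(cl)[cl == big])
    sel <- st$beads$molecule_id %in% big_mols
    data.frame(
      time = st$time,
      largest_cluster_fraction = sizes[big] / length(cl),
      n_clusters = length(sizes),
      kappa_sq = shape_anisotropy(st$coords[sel, , drop = FALSE],
                                  st$beads$mass[sel])
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aggregation_timeline", "data.frame")
  out
}

#' Classify aggregation kinetics
#'
#' Mirrors the three observed behaviours: systems that aggregate within
#' the early window and stay assembled as a sphere-like cluster
#' (\code{fast_stable}), systems that assemble but fail to hold a compact
#' sphere-like structure (\code{transient}), and systems that never
#' assemble (\code{non_aggregator}). Windows are fractions of the frame
#' count: the early window is the first \code{early_fraction} (default
#' 0.05, the 10-of-200 ns ratio), excluding the time-0 frame when more
#' frames are available -- the packed starting configuration is
#' contact-percolated by construction and carries no kinetic information --
#' and the final window is the last \code{final_fraction}.
#'
#' @param tl an \code{aggregation_timeline}.
#' @param early_fraction early-window fraction of frames (default 0.05).
#' @param assembled_threshold largest-cluster fraction counted as
#'   assembled (default 0.4, a plurality cluster of a 16-molecule system).
#' @param stable_threshold final-window mean fraction required for a
#'   stable assembly (default 0.5).
#' @param sphere_threshold max final-window mean kappa-squared for a
#'   sphere-like cluster (default 0.2).
#' @param final_fraction final-window fraction of frames (default 0.25).
#' @return one of \code{"fast_stable"}, \code{"transient"},
#'   \code{"non_aggregator"}.
#' @export
classify_kinetics <- function(tl, early_fraction = 0.05,
                              assembled_threshold = 0.4,
                              stable_threshold = 0.5,
                              sphere_threshold = 0.2,
                              final_fraction = 0.25) {
  stopifnot(inherits(tl, "data.frame"),
            early_fraction > 0, early_fraction < 1,
            assembled_threshold > 0, assembled_threshold < 1,
            stable_threshold > 0, stable_threshold < 1)
  n <- nrow(tl)
  early_idx <- seq_len(max(1L, floor(n * early_fraction)))
  if (n > length(early_idx)) early_idx <- early_idx + 1L  # skip t = 0
  final_idx <- (n - max(1L, floor(n * final_fraction)) + 1L):n
  if (length(early_idx) == 0L || length(final_idx) == 0L) {
    stop("insufficient data: a classification window contains no frames",
         call. = FALSE)
  }
  early_mean <- mean(tl$largest_cluster_fraction[early_idx])
  final_mean <- mean(tl$largest_cluster_fraction[final_idx])
  final_k2 <- mean(tl$kappa_sq[final_idx])
  if (final_mean < assembled_threshold) return("non_aggregator")
  if (early_mean >= assembled_threshold && final_mean >= stable_threshold &&
      final_k2 <= sphere_threshold) {
    return("fast_stable")
  }
  "transient"
}
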