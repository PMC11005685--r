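#' Construct a system state
#'
#' A \code{system_state} holds the concatenated bead table of all molecules,
#' an \code{N x 3} coordinate matrix in Angstrom, the cubic box edge and a
#' time stamp in reduced time units. Coordinates are kept unwrapped per
#' molecule (molecules are never split across the periodic boundary);
#' interactions always use the minimum-image convention, so absolute
#' wrapping is immaterial to the physics.
#'
#' @param beads data.frame with one row per bead (columns as produced by
#'   [to_molecule_spec()], with \code{molecule_id} distinguishing copies).
#' @param coords numeric matrix, \code{nrow(beads)} rows, 3 columns (A).
#' @param box_edge cubic box edge, A.
#' @param time time stamp, reduced units.
#' @return object of class \code{system_state}.
#' @export
system_state <- function(beads, coords, box_edge, time = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (!is.data.frame(beads) || nrow(beads) == 0L) {
    stop("beads must be a non-empty data.frame", call. = FALSE)
  }
  if (nrow(coords) != nrow(beads) || ncol(coords) != 3L) {
    stop(sprintf("coords must be %d x 3, got %d x %d",
                 nrow(beads), nrow(coords), ncol(coords)), call. = FALSE)
  }
  if (!is.numeric(box_edge) || length(box_edge) != 1L || box_edge <= 0) {
    stop("box_edge must be a single positive number", call. = FALSE)
  }
  structure(
    list(beads = beads, coords = coords, box_edge = as.numeric(box_edge),
         time = as.numeric(time)),
    class = "system_state"
  )
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf(
    "<system_state> %d beads, %d molecules, box %.1f A, t = %.3f\n",
    nrow(x$beads), length(unique(x$beads$molecule_id)), x$box_edge, x$time
  ))
  invisible(x)
}

#' Minimum-image displacement components
#' @param d vector/matrix of coordinate differences.
#' @param box_edge cubic box edge.
#' @return displacements folded into \code{[-box/2, box/2)}.
#' @export
min_image <- function(d, box_edge) d - box_edge * round(d / box_edge)

#' All minimum-image distances between two coordinate sets
#' @noRd
cross_min_image_dist <- function(a, b, box_edge) {
  # a: n x 3, b: m x 3 -> n x m distance matrix under minimum image
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box_edge)
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box_edge)
  dz <- min_image(outer(a[, 3], b[, 3], "-"), box_edge)
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Wrap each molecule's centre of mass into the primary box
#'
#' Rigidly translates every molecule by an integer number of box lengths so
#' that its centre of mass lies in \code{[0, box_edge)}; molecules stay
#' whole. Used before writing frames and before geometric metrics.
#'
#' @param state a \code{system_state}.
#' @return a \code{system_state} with translated coordinates.
#' @export
wrap_molecules <- function(state) {
  co <- state$coords
  for (m in unique(state$beads$molecule_id)) {
    i <- which(state$beads$molecule_id == m)
    w <- state$beads$mass[i]
    if (all(is.na(w)) || sum(w, na.rm = TRUE) <= 0) w <- rep(1, length(i))
    com <- colSums(co[i, , drop = FALSE] * w) / sum(w)
    shift <- floor(com / state$box_edge) * state$box_edge
    co[i, ] <- sweep(co[i, , drop = FALSE], 2, shift)
  }
  state$coords <- co
  state
}

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pack molecule copies into a cubic periodic box
#'
#' Places \code{n_copies} of a coarse-grained molecule at random positions
#' and orientations in a cubic box, mirroring a Packmol-style setup: each
#' chain is grown as a self-avoiding walk with fixed bond length, then the
#' whole molecule is dropped at a random location and accepted only if no
#' inter-molecular bead pair comes closer than \code{min_separation} under
#' the minimum-image convention. Deterministic for a fixed seed.
#'
#' @param spec a \code{molecule_spec} from [to_molecule_spec()].
#' @param n_copies number of molecules (16 in the reference screen setup).
#' @param box_edge cubic box edge in A (110 in the reference setup).
#' @param min_separation minimum inter-molecular bead-centre distance, A.
#' @param seed integer RNG seed (R's RNG state is saved and restored).
#' @param bond_length fixed bond length of the self-avoiding walk, A.
#' @param max_attempts placement attempts per molecule before giving up.
#' @return a \code{system_state} at time 0.
#' @export
pack_system <- function(spec, n_copies, box_edge = 110,
                        min_separation = 3.0, seed = 1,
                        bond_length = 4.0, max_attempts = 1e5) {
  stopifnot(inherits(spec, "molecule_spec"), n_copies >= 1)
  if (box_edge <= 2 * min_separation) {
    stop("box_edge must exceed twice min_separation", call. = FALSE)
  }
  n_bead <- nrow(spec$beads)
  run_with_seed(seed, {
    placed <- NULL  # accumulated coordinates of accepted molecules
    coords_list <- vector("list", n_copies)
    for (m in seq_len(n_copies)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        chain <- grow_saw(n_bead, bond_length, min_separation)
        if (is.null(chain)) next
        origin <- runif(3, 0, box_edge)
        cand <- sweep(chain, 2, origin, "+")
        if (!is.null(placed)) {
          dmin <- min(cross_min_image_dist(cand, placed, box_edge))
          if (dmin < min_separation) next
        }
        coords_list[[m]] <- cand
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf(
          paste0("failed to place molecule %d of %d after %d attempts; ",
                 "use a larger box or smaller min_separation"),
          m, n_copies, max_attempts
        ), call. = FALSE)
      }
    }
    beads <- spec$beads[rep(seq_len(n_bead), n_copies), , drop = FALSE]
    beads$molecule_id <- rep(seq_len(n_copies), each = n_bead)
    beads$bead_id <- seq_len(n_bead * n_copies)
    rownames(beads) <- NULL
    st <- system_state(beads, do.call(rbind, coords_list), box_edge, time = 0)
    wrap_molecules(st)
  })
}

# Self-avoiding walk with fixed bond length; returns NULL on dead end.
grow_saw <- function(n_bead, bond_length, self_min, tries_per_bead = 50L) {
  xyz <- matrix(0, n_bead, 3)
  if (n_bead == 1L) return(xyz)
  for (j in 2:n_bead) {
    placed_one <- FALSE
    for (k in seq_len(tries_per_bead)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u * u))
      p <- xyz[j - 1L, ] + bond_length * u
      if (j > 2L) {
        prev <- xyz[seq_len(j - 2L), , drop = FALSE]
        d2 <- rowSums(sweep(prev, 2, p)^2)
        if (min(d2) < self_min^2) next
      }
      xyz[j, ] <- p
      placed_one <- TRUE
      break
    }
    if (!placed_one) return(NULL)
  }
  xyz
}

#' Replicate a molecule's bead table across copies
#' @noRd
replicate_beads <- function(spec, n_copies) {
  n_bead <- nrow(spec$beads)
  beads <- spec$beads[rep(seq_len(n_bead), n_copies), , drop = FALSE]
  beads$molecule_id <- rep(seq_len(n_copies), each = n_bead)
  beads$bead_id <- seq_len(n_bead * n_copies)
  rownames(beads) <- NULL
  beads
}
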