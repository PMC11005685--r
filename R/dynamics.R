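KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/(mol K)

#' Force-field parameters for the coarse-grained model
#'
#' The interaction model is: harmonic bonds \eqn{E = k/2 (r - r_0)^2} along
#' each chain, plus, between beads of different molecules only, a 12-6
#' Lennard-Jones term under Lorentz-Berthelot mixing and a screened Coulomb
#' term \eqn{k_C q_i q_j / (\epsilon_r r)}. Intramolecular nonbonded pairs
#' are excluded. The dielectric constant is an implicit-solvent knob that
#' stands in for aqueous screening.
#'
#' @param mixing mixing rule tag; only \code{"lorentz-berthelot"} supported.
#' @param coulomb_constant kcal A / (mol e^2); 332.0636 by convention.
#' @param dielectric relative dielectric, >= 1 (default 10).
#' @param bond_k harmonic bond constant, kcal/(mol A^2).
#' @param bond_r0 equilibrium bond length, A.
#' @param cutoff nonbonded cutoff in A, or \code{NULL} for full pairwise.
#' @return list of class \code{force_field_params}.
#' @export
force_field_params <- function(mixing = "lorentz-berthelot",
                               coulomb_constant = 332.0636,
                               dielectric = 10, bond_k = 10,
                               bond_r0 = 4.0, cutoff = NULL) {
  mixing <- match.arg(mixing, "lorentz-berthelot")
  stopifnot(dielectric >= 1, bond_k > 0, bond_r0 > 0, coulomb_constant > 0)
  if (!is.null(cutoff)) stopifnot(cutoff > 0)
  structure(
    list(mixing = mixing, coulomb_constant = coulomb_constant,
         dielectric = dielectric, bond_k = bond_k, bond_r0 = bond_r0,
         cutoff = cutoff),
    class = "force_field_params"
  )
}

#' Langevin integrator parameters
#'
#' Time is in reduced units: with energies in kcal/mol, lengths in A and
#' masses in amu, one reduced time unit is about 48.9 fs. The integrator is
#' the BAOAB splitting of Langevin dynamics; with zero friction it reduces
#' to velocity Verlet.
#'
#' @param dt time step, reduced units.
#' @param friction friction coefficient, 1/time.
#' @param temperature bath temperature, K (300 by default).
#' @param n_steps number of steps; must be a multiple of \code{save_every}.
#' @param save_every frame-saving interval in steps.
#' @param seed integer seed for the counter-based thermostat noise and the
#'   Maxwell-Boltzmann initial velocities.
#' @return list of class \code{integrator_params}.
#' @export
integrator_params <- function(dt = 0.05, friction = 0.01, temperature = 300,
                              n_steps = 20000, save_every = 500, seed = 1) {
  stopifnot(dt > 0, friction >= 0, temperature >= 0,
            n_steps >= 1, save_every >= 1)
  if (n_steps %% save_every != 0) {
    stop("n_steps must be a multiple of save_every", call. = FALSE)
  }
  structure(
    list(dt = dt, friction = friction, temperature = temperature,
         n_steps = as.integer(n_steps), save_every = as.integer(save_every),
         seed = as.integer(seed)),
    class = "integrator_params"
  )
}

# consecutive-bead bonds within each molecule (1-based bead indices)
bonds_from_beads <- function(beads) {
  n <- nrow(beads)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  i <- seq_len(n - 1L)
  keep <- beads$molecule_id[i] == beads$molecule_id[i + 1L]
  cbind(i[keep], i[keep] + 1L)
}

check_ff_state <- function(state, ff) {
  need <- c("charge", "lj_epsilon", "lj_sigma", "mass")
  miss <- need[!need %in% names(state$beads)]
  if (length(miss) > 0L) {
    stop("state beads lack physical parameters: ",
         paste(miss, collapse = ", "),
         " (attach a full bead table, e.g. via read_frames(beads = ...))",
         call. = FALSE)
  }
  if (!is.null(ff$cutoff) && ff$cutoff <= max(state$beads$lj_sigma)) {
    stop("cutoff must exceed the largest lj_sigma", call. = FALSE)
  }
  invisible(TRUE)
}

#' Forces and potential energy of a configuration
#'
#' Exact negative gradient of the model potential (bonds + intermolecular
#' LJ + screened Coulomb). Bonds act on the stored unwrapped coordinates;
#' nonbonded pairs use the minimum-image convention.
#'
#' @param state a \code{system_state} with full bead parameters.
#' @param ff a \code{force_field_params}.
#' @return list: \code{forces} (N x 3, kcal/(mol A)), \code{e_vdw},
#'   \code{e_ele}, \code{e_bond}, \code{e_total} (kcal/mol).
#' @export
compute_forces <- function(state, ff = force_field_params()) {
  check_ff_state(state, ff)
  b <- state$beads
  compute_forces_cpp(
    state$coords, as.integer(b$molecule_id), b$charge, b$lj_epsilon,
    b$lj_sigma, bonds_from_beads(b), state$box_edge,
    ff$coulomb_constant, ff$dielectric, ff$bond_k, ff$bond_r0,
    if (is.null(ff$cutoff)) -1 else ff$cutoff
  )
}

#' Relax a configuration by steepest-descent energy minimization
#'
#' Packed starting configurations can leave bead pairs deep inside the
#' Lennard-Jones repulsive wall; a short minimization removes these
#' contacts before dynamics (mirroring the usual minimize-then-heat
#' protocol). Steepest descent with an adaptive step, displacement-capped
#' per iteration.
#'
#' @param state a \code{system_state} with full bead parameters.
#' @param ff force-field parameters.
#' @param max_iter iteration cap.
#' @param max_disp largest per-iteration bead displacement, A.
#' @param force_tol stop when the largest force component falls below
#'   this, kcal/(mol A).
#' @return the relaxed \code{system_state}.
#' @export
minimize_state <- function(state, ff = force_field_params(),
                           max_iter = 200, max_disp = 0.2,
                           force_tol = 10) {
  res <- compute_forces(state, ff)
  for (iter in seq_len(max_iter)) {
    fmax <- max(abs(res$forces))
    if (fmax < force_tol) break
    step <- max_disp / fmax
    repeat {
      cand <- state
      cand$coords <- state$coords + step * res$forces
      cres <- compute_forces(cand, ff)
      if (cres$e_total <= res$e_total || step < 1e-8) break
      step <- step / 2
    }
    if (cres$e_total > res$e_total) break  # stuck; accept current state
    state <- cand
    res <- cres
  }
  state
}

#' Maxwell-Boltzmann initial velocities
#' @noRd
mb_velocities <- function(masses, temperature, seed) {
  if (temperature <= 0) return(matrix(0, length(masses), 3))
  run_with_seed(seed, {
    matrix(rnorm(3 * length(masses)), ncol = 3) *
      sqrt(KB_KCAL * temperature / masses)
  })
}

#' Run BAOAB Langevin dynamics
#'
#' Evolves a system under the coarse-grained potential with a Langevin
#' thermostat (BAOAB splitting). Thermostat noise comes from a
#' counter-based Gaussian generator keyed by (seed, step, bead, axis), so a
#' fixed seed gives a bit-identical trajectory. Initial velocities are
#' Maxwell-Boltzmann at the bath temperature (zero when \code{velocities}
#' are supplied or the temperature is 0).
#'
#' @param state starting \code{system_state} (full bead parameters).
#' @param ff force-field parameters.
#' @param ip integrator parameters.
#' @param velocities optional N x 3 starting velocities (A per reduced
#'   time).
#' @return object of class \code{cg_trajectory}: list with \code{frames}
#'   (list of \code{system_state}, first entry the initial state),
#'   \code{velocities} (matching list of N x 3 matrices) and \code{energy}
#'   (data.frame: time, potential, kinetic, vdw, ele, bond).
#' @export
run_langevin <- function(state, ff = force_field_params(),
                         ip = integrator_params(), velocities = NULL) {
  check_ff_state(state, ff)
  b <- state$beads
  if (is.null(velocities)) {
    velocities <- mb_velocities(b$mass, ip$temperature, ip$seed)
  }
  stopifnot(nrow(velocities) == nrow(b), ncol(velocities) == 3L)
  res <- run_langevin_cpp(
    state$coords, velocities, b$mass, as.integer(b$molecule_id), b$charge,
    b$lj_epsilon, b$lj_sigma, bonds_from_beads(b), state$box_edge,
    ff$coulomb_constant, ff$dielectric, ff$bond_k, ff$bond_r0,
    if (is.null(ff$cutoff)) -1 else ff$cutoff,
    ip$dt, ip$friction, ip$temperature, ip$n_steps, ip$save_every, ip$seed
  )
  frames <- lapply(seq_along(res$frames_x), function(i) {
    system_state(b, res$frames_x[[i]], state$box_edge,
                 time = state$time + res$times[i])
  })
  structure(
    list(frames = frames, velocities = res$frames_v,
         energy = data.frame(
           time = state$time + res$times, potential = res$potential,
           kinetic = res$kinetic, vdw = res$vdw, ele = res$ele,
           bond = res$bond)),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("<cg_trajectory> %d frames, t = %.2f .. %.2f\n",
              n, x$frames[[1]]$time, x$frames[[n]]$time))
  invisible(x)
}
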