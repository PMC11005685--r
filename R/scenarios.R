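SCENARIO_SEQS <- c(
  aggregator     = "KWFWVAALWVAF",  # aromatic-rich, net charge +1
  transient      = "KRWKAVLAVFAL",  # intermediate: +3, two aromatics
  non_aggregator = "KKRKAKRVKALK"   # highly cationic (+8), no aromatics
)

#' Scenario presets for the synthetic-data generator
#'
#' Returns a parameter preset spanning the observed aggregation
#' phenomenology: a hydrophobically driven aggregator (deep CTD
#' Lennard-Jones well, low net charge), a non-aggregator (shallow CTD well,
#' high cationic charge whose electrostatic repulsion opposes assembly) and
#' an intermediate transient system. The CTD well depth is derived from the
#' preset sequence's aromatic content via [ctd_epsilon_from_sequence()].
#'
#' @param kind \code{"aggregator"}, \code{"transient"} or
#'   \code{"non_aggregator"}.
#' @param seed integer seed stamped into the integrator parameters.
#' @return list with \code{spec} (a \code{molecule_spec}), \code{ff}
#'   (force-field parameters), \code{ip} (integrator parameters) and the
#'   packing defaults \code{n_copies} (16) and \code{box_edge}
#'   (48 A, the reduced-scale screening box).
#' @export
make_scenario <- function(kind = c("aggregator", "transient",
                                   "non_aggregator"), seed = 1) {
  kind <- match.arg(kind)
  seq <- SCENARIO_SEQS[[kind]]
  entry <- peptide_entry(paste0("scenario_", kind), seq, modified = TRUE)
  params <- default_bead_params(ctd_epsilon_from_sequence(seq))
  list(
    kind = kind,
    spec = to_molecule_spec(entry, params),
    ff = force_field_params(),
    ip = integrator_params(seed = seed),
    n_copies = 16L,
    box_edge = 48
  )
}

#' Pack and simulate a scenario preset
#'
#' Convenience wrapper: packs \code{n_copies} molecules of the preset into
#' its box, relaxes close contacts by energy minimization and runs
#' Langevin dynamics. The same seed drives packing and dynamics, so the
#' whole trajectory is reproducible.
#'
#' @param kind scenario tag (see [make_scenario()]).
#' @param seed integer seed.
#' @param n_steps,save_every optional overrides of the preset integrator
#'   schedule.
#' @return a \code{cg_trajectory}.
#' @export
run_scenario <- function(kind, seed = 1, n_steps = NULL, save_every = NULL) {
  sc <- make_scenario(kind, seed)
  ip <- sc$ip
  if (!is.null(n_steps)) ip$n_steps <- as.integer(n_steps)
  if (!is.null(save_every)) ip$save_every <- as.integer(save_every)
  if (ip$n_steps %% ip$save_every != 0) {
    stop("n_steps must be a multiple of save_every", call. = FALSE)
  }
  st <- pack_system(sc$spec, sc$n_copies, sc$box_edge, seed = seed)
  st <- minimize_state(st, sc$ff)
  run_langevin(st, sc$ff, ip)
}
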