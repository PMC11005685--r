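#' @useDynLib pepscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Canonical one-letter amino-acid codes
AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

PEPTIDE_LENGTH <- 12L

#' Validate and construct a peptide library entry
#'
#' Each entry is a 12-mer peptide, optionally carrying an N-terminal
#' cholesterol modification (1:1 molar ratio), which in the coarse-grained
#' model becomes a single hydrophobic terminal-domain (CTD) bead.
#'
#' @param name short unique identifier.
#' @param sequence string of exactly 12 canonical one-letter residue codes.
#' @param modified logical; \code{TRUE} when the N-terminus carries the
#'   cholesterol modification (blocking the N-terminal amine).
#' @return a one-row data.frame with columns \code{name}, \code{sequence},
#'   \code{modified}.
#' @export
peptide_entry <- function(name, sequence, modified = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(trimws(sequence))
  if (nchar(sequence) != PEPTIDE_LENGTH) {
    stop(sprintf(
      "peptide '%s': sequence has %d residues; the library is composed of %d-mers",
      name, nchar(sequence), PEPTIDE_LENGTH
    ), call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_CODES)
  if (length(bad) > 0L) {
    stop(sprintf(
      "peptide '%s': unknown residue code(s): %s",
      name, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  data.frame(
    name = name, sequence = sequence, modified = as.logical(modified),
    stringsAsFactors = FALSE
  )
}

#' Parse a peptide library table
#'
#' Reads a comma- or tab-delimited text file with header
#' \code{name,sequence,modified}, one peptide per row. Every sequence must be
#' a 12-mer over the 20 canonical residue codes; duplicate names are
#' rejected.
#'
#' @param path path to the delimited text file (or a connection).
#' @param sep field separator; autodetected from the header line when
#'   \code{NULL} (comma or tab).
#' @return a data.frame of entries in file order, class
#'   \code{"peptide_library"}.
#' @export
parse_library <- function(path, sep = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("library file is empty", call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  tab <- read.csv(text = lines, sep = sep, strip.white = TRUE,
                  stringsAsFactors = FALSE)
  need <- c("name", "sequence", "modified")
  if (!all(need %in% names(tab))) {
    stop("library header must contain columns: name, sequence, modified",
         call. = FALSE)
  }
  entries <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    entries[[i]] <- tryCatch(
      peptide_entry(tab$name[i], tab$sequence[i],
                    parse_flag(tab$modified[i])),
      error = function(e) {
        stop(sprintf("library row %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  lib <- do.call(rbind, entries)
  dup <- lib$name[duplicated(lib$name)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate peptide name(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  class(lib) <- c("peptide_library", "data.frame")
  lib
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  if (v %in% c("true", "t", "1", "yes")) return(TRUE)
  if (v %in% c("false", "f", "0", "no")) return(FALSE)
  stop(sprintf("cannot interpret modified flag '%s'", x), call. = FALSE)
}

#' Net charge of a peptide entry
#'
#' Counts +1 for each lysine (K) and arginine (R), -1 for each aspartate (D)
#' and glutamate (E). Histidine is neutral in the default (physiological)
#' mode and +1 in \code{"acidic"} mode, reflecting its protonation on
#' endosomal acidification. Free termini contribute +1 (N) and -1 (C); the
#' N-terminal contribution is dropped when the terminus is blocked by the
#' cholesterol modification, and the C-terminus is taken as amidated for
#' these synthetic conjugates, so a modified entry has purely side-chain
#' charge.
#'
#' @param entry a one-row entry from [parse_library()] / [peptide_entry()],
#'   or a bare sequence string (then \code{modified} applies).
#' @param ph_mode \code{"neutral"} (default) or \code{"acidic"}.
#' @param modified used only when \code{entry} is a bare sequence.
#' @return signed integer net charge in elementary charges.
#' @export
net_charge <- function(entry, ph_mode = c("neutral", "acidic"),
                       modified = TRUE) {
  ph_mode <- match.arg(ph_mode)
  if (is.character(entry) && length(entry) == 1L) {
    entry <- peptide_entry("seq", entry, modified)
  }
  chars <- strsplit(entry$sequence, "")[[1]]
  q <- sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
  if (ph_mode == "acidic") q <- q + sum(chars == "H")
  if (!entry$modified) q <- q + 1L - 1L  # free N-terminus +1, C-terminus -1
  as.integer(q)
}

#' Residue-level charge vector (per-bead), matching net_charge semantics
#' @noRd
residue_charges <- function(sequence, ph_mode = "neutral") {
  chars <- strsplit(sequence, "")[[1]]
  q <- numeric(length(chars))
  q[chars %in% c("K", "R")] <- 1
  q[chars %in% c("D", "E")] <- -1
  if (ph_mode == "acidic") q[chars == "H"] <- 1
  q
}

#' Default coarse-grained bead parameter table
#'
#' One row per residue code plus \code{CHOL} for the cholesterol terminal
#' domain (CTD) bead. Charges are formal side-chain charges at neutral pH
#' (+1 K/R, -1 D/E, 0 otherwise). Lennard-Jones parameters use a single
#' generic residue type (sigma 4.5 A, epsilon 0.2 kcal/mol) and a larger,
#' deeper CTD bead (sigma 6.0 A, epsilon tunable 0.5-3.0 kcal/mol) that is
#' the hydrophobic aggregation driver. Radii are sigma/2; masses are reduced
#' coarse-grained masses (10 amu residue, 40 amu CTD) chosen to compress
#' diffusive time scales. These are model defaults of this package, not
#' literature force-field values.
#'
#' @param ctd_epsilon CTD Lennard-Jones well depth, kcal/mol (0.5-3.0
#'   recommended range).
#' @return data.frame with columns
#'   \code{code,charge,lj_epsilon,lj_sigma,radius,mass}.
#' @export
default_bead_params <- function(ctd_epsilon = 1.5) {
  stopifnot(ctd_epsilon > 0)
  res <- data.frame(
    code = AA_CODES,
    charge = residue_charges(paste(AA_CODES, collapse = "")),
    lj_epsilon = 0.2, lj_sigma = 4.5, radius = 2.25, mass = 10,
    stringsAsFactors = FALSE
  )
  chol <- data.frame(
    code = "CHOL", charge = 0, lj_epsilon = ctd_epsilon,
    lj_sigma = 6.0, radius = 3.0, mass = 40,
    stringsAsFactors = FALSE
  )
  rbind(chol, res)
}

#' Read a bead parameter table from delimited text
#'
#' Expects the header \code{code,charge,lj_epsilon,lj_sigma,radius,mass}.
#'
#' @param path file path; comma- or tab-delimited.
#' @return validated parameter data.frame.
#' @export
read_bead_params <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.csv(path, sep = sep, strip.white = TRUE,
                  stringsAsFactors = FALSE)
  need <- c("code", "charge", "lj_epsilon", "lj_sigma", "radius", "mass")
  if (!all(need %in% names(tab))) {
    stop("bead parameter header must contain: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tab$lj_sigma <= 0) || any(tab$radius <= 0) || any(tab$mass <= 0)) {
    stop("lj_sigma, radius and mass must all be positive", call. = FALSE)
  }
  tab[need]
}

#' Map a peptide entry to a coarse-grained molecule specification
#'
#' One bead per residue in chain order; a modified entry gains a single
#' leading CTD bead (the cholesterol hydrophobic domain) carrying zero
#' charge. Bead charges sum to [net_charge()] of the entry under the same
#' pH mode.
#'
#' @param entry a one-row peptide entry.
#' @param params bead parameter table covering \code{CHOL} and all residues
#'   present (see [default_bead_params()]).
#' @param molecule_id integer id stamped on every bead.
#' @param ph_mode charge mode passed to the residue-charge rule.
#' @return a \code{molecule_spec}: list with \code{molecule_id},
#'   \code{beads} (data.frame, one row per bead), \code{source} (the entry).
#' @export
to_molecule_spec <- function(entry, params = default_bead_params(),
                             molecule_id = 1L,
                             ph_mode = c("neutral", "acidic")) {
  ph_mode <- match.arg(ph_mode)
  chars <- strsplit(entry$sequence, "")[[1]]
  codes <- if (entry$modified) c("CHOL", chars) else chars
  idx <- match(codes, params$code)
  if (anyNA(idx)) {
    stop(sprintf("bead parameter table is missing entries for: %s",
                 paste(unique(codes[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  p <- params[idx, , drop = FALSE]
  charges <- residue_charges(entry$sequence, ph_mode)
  if (entry$modified) charges <- c(0, charges)
  if (!entry$modified) {
    charges[1] <- charges[1] + 1          # free N-terminus
    charges[length(charges)] <- charges[length(charges)] - 1
  }
  beads <- data.frame(
    bead_id = seq_along(codes),
    molecule_id = as.integer(molecule_id),
    group = ifelse(codes == "CHOL", "CTD", "RESIDUE"),
    residue_code = codes,
    charge = charges,
    lj_epsilon = p$lj_epsilon,
    lj_sigma = p$lj_sigma,
    radius = p$radius,
    mass = p$mass,
    stringsAsFactors = FALSE
  )
  rownames(beads) <- NULL
  structure(
    list(molecule_id = as.integer(molecule_id), beads = beads,
         source = entry),
    class = "molecule_spec"
  )
}

#' Sequence-derived CTD hydrophobicity
#'
#' The screen's hydrophobic driver: aromatic residues (W, F, Y) pack against
#' the cholesterol domain, so the CTD Lennard-Jones well depth is scaled
#' with aromatic content, from 0.5 kcal/mol (no aromatics) in steps of
#' 0.5 kcal/mol per aromatic residue, capped at 3.0 kcal/mol.
#'
#' @param sequence 12-mer sequence string.
#' @return CTD epsilon in kcal/mol.
#' @export
ctd_epsilon_from_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n_arom <- sum(chars %in% c("W", "F", "Y"))
  min(3.0, 0.5 + 0.5 * n_arom)
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf(
    "<molecule_spec> id=%d  %d beads (%d CTD)  net charge %+d e  [%s]\n",
    x$molecule_id, nrow(x$beads), sum(x$beads$group == "CTD"),
    as.integer(round(sum(x$beads$charge))), x$source$sequence
  ))
  invisible(x)
}
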