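AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
  Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", CHOL = "CHL"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

#' Write a trajectory of system states
#'
#' Primary format is multi-model PDB: one \code{MODEL}/\code{ENDMDL} block
#' per frame, a \code{CRYST1} record carrying the cubic box edge and a
#' \code{REMARK} line carrying the reduced time stamp. CTD beads are written
#' with atom name \code{CTD} and residue name \code{CHL}; residue beads with
#' atom name \code{CA} and the standard three-letter code. The molecule id
#' goes in the residue-sequence column. The secondary format is an extended
#' XYZ with \code{box=}/\code{time=} comment fields and explicit
#' molecule-id/group columns. Coordinates are written as stored, to the
#' format's printed precision (PDB and XYZ: 3 decimals).
#'
#' @param traj a single \code{system_state} or a list of them.
#' @param path output file path.
#' @param format \code{"pdb"} (default) or \code{"xyz"}; guessed from the
#'   file extension when \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
write_frames <- function(traj, path, format = NULL) {
  if (inherits(traj, "system_state")) traj <- list(traj)
  stopifnot(length(traj) >= 1L)
  if (is.null(format)) {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  format <- match.arg(format, c("pdb", "xyz"))
  out <- if (format == "pdb") {
    unlist(lapply(seq_along(traj), function(i) pdb_block(traj[[i]], i)))
  } else {
    unlist(lapply(traj, xyz_block))
  }
  if (format == "pdb") out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

pdb_block <- function(state, model_no) {
  b <- state$beads
  name <- ifelse(b$group == "CTD", "CTD", "CA")
  res3 <- AA_THREE[b$residue_code]
  res3[is.na(res3)] <- "UNK"
  atom <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(b)) %% 100000L, name, res3,
    substr(LETTERS[((b$molecule_id - 1L) %% 26L) + 1L], 1, 1),
    b$molecule_id %% 10000L,
    state$coords[, 1], state$coords[, 2], state$coords[, 3], 1, 0
  )
  c(sprintf("MODEL     %4d", model_no),
    sprintf("REMARK 250 TIME=%.6f", state$time),
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            state$box_edge, state$box_edge, state$box_edge, 90, 90, 90),
    atom, "ENDMDL")
}

xyz_block <- function(state) {
  b <- state$beads
  c(sprintf("%d", nrow(b)),
    sprintf("box=%.6f time=%.6f", state$box_edge, state$time),
    sprintf("%-4s %5d %-7s %12.3f %12.3f %12.3f",
            b$residue_code, b$molecule_id, b$group,
            state$coords[, 1], state$coords[, 2], state$coords[, 3]))
}

#' Read a trajectory written by [write_frames()]
#'
#' @param path input file; format guessed from extension unless given.
#' @param format \code{"pdb"}, \code{"xyz"} or \code{NULL} (guess).
#' @param beads optional full bead table (e.g. from [replicate_beads()] or a
#'   previous state) to attach physical parameters to each frame; must match
#'   the stored bead count. Without it, frames carry the identity columns
#'   recoverable from the file (bead_id, molecule_id, group, residue_code).
#' @return list of \code{system_state} frames in file order (possibly
#'   empty).
#' @export
read_frames <- function(path, format = NULL, beads = NULL) {
  lines <- readLines(path)
  if (is.null(format)) {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  format <- match.arg(format, c("pdb", "xyz"))
  frames <- if (format == "pdb") read_pdb_frames(lines) else
    read_xyz_frames(lines)
  if (length(frames) == 0L) return(frames)
  n0 <- nrow(frames[[1]]$beads)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$beads) != n0) {
      stop(sprintf("frame %d has %d atoms; frame 1 has %d",
                   i, nrow(frames[[i]]$beads), n0), call. = FALSE)
    }
    if (!is.null(beads)) {
      if (nrow(beads) != n0) {
        stop(sprintf("supplied bead table has %d rows; frames have %d",
                     nrow(beads), n0), call. = FALSE)
      }
      frames[[i]]$beads <- beads
    }
  }
  frames
}

read_pdb_frames <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    if (!any(grepl("^ATOM", lines))) return(list())
    model_starts <- 1L
    model_ends <- length(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
    }
    model_ends <- ends
  }
  lapply(seq_along(model_starts), function(f) {
    block <- lines[model_starts[f]:model_ends[f]]
    parse_pdb_model(block, f)
  })
}

parse_pdb_model <- function(block, frame_idx) {
  cry <- grep("^CRYST1", block, value = TRUE)
  box <- if (length(cry) > 0) as.numeric(substr(cry[1], 7, 15)) else NA_real_
  tm <- grep("TIME=", block, value = TRUE)
  time <- if (length(tm) > 0) {
    as.numeric(sub(".*TIME=\\s*", "", tm[1]))
  } else 0
  at <- grep("^ATOM|^HETATM", block, value = TRUE)
  if (length(at) == 0L) {
    stop(sprintf("frame %d contains no atom records", frame_idx),
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(substr(at, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(at, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(at, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop(sprintf("frame %d: malformed coordinate field (atom line %d)",
                 frame_idx, which(is.na(x) | is.na(y) | is.na(z))[1]),
         call. = FALSE)
  }
  name <- trimws(substr(at, 13, 16))
  res3 <- trimws(substr(at, 18, 20))
  mol <- suppressWarnings(as.integer(substr(at, 23, 26)))
  if (anyNA(mol)) {
    stop(sprintf("frame %d: malformed residue-sequence (molecule id) field",
                 frame_idx), call. = FALSE)
  }
  code <- unname(AA_ONE[res3])
  code[is.na(code)] <- res3[is.na(code)]
  beads <- data.frame(
    bead_id = seq_along(at),
    molecule_id = mol,
    group = ifelse(name == "CTD", "CTD", "RESIDUE"),
    residue_code = code,
    stringsAsFactors = FALSE
  )
  if (is.na(box)) stop(sprintf("frame %d: missing CRYST1 box record",
                               frame_idx), call. = FALSE)
  system_state(beads, cbind(x, y, z), box, time)
}

read_xyz_frames <- function(lines) {
  frames <- list()
  i <- 1L
  f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- f + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("frame %d: bad atom-count line", f), call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("frame %d: truncated (expected %d atom lines)", f, n),
           call. = FALSE)
    }
    comment <- lines[i + 1L]
    box <- as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", comment))
    time <- if (grepl("time=", comment)) {
      as.numeric(sub(".*time=([0-9.eE+-]+).*", "\\1", comment))
    } else 0
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(vapply(rows, length, 0L) < 6L)
    if (length(bad) > 0L) {
      stop(sprintf("frame %d: malformed atom line %d", f, bad[1]),
           call. = FALSE)
    }
    m <- do.call(rbind, rows)
    beads <- data.frame(
      bead_id = seq_len(n),
      molecule_id = as.integer(m[, 2]),
      group = m[, 3],
      residue_code = m[, 1],
      stringsAsFactors = FALSE
    )
    xyz <- matrix(as.numeric(m[, 4:6]), ncol = 3)
    frames[[f]] <- system_state(beads, xyz, box, time)
    i <- i + 2L + n
  }
  frames
}
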