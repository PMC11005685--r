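RANK_METRICS <- c("mean_sasa", "mean_rg", "mean_vdw", "mean_ele",
                  "mean_sat_max")

#' Composite rank-sum screening of candidate systems
#'
#' Converts each screening metric into a within-library rank -- ascending
#' for mean SASA, Rg, VDW and ELE (smaller area / more negative binding
#' energy indicates stronger aggregation), descending for the mean maximum
#' saturation number -- and scores each system by the weighted sum of its
#' ranks (lower is better). Systems whose sequence net charge exceeds
#' \code{charge_cap} are flagged with the exclusion reason
#' \code{"excess cationic charge"} but remain ranked, so reports stay
#' complete. The top \code{k} non-excluded systems are marked selected.
#'
#' @param reports data.frame, one row per system, with columns \code{name},
#'   \code{mean_sasa}, \code{mean_rg}, \code{mean_vdw}, \code{mean_ele},
#'   \code{mean_sat_max}, \code{net_charge}; any further columns (SDs,
#'   kinetic class) are carried through.
#' @param weights named weights for the five metrics (default equal).
#' @param charge_cap net-charge cap in elementary charges (default +6 for
#'   a 12-mer).
#' @param k number of candidates to select (default 5).
#' @return data.frame of class \code{screening_report}, ordered by rank,
#'   with added columns \code{composite_score}, \code{rank},
#'   \code{excluded}, \code{exclusion_reason}, \code{selected}.
#' @export
rank_candidates <- function(reports,
                            weights = c(mean_sasa = 1, mean_rg = 1,
                                        mean_vdw = 1, mean_ele = 1,
                                        mean_sat_max = 1),
                            charge_cap = 6, k = 5) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  need <- c("name", "net_charge", RANK_METRICS)
  miss <- setdiff(need, names(reports))
  if (length(miss) > 0L) {
    stop("reports lack required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(reports[RANK_METRICS])) {
    stop("inconsistent metric sets: NA metric values across systems",
         call. = FALSE)
  }
  if (anyDuplicated(reports$name)) {
    stop("system names must be unique", call. = FALSE)
  }
  w <- weights[RANK_METRICS]
  if (anyNA(w)) {
    stop("weights must name all of: ", paste(RANK_METRICS, collapse = ", "),
         call. = FALSE)
  }
  ranks <- sapply(RANK_METRICS, function(m) {
    v <- reports[[m]]
    if (m == "mean_sat_max") v <- -v  # larger saturation number is better
    rank(v, ties.method = "average")
  })
  composite <- as.numeric(ranks %*% w)
  out <- reports
  out$composite_score <- composite
  ord <- order(composite, out$name)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$excluded <- out$net_charge > charge_cap
  out$exclusion_reason <- ifelse(out$excluded, "excess cationic charge", "")
  out$selected <- FALSE
  eligible <- which(!out$excluded)
  out$selected[head(eligible, k)] <- TRUE
  rownames(out) <- NULL
  class(out) <- c("screening_report", "data.frame")
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Candidate screening report (rank-sum composite; lower is better)\n")
  cols <- intersect(
    c("rank", "name", "mean_sasa", "mean_vdw", "mean_ele", "mean_sat_max",
      "kinetic_class", "net_charge", "composite_score", "selected",
      "exclusion_reason"),
    names(x))
  print.data.frame(x[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}
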