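#' Synthetic 10-peptide screening library
#'
#' The sequences of the original screening library are not machine-readable
#' from the source figures, so the package ships a synthetic stand-in with
#' the same design logic: ten 12-mer cationic peptides, cholesterol-modified
#' at the N-terminus, spanning planted aggregation propensities. Three
#' low-charge entries are planted aggregators -- one dominant aromatic-rich
#' design (SP01, five aromatics, net charge +1) and two weaker ones
#' (two aromatics, +2) --
#' four intermediate entries are planted transients, and three
#' lysine/arginine heavy entries (net charge +7 to +8) are planted
#' non-aggregators that additionally trip the cationic-charge exclusion
#' rule.
#'
#' @return a \code{peptide_library} data.frame with columns \code{name},
#'   \code{sequence}, \code{modified} and the extra column
#'   \code{planted_kind}.
#' @export
synthetic_library <- function() {
  tab <- data.frame(
    name = sprintf("SP%02d", 1:10),
    sequence = c(
      "KWFWVAALWVAF",  # dominant aggregator: 5 aromatics, +1
      "RWAFLAVALAKL",  # weaker aggregator: 2 aromatics, +2
      "KWYALAAVLKAA",  # weaker aggregator: 2 aromatics, +2
      "KRWKAVLAVFAL",  # transient: 2 aromatics, +3
      "KKWHARVFAVLA",  # transient: 2 aromatics, +3
      "RKAWVALKVAFL",  # transient: 2 aromatics, +3
      "KHRWAVALVKFA",  # transient: 2 aromatics, +3
      "KKRKAKRVKALK",  # non-aggregator: no aromatics, +8
      "RKKRAKVKLKAK",  # non-aggregator: no aromatics, +8
      "KRKKHAKVKKAL"   # non-aggregator: no aromatics, +7
    ),
    modified = TRUE,
    planted_kind = rep(c("aggregator", "transient", "non_aggregator"),
                       c(3, 4, 3)),
    stringsAsFactors = FALSE
  )
  # validate every entry through the standard constructor
  for (i in seq_len(nrow(tab))) {
    peptide_entry(tab$name[i], tab$sequence[i], tab$modified[i])
  }
  class(tab) <- c("peptide_library", "data.frame")
  tab
}
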