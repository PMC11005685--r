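#!/usr/bin/env Rscript
# Step 1: assemble the screening library and its sequence-level features.
#
# The library is the package's synthetic 10-peptide panel of 12-mer
# cholesterol conjugates with planted aggregation propensities. For each
# entry we record the features the screen's rationale rests on: net charge
# (cationic binding / electrostatic repulsion), aromatic content and the
# derived CTD Lennard-Jones well depth (hydrophobic aggregation driver).

library(pepscreen)
dir.create("results", showWarnings = FALSE)

lib <- synthetic_library()
features <- data.frame(
  name = lib$name,
  sequence = lib$sequence,
  planted_kind = lib$planted_kind,
  net_charge = vapply(seq_len(nrow(lib)), function(i)
    net_charge(lib[i, , drop = FALSE]), integer(1)),
  n_aromatic = vapply(lib$sequence, function(s)
    sum(strsplit(s, "")[[1]] %in% c("W", "F", "Y")), integer(1),
    USE.NAMES = FALSE),
  ctd_epsilon = vapply(lib$sequence, ctd_epsilon_from_sequence, numeric(1),
                       USE.NAMES = FALSE)
)
write.csv(features, "results/library_features.csv", row.names = FALSE)

cat("Library of", nrow(features), "peptide-cholesterol conjugates:\n")
print(features, row.names = FALSE)
cat("\nCharge spans", min(features$net_charge), "to", max(features$net_charge),
    "e; CTD well depth spans", min(features$ctd_epsilon), "to",
    max(features$ctd_epsilon), "kcal/mol.\n")
cat("Wrote results/library_features.csv\n")
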