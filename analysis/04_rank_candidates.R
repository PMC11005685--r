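#!/usr/bin/env Rscript
# Step 4: aggregate the replicate summaries, apply the composite rank-sum
# scoring with the cationic-charge exclusion rule, and write the final
# screening report plus a plain-text ranking table.

library(pepscreen)

summaries <- read.csv("results/screen_summaries.csv")
lib <- synthetic_library()

avg <- aggregate(
  summaries[, c("mean_sasa", "mean_rg", "mean_vdw", "mean_ele",
                "mean_sat_max")],
  by = list(name = summaries$name), FUN = mean)
avg$net_charge <- summaries$net_charge[match(avg$name, summaries$name)]
report <- rank_candidates(avg)
report$planted_kind <- lib$planted_kind[match(report$name, lib$name)]
# majority kinetic class across replicates
report$kinetic_class <- vapply(report$name, function(nm) {
  cls <- summaries$kinetic_class[summaries$name == nm]
  names(sort(table(cls), decreasing = TRUE))[1]
}, character(1))

write.csv(as.data.frame(report), "results/screening_report.csv",
          row.names = FALSE)

lines <- c(
  "Candidate ranking (seed-averaged metrics; rank-sum composite)",
  "",
  sprintf("%-4s %-6s %9s %9s %9s %8s %-15s %s",
          "rank", "name", "SASA", "VDW", "ELE", "sat_max", "class",
          "flags"),
  sprintf("%-4d %-6s %9.1f %9.1f %9.1f %8.2f %-15s %s",
          report$rank, report$name, report$mean_sasa, report$mean_vdw,
          report$mean_ele, report$mean_sat_max, report$kinetic_class,
          ifelse(report$selected, "selected",
                 ifelse(report$excluded, report$exclusion_reason, "")))
)
writeLines(lines, "results/ranking.txt")
cat(lines, sep = "\n")
cat("\nWrote results/screening_report.csv and results/ranking.txt\n")
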