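# 05 — Craniodental ratio profile of the holotype against published ranges.
#
# This driver runs on real printed data: the holotype's caption measurements
# and the comparative ratio ranges for extant and fossil Panthera. It
# reproduces the reported percentages (canine height 23.7% of CBL, nasals
# 34.5%, P4 13.4%, M1 14.7% of mandible length) and classifies each against
# the comparative ranges.

source("analysis/00_common.R")

h <- read_measurements(system.file("extdata", "holotype_measurements.csv",
                                   package = "pantherin"))
ranges <- range_table(read.csv(system.file(
  "extdata", "panthera_ratio_ranges.csv", package = "pantherin")))

ratios <- list(canine_height_cbl = c("c1_height", "CBL"),
               nasal_length_cbl = c("nasal_length", "CBL"),
               p4_length_cbl = c("p4_length", "CBL"),
               m1_length_mandible = c("m1_length", "mandible_length"))

pct <- ratio_profile(h, ratios, percent = TRUE, decimals = 1)
cat("holotype ratio profile (% of denominator):\n")
for (nm in names(ratios))
  cat(sprintf("  %-20s %5.1f%%\n", nm, pct[[nm]]))
write.csv(pct, file.path(RESULTS, "holotype_ratios.csv"), row.names = FALSE)

full <- ratio_profile(h, ratios, percent = FALSE)
verdicts <- do.call(rbind, lapply(
  intersect(names(ratios), unique(ranges$ratio)), function(nm)
    cbind(ratio = nm, value = full[[nm]][1],
          range_compare(full[[nm]][1], ranges, nm))))
write.csv(verdicts, file.path(RESULTS, "range_verdicts.csv"),
          row.names = FALSE)

cat("\nverdicts against comparative ranges:\n")
for (nm in unique(verdicts$ratio)) {
  sub <- verdicts[verdicts$ratio == nm, ]
  cat("  ", nm, ": ",
      paste0(sub$group, "=", sub$verdict,
             ifelse(nzchar(sub$qualifier), paste0(" (", sub$qualifier, ")"),
                    ""), collapse = ", "), "\n", sep = "")
}
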