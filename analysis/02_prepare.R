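#!/usr/bin/env Rscript

# Stage 2: screen and species-resolve the survey table.
#
# Re-reads the stage-1 CSV as a cold start, assigns circles to regions
# by the coast-distance/latitude rule table, drops circles below the
# 10-bird lifetime total or surveyed in fewer than half the years, and
# apportions genus-level counts to species by the identified ratio on
# the same count.

suppressPackageStartupMessages(library(grebetrends))
out <- "results/analysis"

d <- read_count_table(file.path(out, "dataset.csv"))
d <- assign_region(d, overwrite = TRUE)
d <- filter_circles(d, min_total = 10, min_coverage = 0.5)
excl <- attr(d, "exclusions")
writeLines(
  if (nrow(excl) == 0) "no circles excluded" else
    sprintf("%s: total=%g, years_surveyed=%d (%s)", excl$circle_id,
            excl$total, excl$years_surveyed, excl$reason),
  file.path(out, "exclusions.txt"))

n_unid <- sum(d$records$count[d$records$species == "UNID"])
d <- allocate_unidentified(d)
write_count_table(d, file.path(out, "dataset_analysis.csv"))

cat("Retained", nrow(d$circles), "circles;", nrow(excl), "excluded",
    "(see exclusions.txt)\n")
cat("Apportioned", n_unid, "genus-level birds to species;",
    "remaining unidentified:",
    sum(d$records$count[d$records$species == "UNID"]), "\n")
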