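#!/usr/bin/env Rscript
# Step 2: compute every system-level succession index per phase.
#
# Reads the per-phase flow networks and the biomass series written by
# 01_simulate.R back from disk (exercising the CSV interface), computes
# the full index family -- functional diversity, succession rate,
# specific eco-exergy, diet C:P, residence times, trophic position,
# metabolic activity, PPMR, transfer efficiency, weighted connectance,
# flow diversity, relative ascendency, small-world indices on the
# disaggregated 24-guild web, and the size-spectrum slope -- and writes
# the long index table to results/index_series.csv.

suppressPackageStartupMessages(library(planksucc))

seed <- 1L
src <- "results/synthetic"
cfg <- scenario_config(seed = seed)   # same configuration as step 1

nets <- function(el) {
  out <- lapply(seq_along(cfg$phases), function(p)
    read_flow_network(file.path(src, sprintf("phase%d_%s_edges.csv", p, el)),
                      file.path(src, sprintf("phase%d_%s_nodes.csv", p, el))))
  stats::setNames(out, cfg$phases)
}
scen <- list(C = nets("C"), P = nets("P"), cfg = cfg)

bio_df <- utils::read.csv(file.path(src, "biomass_series.csv"),
                          check.names = FALSE)
bio <- list(times = bio_df$day, phase = bio_df$phase,
            B = as.matrix(bio_df[, -(1:2)]))

series <- compute_index_series(scen, bio)
dir.create("results", showWarnings = FALSE)
utils::write.csv(series, "results/index_series.csv", row.names = FALSE)
cat("wrote results/index_series.csv:", nrow(series), "rows,",
    length(unique(series$index)), "indices x 7 phases\n\n")

wide <- reshape(series[c("phase", "index", "value")], direction = "wide",
                idvar = "phase", timevar = "index")
names(wide) <- sub("^value\\.", "", names(wide))
print(wide[, c("phase", "H_bio", "TE", "PB", "C_w", "Asc_rel")],
      digits = 3, row.names = FALSE)
cat("\nFunctional diversity dips at the clear-water phase while",
    "connectance and transfer efficiency climb towards autumn.\n")
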