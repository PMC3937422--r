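#!/usr/bin/env Rscript
# Step 1: generate the synthetic seasonal study system.
#
# Emulates one averaged seasonal cycle of a temperate-lake plankton food
# web on the standardized 7-phase axis: per phase, a mass-balanced
# carbon and phosphorus flow network on the 8-group + detritus topology,
# plus weekly 24-guild biomass snapshots.  Everything is written as
# plain CSV under results/synthetic/ so the downstream steps (and any
# external tool) can work from files alone.

suppressPackageStartupMessages(library(planksucc))

seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- scenario_config(seed = seed)
scen <- generate_seasonal_scenario(cfg)

for (p in seq_along(cfg$phases)) {
  slug <- sprintf("phase%d", p)
  for (el in c("C", "P")) {
    net <- scen[[el]][[p]]
    write_flow_network(net,
                       file.path(out, sprintf("%s_%s_edges.csv", slug, el)),
                       file.path(out, sprintf("%s_%s_nodes.csv", slug, el)))
    bal <- validate_mass_balance(net, rtol = 1e-9)
    stopifnot(attr(bal, "pass"))
  }
}
cat("wrote", 7 * 4, "network CSV files; all balanced at rtol 1e-9\n")

bio <- generate_biomass_series(lc_guilds(), cfg)
bio_df <- data.frame(day = bio$times, phase = bio$phase, bio$B,
                     check.names = FALSE)
utils::write.csv(bio_df, file.path(out, "biomass_series.csv"),
                 row.names = FALSE)
cat("wrote biomass series:", nrow(bio_df), "weekly snapshots x",
    ncol(bio$B), "guilds\n")

tst <- sapply(scen$C, total_system_throughput, selection = "full_throughput")
cat("\nTotal system throughput per phase (ugC m-2 d-1):\n")
print(round(tst))
cat("\nThroughput peaks in spring and collapses in winter, as configured.\n")
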