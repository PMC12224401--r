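#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study area.
#
# Three cities tiled into 2,442 census-tract-like neighbourhoods with
# lognormal population density and four correlated census dimension
# scores; a registry of named food establishments whose counts rise
# with population and social environment; and 1,275 survey respondents
# nested in a subset of neighbourhoods. Everything downstream reads the
# files written here.

suppressPackageStartupMessages(library(foodenv))

seed <- as.integer(Sys.getenv("FOODENV_SEED", "1"))
out <- "results/run"

cfg <- city_config(seed = seed)
sim <- simulate_city(cfg)
paths <- write_city(sim, out)

cat(sprintf("neighbourhoods : %d across %s\n", nrow(sim$neighbourhoods),
            paste(cfg$city_labels, collapse = ", ")))
cat(sprintf("establishments : %d (%.1f%% deliberately ambiguous)\n",
            nrow(sim$establishments), 100 * mean(sim$establishments$ambiguous)))
cat(sprintf("participants   : %d in %d neighbourhoods\n",
            nrow(sim$participants), length(unique(sim$participants$neighbourhood_id))))
cat("written:", paste(basename(paths), collapse = ", "), "->", out, "\n")
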