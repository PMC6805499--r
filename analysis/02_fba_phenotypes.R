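#!/usr/bin/env Rscript
# Confirm the strict-aerobe phenotype of the model: growth under the oxic
# minimal medium, zero growth under anoxia in both minimal and rich media.

suppressPackageStartupMessages(library(anaerodesign))

model <- load_model("results/data/toy_model.json")
toy <- make_toy_model()   # media presets matching the generated model

rich <- medium_preset("rich", model)
sweep <- rbind(
  cbind(base = "minimal",
        growth_predicts(model, medium = toy$media$minimal,
                        overlays = list(toy$media$oxic,
                                        toy$media$anoxic))),
  cbind(base = "rich",
        growth_predicts(model, medium = rich,
                        overlays = list(toy$media$oxic,
                                        toy$media$anoxic)))
)
utils::write.table(sweep, "results/media_sweep.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(sweep, row.names = FALSE)
stopifnot(sweep$mu[sweep$condition == "anoxic"] < GROWTH_EPSILON)
cat("anoxic growth is zero in minimal and rich medium;",
    "oxic growth rate:", max(sweep$mu), "h^-1\n")
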