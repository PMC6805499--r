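#!/usr/bin/env Rscript
# Scan every O2-involving enzymatic reaction by single deletion under the
# oxic minimal medium and report which are essential for growth.

suppressPackageStartupMessages(library(anaerodesign))

model <- load_model("results/data/toy_model.json")
toy <- make_toy_model()

scan <- o2_essentiality_scan(apply_medium(model, toy$media$minimal),
                             medium = toy$media$oxic)
write_scan_report(scan, "results/scan.tsv")
print(scan, row.names = FALSE)
cat("baseline mu:", attr(scan, "baseline_mu"), "h^-1;",
    sum(scan$essential), "of", nrow(scan),
    "O2 reactions are essential\n")
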