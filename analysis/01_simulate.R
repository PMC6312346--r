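#!/usr/bin/env Rscript
# Generate the reference synthetic dataset for the analysis workflow.
#
# The study conditions: 14 species on the bundled phylogeny plus a distant
# outgroup, 2,000 ortholog groups, two stages (pre- and post zygotic
# genome activation), 3 replicates per condition, replicate CV 0.2,
# 6.56% missing orthologs, 10% ALT genes. Everything downstream reads
# the fixture written here.

suppressPackageStartupMessages(library(mztevol))

out <- "results/fixture"
cfg <- simulation_config(seed = 20260925 %% 2147483647L)
write_fixture(out, cfg)

sim <- simulate_dataset(cfg)
message("Wrote fixture to ", out)
message("  genes: ", cfg$n_genes, "; species: ",
        length(sim$tree$tip.label), " + outgroup")
message("  true ALT genes: ", sum(sim$truth$alt_gene))
message("  gene-category composition (all species pooled):")
print(round(prop.table(table(sim$truth$gene_category)), 3))
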