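#!/usr/bin/env Rscript
# Conserved zygotic-only gene sets against the distant outgroup: the
# loose set (outgroup + any ingroup species), the core set (outgroup +
# basal species + a subgenus species), breadth-of-conservation summaries
# and ALT-state conservation across the phylogeny.

suppressPackageStartupMessages(library(mztevol))

data <- read_fixture("results/fixture")
species <- data$tree$tip.label
roles <- species_roles(outgroup = "outg", basal = "dwil",
                       subgenus = c("dmoj", "dvir"), ingroup = species)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

orth_in <- filter_ortholog_groups(
  ortholog_table(data$orthologs$groups[, c("ref_gene", species)]), 12)
gene_calls <- lapply(data$expression, function(t) {
  classify_expression(aggregate_isoforms_to_genes(t, data$isoform_map),
                      level = "gene")
})
og_ids <- data$orthologs$groups[["outg"]][
  match(orth_in$groups$ref_gene, data$orthologs$groups$ref_gene)]
all_sp <- c(species, "outg")
calls <- do.call(cbind, lapply(all_sp, function(sp) {
  ids <- if (sp == "outg") og_ids else orth_in$groups[[sp]]
  cc <- gene_calls[[sp]]$category[match(ids, gene_calls[[sp]]$feature_id)]
  cc[ids == ""] <- NA
  cc
}))
dimnames(calls) <- list(orth_in$groups$ref_gene, all_sp)

rec <- conservation_records(calls, roles, "zygotic_only")
utils::write.table(rec, "results/tables/conservation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
loose <- rec$gene[rec$loose_flag]; core <- rec$gene[rec$core_flag]
message(sprintf(
  "Zygotic-only conservation: %d loose (outgroup + >=1 species), %d core",
  length(loose), length(core)))
message(sprintf(
  "  core genes are zygotic-only in %.1f additional species on average; loose-only in %.1f",
  mean_additional_species(core, calls, roles, set_type = "core"),
  mean_additional_species(setdiff(loose, core), calls, roles,
                          set_type = "loose")))
m_loose <- loose_conserved_set(calls, roles, "maternal_only")
message("Maternal-only genes conserved with the outgroup: ", length(m_loose))

# is the core set enriched for broadly conserved zygotic-only status?
broad <- rowSums(calls[, species] == "Z", na.rm = TRUE) >= 10
fe <- category_enrichment(rownames(calls) %in% core, broad)
message(sprintf(
  "Core-set enrichment for broad (>=10 species) zygotic-only status: OR = %.1f, Fisher p = %.3g",
  fe$odds_ratio, fe$p_value))

alt_calls <- lapply(data$expression[species], function(t) {
  detect_alt_genes(classify_expression(t, level = "isoform"),
                   data$isoform_map)
})
alt_mat <- do.call(cbind, lapply(species, function(sp) {
  ids <- orth_in$groups[[sp]]
  f <- alt_calls[[sp]]$alt_flag[match(ids, alt_calls[[sp]]$gene_id)]
  f[ids == ""] <- NA
  f
}))
dimnames(alt_mat) <- list(orth_in$groups$ref_gene, species)
ac <- alt_conservation_count(alt_mat)
utils::write.table(ac, "results/tables/alt_conservation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "ALT state present in >= 2/3 of species for %d ortholog groups (max %d species)",
  sum(ac$conserved), max(ac$n_alt)))
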