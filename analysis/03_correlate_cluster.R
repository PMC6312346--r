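#!/usr/bin/env Rscript
# Cross-species Spearman correlations of stage-restricted transcript
# levels on one-to-one orthologs, decay of correlation with patristic
# distance, and average-linkage clustering of all condition
# transcriptomes.

suppressPackageStartupMessages(library(mztevol))

data <- read_fixture("results/fixture")
species <- data$tree$tip.label
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

orth_in <- filter_ortholog_groups(
  ortholog_table(data$orthologs$groups[, c("ref_gene", species)]), 12)
gene_calls <- lapply(data$expression[species], function(t) {
  classify_expression(aggregate_isoforms_to_genes(t, data$isoform_map),
                      level = "gene")
})
aligned <- lapply(stats::setNames(species, species), function(sp) {
  idx <- match(orth_in$groups[[sp]], gene_calls[[sp]]$feature_id)
  idx[orth_in$groups[[sp]] == ""] <- NA
  data.frame(ref_gene = orth_in$groups$ref_gene,
             category = gene_calls[[sp]]$category[idx],
             s2_mean = gene_calls[[sp]]$s2_mean[idx],
             s5_mean = gene_calls[[sp]]$s5_mean[idx])
})

pairs <- utils::combn(species, 2)
res <- list()
for (k in seq_len(ncol(pairs))) {
  a <- pairs[1, k]; b <- pairs[2, k]
  for (cat in c("stage2", "stage5", "maternal_only", "zygotic_only")) {
    for (mode in c("shared_in_both", "in_either")) {
      res[[length(res) + 1]] <- pairwise_category_correlation(
        aligned[[a]], aligned[[b]], cat, mode,
        species_a = a, species_b = b)
    }
  }
}
correlations <- do.call(rbind, res)
utils::write.table(correlations, "results/tables/correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

pd <- ape::cophenetic.phylo(data$tree)
s2 <- correlations[correlations$category == "stage2" &
                     correlations$mode == "shared_in_both", ]
decay <- stats::cor(s2$rho, pd[cbind(s2$species_a, s2$species_b)],
                    method = "spearman")
message("Stage-2 correlation vs patristic distance (Spearman): ",
        round(decay, 3), "  (negative = divergence grows with distance)")

zb <- correlations[correlations$category == "zygotic_only", ]
message("Zygotic-only rho, shared-in-both vs in-either (means): ",
        round(mean(zb$rho[zb$mode == "shared_in_both"], na.rm = TRUE), 3),
        " vs ",
        round(mean(zb$rho[zb$mode == "in_either"], na.rm = TRUE), 3))

shared <- Reduce(`&`, lapply(aligned, function(a) !is.na(a$category)))
condmat <- do.call(cbind, lapply(species, function(sp) {
  m <- cbind(aligned[[sp]]$s2_mean, aligned[[sp]]$s5_mean)
  colnames(m) <- paste(sp, c("stage2", "stage5"), sep = ".")
  m
}))[shared, , drop = FALSE]
h <- hierarchical_cluster(correlation_matrix(condmat))
utils::write.table(data.frame(merge1 = h$merge[, 1], merge2 = h$merge[, 2],
                              height = h$height),
                   "results/tables/linkage.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
split <- top_split(h)
stage <- sub(".*\\.", "", names(split))
message("Top dendrogram split separates the stages: ",
        length(unique(split[stage == "stage2"])) == 1 &&
          length(unique(split[stage == "stage5"])) == 1 &&
          split[stage == "stage2"][1] != split[stage == "stage5"][1],
        "  (", nrow(condmat), " shared ortholog groups, ",
        length(split), " conditions)")
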