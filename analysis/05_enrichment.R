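#!/usr/bin/env Rscript
# Step 5: functional profiles and enrichment by origin class.
#
# For each origin class, a functional profile of fold enrichments over the
# large biological-process GO terms (class fraction over pooled-duplicate
# fraction), clustered by average linkage on 1 - Pearson r. Essentiality
# (knockout phenotype on the screened subset) and PPI participation
# (restricted to the interactome's screened gene population) are tested per
# class with Fisher's exact test.

suppressMessages(library(dupOrigins))

fx <- read_fixture("results/fixture")
origins <- read.delim("results/origins.tsv", stringsAsFactors = FALSE)

terms <- select_go_terms(fx$go, fx$namespaces, namespace = "BP",
                         min_genes = 300)
cat(sprintf("%d large BP terms selected (>300 genes)\n", length(terms)))

pooled <- origins$gene
classes <- names(which(table(origins$origin) >= 100))
profiles <- t(sapply(classes, function(cls)
  fold_enrichment_profile(origins$gene[origins$origin == cls], pooled,
                          terms, fx$go)))
write.table(data.frame(class = rownames(profiles), profiles,
                       check.names = FALSE),
            "results/functional_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cl <- cluster_profiles(profiles)
cat("\nprofile clustering (average linkage, 1 - r); leaf order:\n  ",
    paste(cl$order, collapse = " | "), "\n")
hc_lines <- utils::capture.output(str(as.dendrogram(cl$hclust)))
writeLines(hc_lines, "results/profile_dendrogram.txt")
if (requireNamespace("pheatmap", quietly = TRUE)) {
  grDevices::png("results/profile_heatmap.png", 900, 500)
  pheatmap::pheatmap(profiles, cluster_rows = cl$hclust,
                     cluster_cols = FALSE)
  grDevices::dev.off()
}

# essentiality: screened knockouts with phenotype
ess <- fx$essential[fx$essential$screened, ]
trait <- ess$gene[ess$phenotype == 1]
cat("\nEssentiality enrichment (screened-set background):\n")
ess_rows <- lapply(classes, function(cls) {
  r <- fisher_enrichment(intersect(origins$gene[origins$origin == cls],
                                   ess$gene), trait, ess$gene)
  cbind(class = cls, r)
})
ess_tab <- do.call(rbind, ess_rows)
print(ess_tab[, c("class", "n_class", "n_overlap", "fold_enrichment", "p")],
      digits = 3)

# PPI participation on the screened interactome population
ppi_genes <- unique(c(fx$ppi_edges$gene_a, fx$ppi_edges$gene_b))
cat("\nPPI enrichment (interactome screened background):\n")
ppi_rows <- lapply(classes, function(cls) {
  r <- ppi_enrichment(origins$gene[origins$origin == cls], ppi_genes,
                      fx$ppi_screened)
  cbind(class = cls, r)
})
ppi_tab <- do.call(rbind, ppi_rows)
print(ppi_tab[, c("class", "n_class", "n_overlap", "fold_enrichment", "p")],
      digits = 3)

write.table(ess_tab, "results/essentiality_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ppi_tab, "results/ppi_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwrote results/functional_profiles.tsv,",
    "results/essentiality_enrichment.tsv, results/ppi_enrichment.tsv\n")
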