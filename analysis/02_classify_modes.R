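#!/usr/bin/env Rscript
# Step 2: detect colinear blocks and classify duplicate modes.
#
# Reads the fixture written by step 1, chains intra-genome anchors into
# colinear blocks (the WGD duplicate pairs), classifies every homolog pair as
# wgd / tandem / proximal / dispersed ("within 10 annotated genes" separates
# local from dispersed; tandem means rank-adjacent), reduces redundancy by
# keeping each gene's smallest-Ks pair per local/dispersed mode, and labels
# genes by mode precedence wgd > tandem > proximal > dispersed.

suppressMessages(library(dupOrigins))

fx <- read_fixture("results/fixture")
lay <- fx$layouts$At

intra <- chain_anchors(
  family_anchor_pairs(lay, intra = TRUE, families = fx$families),
  min_block_size = 5, max_gap = 25, min_self_dist = 25)
cat(sprintf("intra-genome colinearity: %d blocks over %d anchor pairs\n",
            nrow(intra$blocks), nrow(intra$anchors)))
write_collinearity(intra, "results/intra_blocks.collinearity")

pm <- classify_pairs(fx$pairs, lay, wgd_pairs = intra$anchors,
                     local_window = 10)
pm <- reduce_redundancy(pm)
gm <- classify_genes(pm)

cat("\nGene-level duplicate modes:\n")
print(gm$counts)
write.table(gm$labels, "results/modes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pm, "results/pair_modes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/modes.tsv, results/pair_modes.tsv,",
    "results/intra_blocks.collinearity\n")
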