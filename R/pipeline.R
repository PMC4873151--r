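#' Colinearity-conservation matrix of focal genes against the ladder
#'
#' Runs anchor chaining between the focal genome and every ladder outgroup
#' and records, per focal gene, whether it is an anchor of at least one
#' block of each comparison.
#'
#' @param sim a `sim_result`.
#' @param min_block_size,max_gap chaining parameters (see [chain_anchors()]).
#' @return logical matrix, rows = focal genes (rownames), columns = ladder
#'   outgroups nearest to farthest.
#' @export
colinearity_matrix <- function(sim, min_block_size = 5L, max_gap = 25L) {
  lay <- genome_layout(sim)
  og <- sim$config$outgroups
  m <- matrix(FALSE, nrow(lay), nrow(og),
              dimnames = list(lay$gene, og$species))
  for (sp in og$species) {
    chained <- chain_anchors(anchor_pairs(sim, sim$focal, sp),
                             min_block_size, max_gap)
    m[, sp] <- lay$gene %in% chained$anchors$gene_a
  }
  m
}

#' Classify duplicate origins of a simulated focal genome end-to-end
#'
#' Runs the full procedure: intra-genome blocks define WGD anchor pairs;
#' homolog pairs are classified into wgd / tandem / proximal / dispersed with
#' smallest-Ks redundancy reduction; dispersed genes are dated by colinearity
#' conservation against the outgroup ladder; origins (including
#' `transposed` and `relocated_gamma`) are called from the epoch windows.
#'
#' @param sim a `sim_result`.
#' @param min_block_size,max_gap chaining parameters.
#' @param top_k,ks_cap homolog-pair emission parameters.
#' @param local_window proximal rank window.
#' @param pair_seed seed for the Ks/Ka noise of the emitted pairs.
#' @param event origin label of the polyploidy event (default "gamma").
#' @param relocated_window,transposed_window Mya windows forwarded to
#'   [call_origins()] (defaults derived from the ladder there).
#' @return list of class `origin_pipeline`: `pairs` (classified, reduced),
#'   `gene_modes`, `mode_counts`, `intra_blocks`, `colin`, `assignments`
#'   (dispersed genes), `retention`, `origins`, `ladder`.
#' @export
run_origin_pipeline <- function(sim, min_block_size = 5L, max_gap = 25L,
                                top_k = 5L, ks_cap = 3, local_window = 10L,
                                pair_seed = 1L, event = "gamma",
                                relocated_window = NULL,
                                transposed_window = NULL) {
  lay <- genome_layout(sim)
  pairs <- emit_homolog_pairs(sim, top_k = top_k, ks_cap = ks_cap,
                              seed = pair_seed)
  intra <- chain_anchors(anchor_pairs(sim, sim$focal), min_block_size,
                         max_gap, min_self_dist = max_gap)
  pm <- classify_pairs(pairs, lay, wgd_pairs = intra$anchors,
                       local_window = local_window)
  pm <- reduce_redundancy(pm)
  gm <- classify_genes(pm)
  ladder <- epoch_ladder(sim$config$outgroups)
  colin <- colinearity_matrix(sim, min_block_size, max_gap)
  disp <- gm$labels$gene[gm$labels$mode == "dispersed"]
  assignments <- assign_epochs(colin[disp, , drop = FALSE], ladder)
  retention <- retention_rates(assignments, ladder)
  origins <- call_origins(gm$labels, assignments, ladder, event = event,
                          relocated_window = relocated_window,
                          transposed_window = transposed_window)
  structure(list(pairs = pm, gene_modes = gm$labels,
                 mode_counts = gm$counts, intra_blocks = intra,
                 colin = colin, assignments = assignments,
                 retention = retention, origins = origins, ladder = ladder),
            class = "origin_pipeline")
}

#' Attribute WGD genes to polyploidy events by block Ks
#'
#' When event-specific anchor-pair lists are unavailable, each intra-genome
#' block is attributed to the event whose configured Ks range contains the
#' block's median anchor Ks, and block genes inherit the attribution.
#'
#' @param intra_blocks intra-genome `colinear_blocks`.
#' @param pairs pair table with `ks` (unordered pairs matched by gene ids).
#' @param event_ks_ranges named list of length-2 Ks ranges, e.g.
#'   `list(alpha = c(0, 1), gamma = c(1.2, 3))`.
#' @return data.frame(gene, event) with NA where no range matches.
#' @export
attribute_wgd_events <- function(intra_blocks, pairs, event_ks_ranges) {
  a <- intra_blocks$anchors
  if (nrow(a) == 0L)
    return(data.frame(gene = character(0), event = character(0),
                      stringsAsFactors = FALSE))
  ks <- pairs$ks[match(unordered_key(a$gene_a, a$gene_b),
                       unordered_key(pairs$gene_a, pairs$gene_b))]
  med <- tapply(ks, a$block_id, stats::median, na.rm = TRUE)
  ev <- rep(NA_character_, length(med))
  for (nm in names(event_ks_ranges)) {
    r <- event_ks_ranges[[nm]]
    ev[!is.na(med) & med >= r[1] & med < r[2] & is.na(ev)] <- nm
  }
  block_event <- ev[match(a$block_id, as.integer(names(med)))]
  out <- unique(data.frame(gene = c(a$gene_a, a$gene_b),
                           event = rep(block_event, 2L),
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene, out$event), , drop = FALSE]
  out[!duplicated(out$gene), , drop = FALSE]
}

#' Compare inferred origins with simulation truth
#'
#' Joins the inferred origin labels with the truth table over genes the
#' classifier labelled (genes with no qualifying homolog pair are singletons
#' on both sides and are excluded). Truth classes `gamma` (with the event's
#' name), `relocated_gamma`, `tandem`, `proximal`, `transposed` map onto the
#' classifier's classes directly.
#'
#' @param origins output `origins` of [run_origin_pipeline()].
#' @param truth [truth_table()] of the same simulation.
#' @return list with `confusion` (truth x inferred table), `recall` and
#'   `precision` (named vectors over classes present), `n`.
#' @export
evaluate_origins <- function(origins, truth) {
  m <- merge(origins, truth[, c("gene", "truth_origin")], by = "gene")
  m <- m[m$truth_origin != "ancestral", , drop = FALSE]
  classes <- sort(union(m$truth_origin, m$origin))
  conf <- table(factor(m$truth_origin, classes), factor(m$origin, classes))
  diagv <- diag(conf)
  recall <- diagv / pmax(rowSums(conf), 1L)
  precision <- diagv / pmax(colSums(conf), 1L)
  list(confusion = conf, recall = recall, precision = precision, n = nrow(m))
}
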