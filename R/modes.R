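#' Classify homolog pairs by duplication mode
#'
#' A pair is `wgd` if it is a colinear-block anchor pair (unordered match
#' against `wgd_pairs`), else `tandem` if the two genes are rank-adjacent on
#' the same chromosome, else `proximal` if their rank difference is between 2
#' and `local_window`, else `dispersed`.
#'
#' When the pair table has an `evalue` column, pairs failing
#' `evalue < evalue_max` are dropped at ingestion (the homolog-search filter);
#' pair lists without E-values are assumed pre-filtered.
#'
#' @param pairs data.frame(gene_a, gene_b, ...optionally evalue, ks, ka).
#' @param layout gene layout of the genome, as from [genome_layout()].
#' @param wgd_pairs data.frame(gene_a, gene_b) of anchor pairs from an
#'   intra-genome colinearity run (or user-supplied WGD pair lists, possibly
#'   with an `event` column carrying alpha/beta/gamma attributions).
#' @param local_window largest rank difference still called proximal
#'   (default 10).
#' @param evalue_max E-value cutoff applied when an `evalue` column exists.
#' @return the pair table with a `mode` column (and `event` when attributable).
#' @export
classify_pairs <- function(pairs, layout, wgd_pairs = NULL,
                           local_window = 10L, evalue_max = 1e-10) {
  if (local_window < 1L) stop("local_window must be >= 1", call. = FALSE)
  if (!is.null(pairs$evalue)) pairs <- pairs[pairs$evalue < evalue_max, ,
                                             drop = FALSE]
  ia <- match(pairs$gene_a, layout$gene)
  ib <- match(pairs$gene_b, layout$gene)
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a gene missing from the layout", call. = FALSE)
  same_chrom <- layout$chrom[ia] == layout$chrom[ib]
  dr <- abs(layout$rank[ia] - layout$rank[ib])
  key <- unordered_key(pairs$gene_a, pairs$gene_b)
  is_wgd <- if (!is.null(wgd_pairs) && nrow(wgd_pairs)) {
    key %in% unordered_key(wgd_pairs$gene_a, wgd_pairs$gene_b)
  } else rep(FALSE, nrow(pairs))
  mode <- rep("dispersed", nrow(pairs))
  mode[same_chrom & dr <= local_window & dr >= 2] <- "proximal"
  mode[same_chrom & dr == 1] <- "tandem"
  mode[is_wgd] <- "wgd"
  pairs$mode <- mode
  if (!is.null(wgd_pairs$event)) {
    ev <- wgd_pairs$event[match(key, unordered_key(wgd_pairs$gene_a,
                                                   wgd_pairs$gene_b))]
    pairs$event <- ifelse(is_wgd, ev, NA_character_)
  }
  pairs
}

unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Smallest-Ks redundancy reduction
#'
#' For each gene and each reduced mode, keep only the pair with the smallest
#' Ks as the gene's representative pair of that mode (ties broken toward the
#' lexicographically smaller partner id). A pair survives if it is the
#' representative of either member. Genes whose candidate pairs all lack Ks
#' are dropped from the reduced modes with a warning.
#'
#' @param pair_modes output of [classify_pairs()] (needs a `ks` column).
#' @param reduce_modes modes to reduce; local and dispersed duplicates by
#'   default, mirroring the smallest-Ks rule applied to each.
#' @return the pair table with a logical `representative` column; pairs of
#'   non-reduced modes are representatives by definition.
#' @export
reduce_redundancy <- function(pair_modes,
                              reduce_modes = c("tandem", "proximal",
                                               "dispersed")) {
  stopifnot(is.data.frame(pair_modes))
  rep_flag <- !(pair_modes$mode %in% reduce_modes)
  sub_i <- which(!rep_flag)
  if (length(sub_i)) {
    if (is.null(pair_modes$ks))
      stop("Ks values are required to reduce redundancy", call. = FALSE)
    sub <- pair_modes[sub_i, , drop = FALSE]
    if (anyNA(sub$ks)) {
      bad <- is.na(sub$ks)
      warning(sum(bad), " pair(s) lack Ks and are excluded from ",
              "redundancy reduction", call. = FALSE)
      sub_i <- sub_i[!bad]; sub <- sub[!bad, , drop = FALSE]
    }
    # long form: every (gene, pair) incidence, per mode
    long <- data.frame(
      gene = c(sub$gene_a, sub$gene_b),
      partner = c(sub$gene_b, sub$gene_a),
      mode = rep(sub$mode, 2L), ks = rep(sub$ks, 2L),
      row = rep(sub_i, 2L), stringsAsFactors = FALSE)
    o <- order(long$gene, long$mode, long$ks, long$partner)
    long <- long[o, , drop = FALSE]
    first <- !duplicated(paste(long$gene, long$mode, sep = "\r"))
    rep_flag[unique(long$row[first])] <- TRUE
  }
  pair_modes$representative <- rep_flag
  pair_modes
}

#' Gene-level duplication modes
#'
#' Each gene appearing in any classified pair gets the highest-precedence
#' mode among its pairs (wgd > tandem > proximal > dispersed) and a
#' representative pair: the smallest-Ks representative of that mode (tie to
#' the lexicographically smaller partner).
#'
#' @param pair_modes output of [classify_pairs()] (optionally through
#'   [reduce_redundancy()]; reduction never changes a gene's mode).
#' @return list with `labels` (gene, mode, partner, ks, event when present)
#'   and `counts` (mode count table over labelled genes).
#' @export
classify_genes <- function(pair_modes) {
  prec <- c(wgd = 1L, tandem = 2L, proximal = 3L, dispersed = 4L)
  long <- data.frame(
    gene = c(pair_modes$gene_a, pair_modes$gene_b),
    partner = c(pair_modes$gene_b, pair_modes$gene_a),
    mode = rep(pair_modes$mode, 2L),
    ks = if (is.null(pair_modes$ks)) NA_real_ else rep(pair_modes$ks, 2L),
    event = if (is.null(pair_modes$event)) NA_character_
            else rep(pair_modes$event, 2L),
    stringsAsFactors = FALSE)
  o <- order(long$gene, prec[long$mode], long$ks, long$partner)
  long <- long[o, , drop = FALSE]
  labels <- long[!duplicated(long$gene), , drop = FALSE]
  rownames(labels) <- NULL
  counts <- table(factor(labels$mode, levels = names(prec)))
  list(labels = labels, counts = counts)
}
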