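#' Detect colinear blocks by dynamic-programming anchor chaining
#'
#' Chains homolog anchor pairs into colinear (synteny) blocks between two
#' gene orders, inter- or intra-genome. Within each chromosome pair, chains
#' are maximal runs of anchors with strictly increasing ranks on the first
#' axis and strictly increasing (orientation `same`) or strictly decreasing
#' (`inverted`) ranks on the second, with consecutive rank gaps of at most
#' `max_gap` on both axes. Chain score is the number of anchors (unit
#' weights, no gap penalty, hard gap cap). Non-overlapping blocks are
#' extracted greedily by repeatedly peeling off the highest-scoring chain;
#' each anchor belongs to at most one block.
#'
#' Before chaining, anchors sharing a rank on either axis within a chromosome
#' pair are collapsed to the best-scoring one (ties to the smaller opposite
#' rank), mirroring tandem-array collapsing. Score ties between chains are
#' broken toward the chain with lexicographically smallest anchor ranks;
#' orientation `same` wins ties against `inverted`. The result is
#' deterministic.
#'
#' For intra-genome self-comparisons, anchors closer than `min_self_dist`
#' ranks to the self-diagonal of the same chromosome (tandem and proximal
#' pairs) are excluded before chaining, so that scattered local duplications
#' cannot chain into spurious near-diagonal blocks.
#'
#' @param anchors data.frame with columns `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `rank_a`, `rank_b` and optionally `score` (default 1), e.g.
#'   from [anchor_pairs()] or [pairs_to_anchors()].
#' @param min_block_size minimum anchors per block (>= 2; default 5).
#' @param max_gap maximum rank gap between consecutive anchors (default 25).
#' @param min_self_dist same-chromosome anchors with rank difference <=
#'   this value are dropped (default 0, i.e. keep all; the origin pipeline
#'   uses `max_gap` for its intra-genome run).
#' @return list of class `colinear_blocks`: `blocks` (block_id, chrom_a,
#'   chrom_b, orientation, n_anchors, score) and `anchors` (the input rows
#'   assigned to blocks, with `block_id` and `position`).
#' @export
chain_anchors <- function(anchors, min_block_size = 5L, max_gap = 25L,
                          min_self_dist = 0L) {
  if (min_block_size < 2L) stop("min_block_size must be >= 2", call. = FALSE)
  req <- c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")
  if (!all(req %in% names(anchors)))
    stop("anchors must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (is.null(anchors$score)) anchors$score <- 1
  if (min_self_dist > 0L && nrow(anchors)) {
    near_diag <- anchors$chrom_a == anchors$chrom_b &
      abs(anchors$rank_a - anchors$rank_b) <= min_self_dist
    anchors <- anchors[!near_diag, , drop = FALSE]
  }
  out_blocks <- list(); out_anchors <- list()
  bid <- 0L
  if (nrow(anchors)) {
    key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
    grp <- split(seq_len(nrow(anchors)), key)
    # deterministic group order
    grp <- grp[order(names(grp))]
    for (idx in grp) {
      if (length(idx) < min_block_size) next
      sub <- anchors[idx, , drop = FALSE]
      sub <- collapse_shared_ranks(sub)
      res <- peel_chains(sub, min_block_size, max_gap)
      for (ch in res) {
        bid <- bid + 1L
        blk <- sub[ch$members, , drop = FALSE]
        blk$block_id <- bid
        blk$position <- seq_len(nrow(blk))
        out_anchors[[bid]] <- blk
        out_blocks[[bid]] <- data.frame(
          block_id = bid, chrom_a = blk$chrom_a[1], chrom_b = blk$chrom_b[1],
          orientation = ch$orientation, n_anchors = nrow(blk),
          score = nrow(blk), stringsAsFactors = FALSE)
      }
    }
  }
  blocks <- if (length(out_blocks)) do.call(rbind, out_blocks) else
    data.frame(block_id = integer(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               n_anchors = integer(0), score = numeric(0),
               stringsAsFactors = FALSE)
  banchors <- if (length(out_anchors)) do.call(rbind, out_anchors) else
    cbind(anchors[0, , drop = FALSE],
          data.frame(block_id = integer(0), position = integer(0)))
  rownames(blocks) <- rownames(banchors) <- NULL
  structure(list(blocks = blocks, anchors = banchors,
                 params = list(min_block_size = min_block_size,
                               max_gap = max_gap)),
            class = "colinear_blocks")
}

# reciprocal-best collapse: an anchor survives iff it is the best-scoring
# anchor of its rank on BOTH axes (ties to the smaller opposite rank).
# Symmetric under swapping the two genomes, and leaves at most one anchor
# per rank on each axis.
collapse_shared_ranks <- function(sub) {
  winner <- function(rank, opp) {
    o <- order(rank, -sub$score, opp)
    idx <- o[!duplicated(rank[o])]
    seq_len(nrow(sub)) %in% idx
  }
  keep <- winner(sub$rank_a, sub$rank_b) & winner(sub$rank_b, sub$rank_a)
  sub <- sub[keep, , drop = FALSE]
  sub[order(sub$rank_a), , drop = FALSE]
}

# repeatedly extract the best chain (over both orientations) from one
# chromosome-pair anchor set; returns list of list(members, orientation)
peel_chains <- function(sub, min_block_size, max_gap) {
  avail <- rep(TRUE, nrow(sub))
  chains <- list()
  repeat {
    if (sum(avail) < min_block_size) break
    ra <- sub$rank_a[avail]; rb <- sub$rank_b[avail]
    c_same <- best_chain_dp(ra, rb, max_gap)
    c_inv <- best_chain_dp(ra, -rb, max_gap)
    use_same <- length(c_same) >= length(c_inv)
    best <- if (use_same) c_same else c_inv
    if (length(best) < min_block_size) break
    members <- which(avail)[best]
    chains[[length(chains) + 1L]] <-
      list(members = members,
           orientation = if (use_same) "same" else "inverted")
    avail[members] <- FALSE
  }
  chains
}

# longest strictly-increasing chain in both coordinates with bounded gaps;
# ties broken toward smallest (rank_a, rank_b); returns indices into input
best_chain_dp <- function(ra, rb, max_gap) {
  o <- order(ra, rb)
  ra_s <- ra[o]; rb_s <- rb[o]
  n <- length(ra_s)
  dp <- rep(1L, n); prev <- rep(0L, n)
  lo_j <- findInterval(ra_s - max_gap - 0.5, ra_s) + 1L
  for (i in seq_len(n)) {
    if (i == 1L || lo_j[i] > i - 1L) next
    js <- lo_j[i]:(i - 1L)
    ok <- ra_s[js] < ra_s[i] &
      rb_s[js] < rb_s[i] & (rb_s[i] - rb_s[js]) <= max_gap
    if (!any(ok)) next
    js <- js[ok]
    best <- max(dp[js])
    dp[i] <- best + 1L
    prev[i] <- js[which.max(dp[js] == best)]  # smallest index among ties
  }
  end <- which.max(dp)  # smallest index among maxima
  chain <- integer(dp[end])
  k <- dp[end]; i <- end
  while (i > 0L) { chain[k] <- i; k <- k - 1L; i <- prev[i] }
  o[chain]
}

#' Per-gene colinear partners
#'
#' @param chained result of [chain_anchors()].
#' @return data.frame(gene, partner, block_id, side): one row per anchor and
#'   side; genes in no block are absent.
#' @export
colinear_gene_sets <- function(chained) {
  a <- chained$anchors
  if (nrow(a) == 0L)
    return(data.frame(gene = character(0), partner = character(0),
                      block_id = integer(0), side = character(0),
                      stringsAsFactors = FALSE))
  rbind(
    data.frame(gene = a$gene_a, partner = a$gene_b, block_id = a$block_id,
               side = "a", stringsAsFactors = FALSE),
    data.frame(gene = a$gene_b, partner = a$gene_a, block_id = a$block_id,
               side = "b", stringsAsFactors = FALSE))
}

#' Is a gene colinearity-conserved in a comparison?
#'
#' TRUE iff the gene is an anchor of at least one colinear block of the
#' comparison (either side for intra-genome blocks).
#'
#' @param genes character vector of gene ids.
#' @param chained result of [chain_anchors()] for the comparison.
#' @return logical vector along `genes`.
#' @export
is_colinear_with <- function(genes, chained) {
  genes %in% c(chained$anchors$gene_a, chained$anchors$gene_b)
}

#' @export
print.colinear_blocks <- function(x, ...) {
  cat("colinear_blocks:", nrow(x$blocks), "blocks,",
      nrow(x$anchors), "anchors (min_block_size=",
      x$params$min_block_size, ", max_gap=", x$params$max_gap, ")\n", sep = "")
  invisible(x)
}
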