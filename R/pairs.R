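#' Emit intra-genome homolog pairs with clock-scaled Ks and Ka
#'
#' Emulates the within-genome BLASTP homolog search that feeds the duplicate
#' classifier: for every gene, at most `top_k` same-family partners with the
#' smallest Ks, subject to a detectability cap `ks_cap` (the stand-in for the
#' E-value cutoff of a sequence search). Ks of a pair is
#' `2 * mu * divergence_time` times multiplicative lognormal noise; Ka is
#' `omega * Ks` with omega drawn per pair from the configured lognormal.
#'
#' The pair list is symmetric-closed (a pair survives if it is within the
#' `top_k` smallest-Ks partners of either member) and deduplicated over
#' unordered pairs.
#'
#' @param sim a `sim_result`.
#' @param species species name (default focal).
#' @param top_k maximum partners per gene (>= 1).
#' @param ks_cap pairs with Ks >= `ks_cap` are not emitted.
#' @param seed optional seed for the Ks/Ka noise draws.
#' @return data.frame(gene_a, gene_b, evalue, ks, ka, omega); `gene_a <
#'   gene_b` lexicographically.
#' @export
emit_homolog_pairs <- function(sim, species = sim$focal, top_k = 5L,
                               ks_cap = 3, seed = NULL) {
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lay <- genome_layout(sim, species)
  ids <- gene_to_id(lay$gene)
  fam <- sim$nodes$family[ids]
  by_fam <- split(ids, fam)
  by_fam <- by_fam[lengths(by_fam) >= 2L]
  if (length(by_fam) == 0L || ks_cap <= 0)
    return(empty_pairs())
  a <- integer(0); b <- integer(0)
  for (v in by_fam) {
    v <- sort(v)
    cmb <- utils::combn(v, 2L)
    a <- c(a, cmb[1L, ]); b <- c(b, cmb[2L, ])
  }
  div <- vapply(seq_along(a), function(i)
    node_divergence_one(sim$nodes$parent, sim$nodes$time, a[i], b[i]),
    numeric(1))
  mu <- sim$config$clock$mu
  sd <- sim$config$clock$ks_sd
  noise <- if (sd > 0) exp(stats::rnorm(length(a), 0, sd)) else 1
  ks <- 2 * mu * div * noise
  om <- stats::rlnorm(length(a), sim$config$omega$meanlog,
                      sim$config$omega$sdlog)
  keep <- ks < ks_cap
  a <- a[keep]; b <- b[keep]; ks <- ks[keep]; om <- om[keep]
  if (length(a) == 0L) return(empty_pairs())
  # top_k smallest-Ks partners per gene, symmetric closure
  long_gene <- c(a, b)
  long_pair <- c(seq_along(a), seq_along(a))
  ord <- order(long_gene, ks[long_pair])
  long_gene <- long_gene[ord]; long_pair <- long_pair[ord]
  rk <- stats::ave(seq_along(long_gene), long_gene, FUN = seq_along)
  keep_pair <- sort(unique(long_pair[rk <= top_k]))
  a <- a[keep_pair]; b <- b[keep_pair]
  ks <- ks[keep_pair]; om <- om[keep_pair]
  data.frame(gene_a = id_to_gene(a), gene_b = id_to_gene(b),
             evalue = evalue_proxy(ks), ks = ks, ka = om * ks, omega = om,
             stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             evalue = numeric(0), ks = numeric(0), ka = numeric(0),
             omega = numeric(0), stringsAsFactors = FALSE)
}

# monotone map from Ks to a BLAST-like E-value stand-in
evalue_proxy <- function(ks) 10^(-pmax(11, 200 * exp(-ks)))

#' Same-family anchor pairs between two genomes
#'
#' Candidate anchors for colinearity detection: every pair of same-family
#' genes, one from each genome (or unordered pairs within one genome when
#' `species_a == species_b`), annotated with chromosome and rank on each
#' side. Anchor scores are unit weights.
#'
#' @param sim a `sim_result`.
#' @param species_a,species_b species names; equal for the intra-genome
#'   self-comparison (the trivial self-pairing of a gene with itself is
#'   excluded, and unordered pairs appear once).
#' @return data.frame(gene_a, gene_b, chrom_a, chrom_b, rank_a, rank_b,
#'   score).
#' @export
anchor_pairs <- function(sim, species_a, species_b = species_a) {
  la <- genome_layout(sim, species_a)
  lb <- genome_layout(sim, species_b)
  fa <- sim$nodes$family[gene_to_id(la$gene)]
  fb <- sim$nodes$family[gene_to_id(lb$gene)]
  da <- data.frame(gene_a = la$gene, chrom_a = la$chrom, rank_a = la$rank,
                   fam = fa, stringsAsFactors = FALSE)
  db <- data.frame(gene_b = lb$gene, chrom_b = lb$chrom, rank_b = lb$rank,
                   fam = fb, stringsAsFactors = FALSE)
  m <- merge(da, db, by = "fam")
  if (species_a == species_b) {
    m <- m[m$gene_a < m$gene_b, , drop = FALSE]
    m <- canonicalize_intra(m)
  }
  m$fam <- NULL
  m$score <- 1
  rownames(m) <- NULL
  m[, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b", "score")]
}

# orient intra-genome anchors so chrom_a <= chrom_b (rank_a < rank_b within a
# chromosome); each unordered pair appears exactly once
canonicalize_intra <- function(m) {
  swap <- m$chrom_a > m$chrom_b |
    (m$chrom_a == m$chrom_b & m$rank_a > m$rank_b)
  if (any(swap)) {
    tmp <- m[swap, ]
    m[swap, c("gene_a", "chrom_a", "rank_a")] <-
      tmp[, c("gene_b", "chrom_b", "rank_b")]
    m[swap, c("gene_b", "chrom_b", "rank_b")] <-
      tmp[, c("gene_a", "chrom_a", "rank_a")]
  }
  m
}

#' Same-family anchor pairs from layouts and a family table
#'
#' File-based counterpart of [anchor_pairs()]: builds candidate anchors from
#' gene layouts plus a gene-to-family map (e.g. a fixture's `families.tsv`).
#'
#' @param layout_a,layout_b gene layouts ([genome_layout()]-shaped).
#' @param families data.frame(gene, family) covering both layouts.
#' @param intra TRUE for an intra-genome self-comparison (unordered pairs
#'   once, self-pairs excluded).
#' @return anchor data.frame as from [anchor_pairs()].
#' @export
family_anchor_pairs <- function(layout_a, layout_b = layout_a,
                                intra = identical(layout_a, layout_b),
                                families) {
  fa <- families$family[match(layout_a$gene, families$gene)]
  fb <- families$family[match(layout_b$gene, families$gene)]
  if (anyNA(fa) || anyNA(fb))
    stop("layout gene(s) missing from the family table", call. = FALSE)
  da <- data.frame(gene_a = layout_a$gene, chrom_a = layout_a$chrom,
                   rank_a = layout_a$rank, fam = fa, stringsAsFactors = FALSE)
  db <- data.frame(gene_b = layout_b$gene, chrom_b = layout_b$chrom,
                   rank_b = layout_b$rank, fam = fb, stringsAsFactors = FALSE)
  m <- merge(da, db, by = "fam")
  if (intra) {
    m <- m[m$gene_a < m$gene_b, , drop = FALSE]
    m <- canonicalize_intra(m)
  } else {
    m <- m[m$gene_a != m$gene_b, , drop = FALSE]
  }
  m$fam <- NULL
  m$score <- 1
  rownames(m) <- NULL
  m[, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b", "score")]
}

#' Attach ranks to a homolog pair list
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (plus any other columns).
#' @param layout_a,layout_b gene layouts as from [genome_layout()].
#' @return the pair table with chrom/rank columns for both members.
#' @export
pairs_to_anchors <- function(pairs, layout_a, layout_b = layout_a) {
  ia <- match(pairs$gene_a, layout_a$gene)
  ib <- match(pairs$gene_b, layout_b$gene)
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a gene missing from the layout", call. = FALSE)
  out <- pairs
  out$chrom_a <- layout_a$chrom[ia]; out$rank_a <- layout_a$rank[ia]
  out$chrom_b <- layout_b$chrom[ib]; out$rank_b <- layout_b$rank[ib]
  if (is.null(out$score)) out$score <- 1
  out
}
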