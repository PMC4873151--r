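#' Write a simulated data set as plain-text fixture files
#'
#' Emits, per species, a BED-like gene table (`genes_<species>.bed`: chrom,
#' start = rank, end = rank + 1, gene, score 0, strand +), plus
#' `pairs.tsv` (gene_a, gene_b, evalue, ks, ka), `ladder.tsv` (species,
#' divergence_mya), `truth.tsv`, `families.tsv`, and, when an annotation
#' bundle is given, `go.tsv`, `go_namespaces.tsv`, `essential.tsv`,
#' `ppi_edges.tsv`, `ppi_screened.tsv`, `expression.tsv`, `pwm_hits.tsv`.
#' All files round-trip losslessly through [read_fixture()].
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if missing).
#' @param pairs homolog pair table, e.g. from [emit_homolog_pairs()];
#'   optional.
#' @param annotations an `annotation_bundle`; optional.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, pairs = NULL, annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in names(sim$genomes)) {
    lay <- genome_layout(sim, sp)
    bed <- data.frame(chrom = lay$chrom, start = lay$rank,
                      end = lay$rank + 1L, gene = lay$gene,
                      score = rep(0L, nrow(lay)),
                      strand = rep("+", nrow(lay)), stringsAsFactors = FALSE)
    tsv(bed, sprintf("genes_%s.bed", sp))
  }
  if (!is.null(pairs))
    tsv(pairs[, c("gene_a", "gene_b", "evalue", "ks", "ka")], "pairs.tsv")
  tsv(sim$config$outgroups, "ladder.tsv")
  tsv(truth_table(sim), "truth.tsv")
  all_genes <- unlist(lapply(names(sim$genomes), function(sp)
    genome_layout(sim, sp)$gene), use.names = FALSE)
  fams <- data.frame(gene = all_genes,
                     family = sim$nodes$family[gene_to_id(all_genes)],
                     stringsAsFactors = FALSE)
  tsv(fams, "families.tsv")
  if (!is.null(annotations)) {
    tsv(annotations$go, "go.tsv")
    tsv(annotations$namespaces, "go_namespaces.tsv")
    tsv(annotations$essential, "essential.tsv")
    tsv(annotations$ppi_edges, "ppi_edges.tsv")
    tsv(data.frame(gene = annotations$ppi_screened), "ppi_screened.tsv")
    expr <- data.frame(gene = rownames(annotations$expression),
                       annotations$expression, check.names = FALSE,
                       stringsAsFactors = FALSE)
    tsv(expr, "expression.tsv")
    tsv(annotations$pwm_hits, "pwm_hits.tsv")
  }
  invisible(dir)
}

#' Read a fixture directory
#'
#' @param dir directory written by [write_fixture()] (or hand-assembled with
#'   the same file names).
#' @return list with `layouts` (per species gene/chrom/rank data.frames),
#'   `pairs`, `ladder`, `truth`, `families`, and any annotation tables
#'   present.
#' @export
read_fixture <- function(dir) {
  tsv <- function(name, ...) {
    f <- file.path(dir, name)
    if (!file.exists(f)) return(NULL)
    utils::read.table(f, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
  }
  beds <- list.files(dir, pattern = "^genes_.*\\.bed$")
  layouts <- list()
  for (b in beds) {
    sp <- sub("^genes_(.*)\\.bed$", "\\1", b)
    layouts[[sp]] <- read_gene_bed(file.path(dir, b))
  }
  out <- list(layouts = layouts, pairs = tsv("pairs.tsv"),
              ladder = tsv("ladder.tsv"), truth = tsv("truth.tsv"),
              families = tsv("families.tsv"), go = tsv("go.tsv"),
              namespaces = tsv("go_namespaces.tsv"),
              essential = tsv("essential.tsv"),
              ppi_edges = tsv("ppi_edges.tsv"),
              pwm_hits = tsv("pwm_hits.tsv"))
  scr <- tsv("ppi_screened.tsv")
  if (!is.null(scr)) out$ppi_screened <- scr$gene
  expr <- tsv("expression.tsv")
  if (!is.null(expr)) {
    m <- as.matrix(expr[, -1, drop = FALSE])
    rownames(m) <- expr$gene
    out$expression <- m
  }
  out
}

#' Read a BED-like gene table into a layout
#'
#' Expects columns chrom, start, end, gene (and optionally score, strand);
#' ranks are re-derived from the start order within each chromosome, so any
#' coordinate system whose order matches gene order works.
#'
#' @param path BED-like file (with or without a header line).
#' @return data.frame(gene, chrom, rank) with 0-based ranks.
#' @export
read_gene_bed <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first)
  bed <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!has_header) names(bed)[1:4] <- c("chrom", "start", "end", "gene")
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(bed)), bed$chrom, FUN = seq_along) - 1L
  data.frame(gene = as.character(bed$gene), chrom = as.character(bed$chrom),
             rank = as.integer(rank), stringsAsFactors = FALSE)
}

#' Read a homolog pair TSV, applying the homolog-search filter
#'
#' Keeps pairs with `evalue < evalue_max` (when an evalue column exists) and
#' at most `top_k` partners per gene by ascending E-value, mirroring a
#' top-hits BLAST export.
#'
#' @param path TSV with columns gene_a, gene_b and optionally evalue, ks, ka.
#' @param top_k partners kept per gene (default 5); NULL disables the cap.
#' @param evalue_max E-value cutoff (default 1e-10).
#' @return filtered pair data.frame.
#' @export
read_pair_tsv <- function(path, top_k = 5L, evalue_max = 1e-10) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!is.null(p$evalue)) {
    p <- p[p$evalue < evalue_max, , drop = FALSE]
    if (!is.null(top_k) && nrow(p)) {
      long_gene <- c(p$gene_a, p$gene_b)
      long_pair <- rep(seq_len(nrow(p)), 2L)
      ev <- rep(p$evalue, 2L)
      o <- order(long_gene, ev)
      rk <- stats::ave(seq_along(o), long_gene[o], FUN = seq_along)
      p <- p[sort(unique(long_pair[o][rk <= top_k])), , drop = FALSE]
    }
  }
  rownames(p) <- NULL
  p
}
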