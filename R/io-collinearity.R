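#' Write colinear blocks in the MCScanX .collinearity dialect
#'
#' Block headers are `## Alignment n: score=S e_value=E N=k chrA&chrB plus`
#' (`minus` for inverted blocks); anchor lines are `n-i: geneA geneB e-value`.
#' Files written this way round-trip through [read_collinearity()].
#'
#' @param chained result of [chain_anchors()].
#' @param path output file.
#' @export
write_collinearity <- function(chained, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### dupOrigins collinear blocks ###############", con)
  b <- chained$blocks
  a <- chained$anchors
  for (i in seq_len(nrow(b))) {
    ori <- if (b$orientation[i] == "inverted") "minus" else "plus"
    writeLines(sprintf("## Alignment %d: score=%.1f e_value=0 N=%d %s&%s %s",
                       b$block_id[i] - 1L, b$score[i], b$n_anchors[i],
                       b$chrom_a[i], b$chrom_b[i], ori), con)
    rows <- a[a$block_id == b$block_id[i], , drop = FALSE]
    ev <- if (is.null(rows$evalue)) rep(0, nrow(rows)) else rows$evalue
    writeLines(sprintf("%3d-%3d:\t%s\t%s\t%g", b$block_id[i] - 1L,
                       seq_len(nrow(rows)) - 1L, rows$gene_a, rows$gene_b, ev),
               con)
  }
  invisible(path)
}

#' Read colinear blocks from a MCScanX-style .collinearity file
#'
#' Accepts the dialect written by [write_collinearity()] as well as real
#' MCScanX output (orientation `plus`/`minus`). Ranks are attached from the
#' supplied layouts so the result can feed the same downstream operations as
#' [chain_anchors()].
#'
#' @param path .collinearity file.
#' @param layout_a,layout_b gene layouts ([genome_layout()]-shaped); pass the
#'   same layout twice for an intra-genome file.
#' @return a `colinear_blocks` object.
#' @export
read_collinearity <- function(path, layout_a, layout_b = layout_a) {
  lines <- readLines(path)
  hdr <- grepl("^## Alignment", lines)
  blocks <- list(); anchors <- list()
  cur <- 0L
  for (ln in lines) {
    if (grepl("^#", ln) && !grepl("^## Alignment", ln)) next
    if (grepl("^## Alignment", ln)) {
      m <- regmatches(ln, regexec(
        paste0("^## Alignment\\s+(\\S+):\\s+score=(\\S+)\\s+e_value=(\\S+)",
               "\\s+N=(\\S+)\\s+(\\S+)&(\\S+)\\s+(\\S+)"), ln))[[1]]
      if (length(m) != 8) stop("malformed block header: ", ln, call. = FALSE)
      cur <- cur + 1L
      blocks[[cur]] <- data.frame(
        block_id = cur, chrom_a = m[6], chrom_b = m[7],
        orientation = if (m[8] %in% c("minus", "inverted")) "inverted"
                      else "same",
        n_anchors = as.integer(m[5]), score = as.numeric(m[3]),
        stringsAsFactors = FALSE)
      anchors[[cur]] <- list()
    } else if (nzchar(trimws(ln))) {
      f <- strsplit(trimws(sub("^[^:]*:", "", ln)), "\\s+")[[1]]
      if (length(f) < 2) stop("malformed anchor line: ", ln, call. = FALSE)
      anchors[[cur]][[length(anchors[[cur]]) + 1L]] <-
        c(f[1], f[2], if (length(f) >= 3) f[3] else "0")
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               n_anchors = integer(0), score = numeric(0))
  arows <- list()
  for (i in seq_along(anchors)) {
    if (!length(anchors[[i]])) next
    m <- do.call(rbind, anchors[[i]])
    arows[[i]] <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                             evalue = as.numeric(m[, 3]), block_id = i,
                             position = seq_len(nrow(m)),
                             stringsAsFactors = FALSE)
  }
  a <- if (length(arows)) do.call(rbind, arows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               evalue = numeric(0), block_id = integer(0),
               position = integer(0), stringsAsFactors = FALSE)
  if (nrow(a)) {
    ia <- match(a$gene_a, layout_a$gene); ib <- match(a$gene_b, layout_b$gene)
    if (anyNA(ia) || anyNA(ib))
      stop("collinearity file references genes missing from the layouts",
           call. = FALSE)
    a$chrom_a <- layout_a$chrom[ia]; a$rank_a <- layout_a$rank[ia]
    a$chrom_b <- layout_b$chrom[ib]; a$rank_b <- layout_b$rank[ib]
    a$score <- 1
    a <- a[, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b",
               "score", "evalue", "block_id", "position")]
  }
  blocks$n_anchors <- as.integer(table(factor(a$block_id,
                                              levels = blocks$block_id)))
  structure(list(blocks = blocks, anchors = a,
                 params = list(min_block_size = NA, max_gap = NA)),
            class = "colinear_blocks")
}
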