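#' Select large GO terms of one namespace
#'
#' Terms of the requested namespace annotating strictly more than `min_genes`
#' genes, sorted by gene count descending (ties by term id).
#'
#' @param annotations data.frame(gene, term), pre-propagated.
#' @param namespaces data.frame(term, namespace).
#' @param namespace namespace to keep (default "BP").
#' @param min_genes strict lower bound on annotated genes (default 300).
#' @return character vector of term ids (possibly empty, with a warning).
#' @export
select_go_terms <- function(annotations, namespaces, namespace = "BP",
                            min_genes = 300L) {
  keep <- namespaces$term[namespaces$namespace == namespace]
  ann <- unique(annotations[annotations$term %in% keep, c("gene", "term")])
  cnt <- table(ann$term)
  cnt <- cnt[cnt > min_genes]
  if (length(cnt) == 0L) {
    warning("no ", namespace, " term annotates more than ", min_genes,
            " genes", call. = FALSE)
    return(character(0))
  }
  names(cnt)[order(-cnt, names(cnt))]
}

#' Fold-enrichment functional profile of a duplicate class
#'
#' Per term, the fraction of the class's genes carrying the term divided by
#' the fraction of the pooled duplicates carrying it.
#'
#' @param class_genes genes of one origin class (subset of `pooled_genes`).
#' @param pooled_genes union of all classified duplicate genes.
#' @param terms ordered term ids (e.g. from [select_go_terms()]).
#' @param annotations data.frame(gene, term).
#' @return named numeric vector of fold enrichments along `terms`; a term
#'   absent from the pooled set yields NA with a warning.
#' @export
fold_enrichment_profile <- function(class_genes, pooled_genes, terms,
                                    annotations) {
  if (!all(class_genes %in% pooled_genes))
    stop("class genes must be a subset of the pooled duplicates",
         call. = FALSE)
  ann <- annotations[annotations$term %in% terms, ]
  by_term <- split(ann$gene, factor(ann$term, levels = terms))
  fe <- vapply(by_term, function(g) {
    pooled_frac <- length(intersect(g, pooled_genes)) / length(pooled_genes)
    class_frac <- length(intersect(g, class_genes)) / length(class_genes)
    if (pooled_frac == 0) NA_real_ else class_frac / pooled_frac
  }, numeric(1))
  if (anyNA(fe))
    warning("term(s) absent from the pooled set: ",
            paste(terms[is.na(fe)], collapse = ", "), call. = FALSE)
  fe
}

#' Cluster functional profiles (average linkage, 1 - r)
#'
#' Pairwise distance is 1 minus the Pearson correlation of the profiles;
#' merging is average-linkage hierarchical clustering. Leaf order is made
#' deterministic by rotating each merge so the lexicographically smallest
#' class name comes first.
#'
#' @param profiles numeric matrix, one row per origin class (rownames =
#'   class names), columns = terms; >= 2 rows, equal term sets, nonzero
#'   variance per row.
#' @return list(hclust, dist (matrix), order (leaf names)).
#' @export
cluster_profiles <- function(profiles) {
  if (nrow(profiles) < 2) stop("need >= 2 profiles", call. = FALSE)
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0))
    stop("constant profile(s): ",
         paste(rownames(profiles)[v == 0], collapse = ", "), call. = FALSE)
  d <- 1 - stats::cor(t(profiles))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  hc <- rotate_smallest_first(hc)
  list(hclust = hc, dist = d, order = hc$labels[hc$order])
}

# deterministic leaf rotation: at every merge put the subtree whose smallest
# label is lexicographically smaller on the left
rotate_smallest_first <- function(hc) {
  n <- length(hc$labels)
  smallest <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    lab <- function(j) if (j < 0) hc$labels[-j] else smallest[j]
    l <- lab(hc$merge[i, 1]); r <- lab(hc$merge[i, 2])
    if (r < l) hc$merge[i, ] <- hc$merge[i, 2:1]
    smallest[i] <- min(l, r)
  }
  ord <- integer(0)
  walk <- function(j) {
    if (j < 0) ord <<- c(ord, -j)
    else { walk(hc$merge[j, 1]); walk(hc$merge[j, 2]) }
  }
  walk(nrow(hc$merge))
  hc$order <- ord
  hc
}

#' Fisher exact enrichment of a trait in a duplicate class
#'
#' Builds the 2x2 class-by-trait table over the background and reports the
#' two-sided exact p (hypergeometric enumeration), the odds ratio, and the
#' fold enrichment (trait fraction in class over trait fraction in
#' background).
#'
#' @param class_genes,trait_genes character vectors, subsets of
#'   `background_genes`.
#' @param background_genes the background gene universe.
#' @return data.frame(n_class, n_trait, n_background, n_overlap, odds_ratio,
#'   p, fold_enrichment).
#' @export
fisher_enrichment <- function(class_genes, trait_genes, background_genes) {
  bg <- unique(background_genes)
  if (length(bg) == 0L) stop("empty background", call. = FALSE)
  cl <- unique(intersect(class_genes, bg))
  tr <- unique(intersect(trait_genes, bg))
  k <- length(intersect(cl, tr))
  tab <- matrix(c(k, length(cl) - k,
                  length(tr) - k, length(bg) - length(cl) - length(tr) + k),
                nrow = 2)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  fold <- if (length(cl) == 0 || length(tr) == 0) NA_real_ else
    (k / length(cl)) / (length(tr) / length(bg))
  data.frame(n_class = length(cl), n_trait = length(tr),
             n_background = length(bg), n_overlap = k,
             odds_ratio = unname(ft$estimate), p = ft$p.value,
             fold_enrichment = fold)
}

#' PPI enrichment on a screened background
#'
#' Enrichment of protein-protein-interaction participation, restricted to
#' the population of genes actually screened by the interactome assay: class
#' genes are intersected with the screened set before testing.
#'
#' @param class_genes genes of one origin class.
#' @param ppi_genes genes participating in >= 1 interaction.
#' @param screened_genes the assay's screened gene population (the
#'   background).
#' @return [fisher_enrichment()] row plus a logical `untestable` flag (TRUE
#'   when the class does not intersect the screened set).
#' @export
ppi_enrichment <- function(class_genes, ppi_genes, screened_genes) {
  cl <- intersect(class_genes, screened_genes)
  if (length(cl) == 0L) {
    res <- data.frame(n_class = 0L, n_trait = length(unique(
      intersect(ppi_genes, screened_genes))),
      n_background = length(unique(screened_genes)), n_overlap = 0L,
      odds_ratio = NA_real_, p = NA_real_, fold_enrichment = NA_real_)
    res$untestable <- TRUE
    return(res)
  }
  res <- fisher_enrichment(cl, ppi_genes, screened_genes)
  res$untestable <- FALSE
  res
}
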