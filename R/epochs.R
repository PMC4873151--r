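#' Build an epoch ladder from ordered outgroups
#'
#' Outgroups ordered from nearest to farthest define half-open epoch
#' intervals `[t_i, t_{i+1})` in Mya: the youngest epoch `[0, t_1)` plus one
#' epoch per adjacent outgroup gap, so the number of epochs equals the number
#' of outgroups. Genes colinear with the farthest outgroup predate the ladder
#' (sentinel `pre_ladder`).
#'
#' @param outgroups data.frame(species, divergence_mya), strictly increasing.
#' @return object of class `epoch_ladder` with `outgroups` and `epochs`
#'   (epoch, start, end, label).
#' @export
epoch_ladder <- function(outgroups = default_ladder()) {
  if (nrow(outgroups) < 1) stop("ladder is empty", call. = FALSE)
  t <- outgroups$divergence_mya
  if (any(diff(t) <= 0) || any(t <= 0))
    stop("divergence times must be positive and strictly increasing",
         call. = FALSE)
  start <- c(0, t[-length(t)])
  end <- t
  epochs <- data.frame(
    epoch = seq_along(t), start = start, end = end,
    label = sprintf("[%g,%g)", start, end), stringsAsFactors = FALSE)
  structure(list(outgroups = outgroups, epochs = epochs),
            class = "epoch_ladder")
}

#' Date genes by colinearity conservation against the outgroup ladder
#'
#' The deepest (farthest) outgroup for which a gene still shows colinearity
#' conservation bounds its creation epoch: colinear with outgroup i but not
#' with outgroup i+1 places the gene in `[t_i, t_{i+1})`. Colinear with no
#' outgroup means the youngest epoch `[0, t_1)`; colinear with the farthest
#' outgroup means the gene predates the ladder (`pre_ladder`). Non-nested
#' patterns (colinear with a distal outgroup but not a proximal one, e.g.
#' through lineage-specific block loss) are resolved as deepest-outgroup
#' wins.
#'
#' @param colin logical matrix, rows = genes (rownames = gene ids), columns =
#'   ladder outgroups nearest-to-farthest; TRUE where [is_colinear_with()]
#'   holds for that comparison.
#' @param ladder an [epoch_ladder()].
#' @return data.frame(gene, epoch, deepest_colinear_outgroup, start, end);
#'   `epoch` is the 1-based epoch index or NA with
#'   `deepest_colinear_outgroup` = farthest species for pre-ladder genes.
#' @export
assign_epochs <- function(colin, ladder) {
  og <- ladder$outgroups
  if (ncol(colin) != nrow(og))
    stop("colinearity matrix must have one column per ladder outgroup",
         call. = FALSE)
  if (nrow(colin) == 0L)
    return(data.frame(gene = character(0), epoch = integer(0),
                      deepest_colinear_outgroup = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  deepest <- apply(colin, 1L, function(z) {
    w <- which(z)
    if (length(w)) max(w) else 0L
  })
  n_og <- nrow(og)
  epoch <- ifelse(deepest == n_og, NA_integer_, deepest + 1L)
  data.frame(
    gene = rownames(colin),
    epoch = epoch,
    deepest_colinear_outgroup = ifelse(deepest == 0L, NA_character_,
                                       og$species[pmax(deepest, 1L)]),
    start = ifelse(is.na(epoch), og$divergence_mya[n_og],
                   ladder$epochs$start[pmin(epoch, n_og)]),
    end = ifelse(is.na(epoch), Inf, ladder$epochs$end[pmin(epoch, n_og)]),
    stringsAsFactors = FALSE)
}

#' Per-epoch retention rates of dispersed duplicates
#'
#' Retention rate = number of retained dispersed duplicates dated to the
#' epoch divided by the epoch length in My. Pre-ladder genes (NA epoch) are
#' excluded.
#'
#' @param assignments output of [assign_epochs()] restricted to dispersed
#'   duplicates.
#' @param ladder an [epoch_ladder()].
#' @return data.frame(epoch, label, start, end, length_my, count, rate).
#' @export
retention_rates <- function(assignments, ladder) {
  ep <- ladder$epochs
  len <- ep$end - ep$start
  if (any(len <= 0)) stop("zero-length epoch", call. = FALSE)
  cnt <- as.integer(table(factor(assignments$epoch, levels = ep$epoch)))
  data.frame(epoch = ep$epoch, label = ep$label, start = ep$start,
             end = ep$end, length_my = len, count = cnt, rate = cnt / len,
             stringsAsFactors = FALSE)
}

#' Call duplicate origins from modes and epoch dating
#'
#' Non-dispersed genes keep their mode-derived origin (wgd genes carry their
#' event attribution when one exists, e.g. `gamma`). Dispersed genes are
#' split by their epoch interval: inside the `transposed` window they are
#' `transposed`; inside the `relocated` window (defaulting to the span
#' between the 5th and 7th ladder outgroups, i.e. the two epochs between the
#' focal-Populus and focal-Solanum splits on the default ladder) they are
#' `relocated_<event>`; everything else, including the oldest ladder epoch
#' and pre-ladder genes, is `dispersed_other`.
#'
#' @param gene_modes `labels` from [classify_genes()].
#' @param assignments [assign_epochs()] output covering the dispersed genes.
#' @param ladder an [epoch_ladder()].
#' @param relocated_window length-2 Mya vector; epochs contained in it are
#'   called relocated. Default spans outgroups 5..7 of the ladder.
#' @param transposed_window length-2 Mya vector; default `[0, t_2)` (younger
#'   than the second ladder outgroup).
#' @param event event name for the relocated class (default "gamma") and for
#'   wgd genes without an attribution.
#' @return data.frame(gene, origin).
#' @export
call_origins <- function(gene_modes, assignments, ladder,
                         relocated_window = NULL, transposed_window = NULL,
                         event = "gamma") {
  og <- ladder$outgroups$divergence_mya
  if (is.null(relocated_window)) {
    if (length(og) < 7) stop("default relocated window needs >= 7 outgroups; ",
                             "pass relocated_window explicitly", call. = FALSE)
    relocated_window <- c(og[5], og[7])
  }
  if (is.null(transposed_window)) {
    transposed_window <- c(0, og[min(2, length(og))])
  }
  if (max(transposed_window) > min(relocated_window))
    stop("transposed and relocated windows overlap", call. = FALSE)
  origin <- gene_modes$mode
  if (!is.null(gene_modes$event))
    origin <- ifelse(origin == "wgd" & !is.na(gene_modes$event),
                     gene_modes$event, origin)
  origin[origin == "wgd"] <- event
  disp <- which(gene_modes$mode == "dispersed")
  if (length(disp)) {
    m <- match(gene_modes$gene[disp], assignments$gene)
    if (anyNA(m))
      stop("dispersed genes missing from epoch assignments", call. = FALSE)
    s <- assignments$start[m]; e <- assignments$end[m]
    cls <- rep("dispersed_other", length(disp))
    cls[s >= transposed_window[1] & e <= transposed_window[2]] <- "transposed"
    cls[s >= relocated_window[1] & e <= relocated_window[2]] <-
      paste0("relocated_", event)
    origin[disp] <- cls
  }
  data.frame(gene = gene_modes$gene, origin = origin, stringsAsFactors = FALSE)
}

#' Relocated fraction of a polyploidy-born duplicate population
#'
#' `100 * n_relocated / (n_retained + n_relocated)`, reported to one decimal
#' (round half up, matching the reporting convention for these percentages).
#'
#' @param n_retained count of duplicates still at colinear positions.
#' @param n_relocated count of relocated duplicates.
#' @return percentage, one decimal.
#' @export
relocated_fraction <- function(n_retained, n_relocated) {
  if (n_retained < 0 || n_relocated < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (n_retained + n_relocated == 0)
    stop("relocated fraction undefined for two zero counts", call. = FALSE)
  floor(1000 * n_relocated / (n_retained + n_relocated) + 0.5) / 10
}

#' Gamma and relocated-gamma sets for a lineage without recent WGD
#'
#' For a focal lineage with no lineage-specific polyploidy, the
#' polyploidy-born ("gamma") set is estimated as genes in intra-genome
#' colinear blocks that also have colinear homologs in at least one outgroup
#' (excluding recent segmental duplicates); the relocated set is the
#' dispersed duplicates colinear with at least one designated mid-ladder
#' outgroup but with none of the designated distal outgroups.
#'
#' @param intra_genes genes in intra-genome colinear blocks (character).
#' @param colin logical gene-by-outgroup colinearity matrix (rownames = gene
#'   ids) covering all columns named below.
#' @param dispersed_genes genes classified dispersed.
#' @param mid_outgroups outgroup names whose colinearity qualifies a
#'   dispersed gene as relocated.
#' @param distal_outgroups outgroup names whose colinearity disqualifies it.
#' @return list(gamma = character, relocated = character).
#' @export
gamma_set_no_recent_wgd <- function(intra_genes, colin, dispersed_genes,
                                    mid_outgroups, distal_outgroups) {
  need <- c(mid_outgroups, distal_outgroups)
  if (!all(need %in% colnames(colin)))
    stop("designated outgroups absent from the colinearity matrix: ",
         paste(setdiff(need, colnames(colin)), collapse = ", "),
         call. = FALSE)
  any_out <- rownames(colin)[rowSums(colin) > 0]
  gamma <- intersect(intra_genes, any_out)
  disp <- intersect(dispersed_genes, rownames(colin))
  mid_ok <- rowSums(colin[disp, mid_outgroups, drop = FALSE]) > 0
  distal_no <- rowSums(colin[disp, distal_outgroups, drop = FALSE]) == 0
  list(gamma = gamma, relocated = disp[mid_ok & distal_no])
}
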