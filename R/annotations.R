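#' Configuration for the synthetic annotation generator
#'
#' Controls per-origin-class enrichment of GO membership, essentiality and
#' PPI participation, the Brownian-motion rate of expression-profile
#' divergence, and the promoter-motif gain/loss rates (which make PWM-set
#' overlap decay with pair age).
#'
#' @param n_conditions expression conditions per profile.
#' @param expr_bm_var Brownian-motion variance of expression per My.
#' @param n_motifs motif universe size.
#' @param pwm_gain,pwm_loss per-My per-motif gain/loss rates (stationary
#'   presence = gain / (gain + loss)).
#' @param essential_base baseline essentiality probability.
#' @param essential_mult named per-class multipliers (>= 0).
#' @param essential_screened_frac fraction of genes covered by the knockout
#'   screen.
#' @param ppi_base baseline probability that a screened gene participates in
#'   an interaction.
#' @param ppi_mult named per-class multipliers (>= 0).
#' @param ppi_screened_frac fraction of genes in the interactome's screened
#'   population.
#' @param go_bp_large_p membership probabilities of the large
#'   biological-process terms.
#' @param go_bp_small_p,go_mf_p membership probabilities of small BP terms
#'   and of molecular-function terms.
#' @param go_bias_wgd,go_bias_single per-term multiplier profiles (length of
#'   `go_bp_large_p`) applied to polyploidy-derived and single-gene classes.
#' @return list of class `ann_config`.
#' @export
ann_config <- function(n_conditions = 20L,
                       expr_bm_var = 0.012,
                       n_motifs = 50L,
                       pwm_gain = 0.002, pwm_loss = 0.008,
                       essential_base = 0.12,
                       essential_mult = c(gamma = 1.1, relocated_gamma = 2.5,
                                          tandem = 0.5, proximal = 0.5,
                                          transposed = 0.4, ancestral = 1.0),
                       essential_screened_frac = 0.35,
                       ppi_base = 0.3,
                       ppi_mult = c(gamma = 1.3, relocated_gamma = 1.0,
                                    tandem = 0.6, proximal = 0.6,
                                    transposed = 0.5, ancestral = 1.0),
                       ppi_screened_frac = 0.6,
                       go_bp_large_p = seq(0.08, 0.36, length.out = 29),
                       go_bp_small_p = rep(0.01, 6),
                       go_mf_p = rep(0.05, 10),
                       go_bias_wgd = c(rep(1.6, 10), rep(1, 9), rep(0.5, 10)),
                       go_bias_single = c(rep(0.5, 10), rep(1, 9),
                                          rep(1.6, 10))) {
  cfg <- as.list(environment())
  if (any(c(cfg$essential_mult, cfg$ppi_mult,
            cfg$go_bias_wgd, cfg$go_bias_single) < 0))
    stop("enrichment multipliers must be >= 0", call. = FALSE)
  if (length(go_bias_wgd) != length(go_bp_large_p) ||
      length(go_bias_single) != length(go_bp_large_p))
    stop("GO bias profiles must match the number of large BP terms",
         call. = FALSE)
  class(cfg) <- "ann_config"
  cfg
}

#' Generate synthetic gene annotations for the focal genome
#'
#' GO membership, essentiality and PPI participation are drawn per gene with
#' per-origin-class multipliers on the baseline probabilities; expression
#' profiles evolve by Brownian motion along the simulated genealogy (so
#' expression correlation decays with pair age); promoter PWM hit sets evolve
#' by per-motif gain/loss toggling along the genealogy (so Jaccard overlap
#' decays with pair age; age-0 pairs have identical sets).
#'
#' @param sim a `sim_result`.
#' @param config an [ann_config()].
#' @param seed RNG seed.
#' @return list of class `annotation_bundle`: `go` (gene, term),
#'   `namespaces` (term, namespace), `essential` (gene, screened, phenotype),
#'   `ppi_edges` (gene_a, gene_b), `ppi_screened` (character),
#'   `expression` (genes x conditions matrix), `pwm_hits` (gene, pwm_id).
#' @export
generate_annotations <- function(sim, config = ann_config(), seed = 1L) {
  set.seed(seed)
  truth <- truth_table(sim)
  genes <- truth$gene
  cls <- truth$truth_origin
  n <- length(genes)

  mult_of <- function(mult, cls) {
    m <- mult[cls]
    m[is.na(m)] <- 1
    unname(m)
  }

  # GO terms
  p_large <- config$go_bp_large_p
  n_large <- length(p_large)
  bias <- matrix(1, n, n_large)
  wgd_like <- cls %in% c("gamma", "relocated_gamma", "alpha", "beta")
  single <- cls %in% c("tandem", "proximal", "transposed")
  if (any(wgd_like))
    bias[wgd_like, ] <- matrix(config$go_bias_wgd, sum(wgd_like), n_large,
                               byrow = TRUE)
  if (any(single))
    bias[single, ] <- matrix(config$go_bias_single, sum(single), n_large,
                             byrow = TRUE)
  terms_large <- sprintf("GO:BP%04d", seq_len(n_large))
  terms_small <- sprintf("GO:BPS%03d", seq_along(config$go_bp_small_p))
  terms_mf <- sprintf("GO:MF%04d", seq_along(config$go_mf_p))
  go <- list()
  add_term <- function(hit, term) {
    go[[length(go) + 1L]] <<- data.frame(
      gene = genes[hit], term = rep(term, sum(hit)), stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_large))
    add_term(stats::runif(n) < pmin(p_large[j] * bias[, j], 1),
             terms_large[j])
  for (j in seq_along(terms_small))
    add_term(stats::runif(n) < config$go_bp_small_p[j], terms_small[j])
  for (j in seq_along(terms_mf))
    add_term(stats::runif(n) < config$go_mf_p[j], terms_mf[j])
  go <- do.call(rbind, go)
  namespaces <- data.frame(
    term = c(terms_large, terms_small, terms_mf),
    namespace = c(rep("BP", n_large + length(terms_small)),
                  rep("MF", length(terms_mf))),
    stringsAsFactors = FALSE)

  # essentiality (phenotype on knockout), on a screened subset
  screened_ess <- stats::runif(n) < config$essential_screened_frac
  p_ess <- pmin(config$essential_base * mult_of(config$essential_mult, cls), 1)
  phenotype <- ifelse(screened_ess, as.integer(stats::runif(n) < p_ess),
                      NA_integer_)
  essential <- data.frame(gene = genes, screened = screened_ess,
                          phenotype = phenotype, stringsAsFactors = FALSE)

  # PPI participation on the interactome's screened population
  in_screen <- stats::runif(n) < config$ppi_screened_frac
  p_ppi <- pmin(config$ppi_base * mult_of(config$ppi_mult, cls), 1)
  participates <- in_screen & stats::runif(n) < p_ppi
  participants <- genes[participates]
  n_edges <- max(0L, as.integer(round(1.05 * length(participants))))
  ppi_edges <- if (length(participants) >= 2 && n_edges > 0) {
    ea <- sample(participants, n_edges, replace = TRUE)
    eb <- sample(participants, n_edges, replace = TRUE)
    keep <- ea != eb
    unique(data.frame(gene_a = pmin(ea[keep], eb[keep]),
                      gene_b = pmax(ea[keep], eb[keep]),
                      stringsAsFactors = FALSE))
  } else data.frame(gene_a = character(0), gene_b = character(0),
                    stringsAsFactors = FALSE)
  # every participant appears in at least one edge
  missing <- setdiff(participants, c(ppi_edges$gene_a, ppi_edges$gene_b))
  if (length(missing) && length(participants) >= 2) {
    partner <- vapply(missing, function(g)
      sample(setdiff(participants, g), 1L), character(1))
    ppi_edges <- unique(rbind(ppi_edges, data.frame(
      gene_a = pmin(missing, partner), gene_b = pmax(missing, partner),
      stringsAsFactors = FALSE)))
  }

  # expression: Brownian motion along the genealogy
  C <- config$n_conditions
  sd1 <- sqrt(config$expr_bm_var)
  expr_vals <- evolve_genealogy(
    sim, genes,
    init_fn = function() stats::rnorm(C),
    step_fn = function(v, dt) v + stats::rnorm(C, 0, sd1 * sqrt(dt)))
  expression <- do.call(rbind, expr_vals)
  rownames(expression) <- genes
  colnames(expression) <- sprintf("cond%02d", seq_len(C))

  # PWM hit sets: per-motif gain/loss toggling along the genealogy
  M <- config$n_motifs
  stat_p <- config$pwm_gain / (config$pwm_gain + config$pwm_loss)
  toggle <- function(v, dt) {
    p_on <- ifelse(v, exp(-config$pwm_loss * dt),
                   1 - exp(-config$pwm_gain * dt))
    stats::runif(M) < p_on
  }
  pwm_vals <- evolve_genealogy(
    sim, genes,
    init_fn = function() stats::runif(M) < stat_p,
    step_fn = toggle)
  motif_ids <- sprintf("PWM%03d", seq_len(M))
  pwm_hits <- data.frame(
    gene = rep(genes, vapply(pwm_vals, sum, integer(1))),
    pwm_id = unlist(lapply(pwm_vals, function(v) motif_ids[v]),
                    use.names = FALSE),
    stringsAsFactors = FALSE)

  structure(list(go = go, namespaces = namespaces, essential = essential,
                 ppi_edges = ppi_edges,
                 ppi_screened = genes[in_screen],
                 expression = expression, pwm_hits = pwm_hits,
                 config = config),
            class = "annotation_bundle")
}

# Evolve a per-lineage state down the genealogy restricted to the ancestors
# of `leaf_genes`. A parent lineage persists alongside its children, so the
# parent state is advanced to each child's birth time before being copied.
evolve_genealogy <- function(sim, leaf_genes, init_fn, step_fn) {
  nodes <- sim$nodes
  leaves <- gene_to_id(leaf_genes)
  relevant <- logical(nrow(nodes))
  for (id in leaves) {
    while (id > 0L && !relevant[id]) {
      relevant[id] <- TRUE
      id <- nodes$parent[id]
    }
  }
  ids <- which(relevant)
  ids <- ids[order(-nodes$time[ids], ids)]
  values <- vector("list", nrow(nodes))
  last_t <- numeric(nrow(nodes))
  for (id in ids) {
    p <- nodes$parent[id]
    t <- nodes$time[id]
    if (p == 0L || !relevant[p]) {
      values[[id]] <- init_fn()
    } else {
      dt <- last_t[p] - t
      if (dt > 0) values[[p]] <- step_fn(values[[p]], dt)
      last_t[p] <- t
      values[[id]] <- values[[p]]
    }
    last_t[id] <- t
  }
  out <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    id <- leaves[i]
    v <- values[[id]]
    if (last_t[id] > 0) v <- step_fn(v, last_t[id])
    out[[i]] <- v
  }
  names(out) <- leaf_genes
  out
}
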