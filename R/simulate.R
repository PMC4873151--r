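#' Forward-in-time simulation of gene-order evolution
#'
#' Simulates a focal genome and an ordered set of outgroups descending from a
#' common ancestor along a ladder tree. Supported events: whole-genome
#' duplication / triplication on the shared stem (new subgenome copies are
#' placed on newly created chromosomes preserving ancestral order), per-gene
#' loss (the rank gap closes, i.e. fractionation), per-gene relocation to a
#' uniformly chosen position of the same genome (with a burst window at an
#' elevated rate), and tandem / proximal / transposed single-gene
#' duplications. Every copy carries its genealogy, so clock-scaled Ks can be
#' computed for any homolog pair, and every focal gene carries a ground-truth
#' origin label.
#'
#' A polyploidy event is inherited by every outgroup whose divergence time is
#' less than or equal to the event time. At such an event all pre-existing
#' genes are relabelled with the event's class (they become members of the
#' polyploidy-born duplicate population) and their relocation history is
#' reset.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_result` with elements `config`, `nodes`
#'   (genealogy table), `genomes` (per species, a named list of chromosome
#'   gene-id vectors), `event_log`, and `focal`.
#' @export
simulate_genomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n0 <- config$n_ancestral_genes
  reg <- new_node_registry(max(4096L, 8L * n0))
  root_age <- max(config$outgroups$divergence_mya)
  root_ids <- reg_new_nodes(reg, parent = rep(0L, n0), time = root_age,
                            family = seq_len(n0), origin_class = "ancestral")
  sizes <- rep(n0 %/% config$n_chromosomes, config$n_chromosomes)
  rem <- n0 %% config$n_chromosomes
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  chr <- split(root_ids, rep(seq_along(sizes), sizes))
  names(chr) <- NULL
  elog <- new_event_log()

  ev <- config$events
  sched <- data.frame(
    time = c(if (nrow(ev)) ev$time else numeric(0),
             config$outgroups$divergence_mya),
    type = c(rep("event", nrow(ev)), rep("speciation", nrow(config$outgroups))),
    kind = c(if (nrow(ev)) ev$kind else character(0),
             rep(NA_character_, nrow(config$outgroups))),
    label = c(if (nrow(ev)) {
      if (is.null(ev$label)) ev$kind else ev$label
    } else character(0), rep(NA_character_, nrow(config$outgroups))),
    species = c(rep(NA_character_, nrow(ev)), config$outgroups$species),
    stringsAsFactors = FALSE
  )
  # chronological (Mya descending); polyploidy before a co-timed split so the
  # splitting outgroup inherits it
  sched <- sched[order(-sched$time, sched$type != "event"), , drop = FALSE]

  spine <- chr
  gamma_times <- numeric(0)
  t_cur <- root_age
  genomes <- list()

  for (i in seq_len(nrow(sched))) {
    row <- sched[i, ]
    spine <- evolve_lineage(spine, t_cur, row$time, config, gamma_times,
                            reg, elog, config$focal)
    t_cur <- row$time
    if (row$type == "speciation") {
      branch <- clone_genome(spine, t_cur, reg)
      log_event(elog, t_cur, row$species, "speciation", 0L,
                sum(lengths(branch)))
      branch <- evolve_lineage(branch, t_cur, 0, config, gamma_times,
                               reg, elog, row$species)
      check_alive(branch, row$species, elog)
      genomes[[row$species]] <- branch
    } else {
      spine <- apply_polyploidy(spine, t_cur, row$kind, row$label, reg, elog,
                                config$focal)
      gamma_times <- c(gamma_times, t_cur)
    }
  }
  spine <- evolve_lineage(spine, t_cur, 0, config, gamma_times, reg, elog,
                          config$focal)
  check_alive(spine, config$focal, elog)
  genomes[[config$focal]] <- spine

  nodes <- data.frame(
    id = seq_len(reg$n),
    parent = reg$parent[seq_len(reg$n)],
    time = reg$time[seq_len(reg$n)],
    family = reg$family[seq_len(reg$n)],
    origin_class = reg$origin_class[seq_len(reg$n)],
    origin_time = reg$origin_time[seq_len(reg$n)],
    reloc_time = reg$reloc_time[seq_len(reg$n)],
    reloc_count = reg$reloc_count[seq_len(reg$n)],
    stringsAsFactors = FALSE
  )
  genomes <- lapply(genomes, function(g) {
    g <- lapply(g, id_to_gene)
    names(g) <- sprintf("chr%02d", seq_along(g))
    g
  })
  res <- list(config = config, nodes = nodes, genomes = genomes,
              event_log = finish_event_log(elog), focal = config$focal)
  class(res) <- "sim_result"
  res
}

check_alive <- function(genome, species, elog) {
  if (sum(lengths(genome)) == 0L) {
    cond <- structure(
      class = c("dupSimError", "error", "condition"),
      list(message = paste0("all genes lost in lineage ", species),
           call = NULL, event_log = finish_event_log(elog)))
    stop(cond)
  }
}

clone_genome <- function(chr, time, reg) {
  lapply(chr, function(v) {
    if (length(v) == 0L) return(integer(0))
    reg_new_nodes(reg, parent = v, time = time,
                  family = reg$family[v],
                  origin_class = reg$origin_class[v],
                  origin_time = reg$origin_time[v])
  })
}

apply_polyploidy <- function(chr, time, kind, label, reg, elog, lineage) {
  n_extra <- if (kind == "triplication") 2L else 1L
  ids <- unlist(chr, use.names = FALSE)
  # pre-existing genes join the polyploidy-born duplicate population
  reg$origin_class[ids] <- label
  reg$origin_time[ids] <- time
  reg$reloc_time[ids] <- NA_real_
  new_chr <- chr
  for (k in seq_len(n_extra)) {
    copies <- lapply(chr, function(v) {
      if (length(v) == 0L) return(integer(0))
      reg_new_nodes(reg, parent = v, time = time, family = reg$family[v],
                    origin_class = label)
    })
    new_chr <- c(new_chr, copies)
  }
  log_event(elog, time, lineage, kind, 0L, n_extra * length(ids))
  new_chr
}

# --- event log ---------------------------------------------------------------

new_event_log <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$time <- numeric(1024L); e$lineage <- character(1024L)
  e$kind <- character(1024L); e$gene <- integer(1024L)
  e$n_change <- integer(1024L)
  e
}

log_event <- function(e, time, lineage, kind, gene, n_change) {
  e$n <- e$n + 1L
  if (e$n > length(e$time)) {
    grow <- function(v) c(v, v)
    e$time <- grow(e$time); e$lineage <- grow(e$lineage)
    e$kind <- grow(e$kind); e$gene <- grow(e$gene)
    e$n_change <- grow(e$n_change)
  }
  i <- e$n
  e$time[i] <- time; e$lineage[i] <- lineage; e$kind[i] <- kind
  e$gene[i] <- gene; e$n_change[i] <- n_change
}

finish_event_log <- function(e) {
  i <- seq_len(e$n)
  data.frame(time = e$time[i], lineage = e$lineage[i], kind = e$kind[i],
             gene = ifelse(e$gene[i] > 0L, id_to_gene(e$gene[i]), NA),
             n_change = e$n_change[i], stringsAsFactors = FALSE)
}

# --- per-branch evolution ----------------------------------------------------

in_window <- function(t, w) length(w) == 2 && t <= w[2] && t >= w[1]

evolve_lineage <- function(chr, t_from, t_to, cfg, gamma_times, reg, elog,
                           lineage) {
  if (t_from <= t_to) return(chr)
  r <- cfg$rates
  bounds <- c(t_from, t_to)
  if (!is.null(r$relocation_burst)) bounds <- c(bounds, r$relocation_burst)
  for (g in gamma_times)
    bounds <- c(bounds, g, g - r$loss_postpoly_span)
  bounds <- sort(unique(pmin(pmax(bounds, t_to), t_from)), decreasing = TRUE)
  for (s in seq_len(length(bounds) - 1L)) {
    hi <- bounds[s]; lo <- bounds[s + 1L]
    if (hi <= lo) next
    mid <- (hi + lo) / 2
    loss_mult <- if (any(vapply(gamma_times, function(g)
      mid <= g && mid >= g - r$loss_postpoly_span, logical(1)))) {
      r$loss_postpoly_mult %||% 1
    } else 1
    rel_mult <- if (!is.null(r$relocation_burst) &&
                    in_window(mid, r$relocation_burst)) {
      r$relocation_burst_mult %||% 1
    } else 1
    rates <- c(loss = r$loss * loss_mult,
               relocation = r$relocation * rel_mult,
               tandem = r$tandem, proximal = r$proximal,
               transposed = r$transposed)
    chr <- gillespie_segment(chr, hi, lo, rates, cfg, reg, elog, lineage)
  }
  chr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gillespie_segment <- function(chr, hi, lo, rates, cfg, reg, elog, lineage) {
  per_gene <- sum(rates)
  if (per_gene <= 0) return(chr)
  t <- hi
  repeat {
    n <- sum(lengths(chr))
    if (n == 0L) break
    t <- t - stats::rexp(1L, rate = n * per_gene)
    if (t <= lo) break
    kind <- sample(names(rates), 1L, prob = rates)
    chr <- apply_gene_event(chr, kind, t, cfg, reg, elog, lineage)
  }
  chr
}

locate_gene <- function(chr, k) {
  cum <- cumsum(lengths(chr))
  ci <- which(k <= cum)[1L]
  pos <- k - if (ci > 1L) cum[ci - 1L] else 0L
  c(ci, pos)
}

sample_slot <- function(chr) {
  lens <- lengths(chr)
  s <- sample.int(sum(lens + 1L), 1L)
  cum <- cumsum(lens + 1L)
  ci <- which(s <= cum)[1L]
  slot <- s - if (ci > 1L) cum[ci - 1L] else 0L
  c(ci, slot)  # insert before position `slot` (1..len+1)
}

apply_gene_event <- function(chr, kind, t, cfg, reg, elog, lineage) {
  n <- sum(lengths(chr))
  k <- sample.int(n, 1L)
  lp <- locate_gene(chr, k)
  ci <- lp[1L]; pos <- lp[2L]
  id <- chr[[ci]][pos]
  if (kind == "loss") {
    chr[[ci]] <- chr[[ci]][-pos]
    log_event(elog, t, lineage, "loss", id, -1L)
  } else if (kind == "relocation") {
    chr[[ci]] <- chr[[ci]][-pos]
    sl <- sample_slot(chr)
    chr[[sl[1L]]] <- append(chr[[sl[1L]]], id, after = sl[2L] - 1L)
    reg$reloc_time[id] <- t
    reg$reloc_count[id] <- reg$reloc_count[id] + 1L
    log_event(elog, t, lineage, "relocation", id, 0L)
  } else if (kind == "tandem") {
    new <- reg_new_nodes(reg, id, t, reg$family[id], "tandem")
    chr[[ci]] <- append(chr[[ci]], new, after = pos)
    log_event(elog, t, lineage, "tandem", new, 1L)
  } else if (kind == "proximal") {
    new <- reg_new_nodes(reg, id, t, reg$family[id], "proximal")
    offset <- sample(2:cfg$local_window, 1L)
    len <- length(chr[[ci]])
    after <- if (pos + offset <= len + 1L) pos + offset - 1L
             else max(pos - offset, 0L)
    chr[[ci]] <- append(chr[[ci]], new, after = after)
    log_event(elog, t, lineage, "proximal", new, 1L)
  } else { # transposed
    new <- reg_new_nodes(reg, id, t, reg$family[id], "transposed")
    sl <- sample_slot(chr)
    chr[[sl[1L]]] <- append(chr[[sl[1L]]], new, after = sl[2L] - 1L)
    log_event(elog, t, lineage, "transposed", new, 1L)
  }
  chr
}

# --- accessors ---------------------------------------------------------------

#' Gene positions of one simulated species
#'
#' @param sim a `sim_result`.
#' @param species species name; defaults to the focal species.
#' @return data.frame(gene, chrom, rank) with 0-based ranks.
#' @export
genome_layout <- function(sim, species = sim$focal) {
  g <- sim$genomes[[species]]
  if (is.null(g)) stop("unknown species: ", species, call. = FALSE)
  data.frame(
    gene = unlist(g, use.names = FALSE),
    chrom = rep(names(g), lengths(g)),
    rank = unlist(lapply(g, function(v) seq_along(v) - 1L), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth origin labels of the focal genome
#'
#' A polyploidy-born gene relocated inside the configured burst window is the
#' truth class `relocated_<event label>` (e.g. `relocated_gamma`); a
#' polyploidy-born gene relocated outside the window keeps its event class
#' and is flagged `relocated`. Single-gene duplicates carry their birth kind.
#' Genes never duplicated are labelled `ancestral`.
#'
#' @param sim a `sim_result`.
#' @return data.frame(gene, family, origin_class, origin_time, reloc_time,
#'   relocated, truth_origin).
#' @export
truth_table <- function(sim) {
  lay <- genome_layout(sim)
  ids <- gene_to_id(lay$gene)
  nd <- sim$nodes[ids, ]
  burst <- sim$config$rates$relocation_burst
  labels <- unique(if (nrow(sim$config$events)) {
    if (is.null(sim$config$events$label)) sim$config$events$kind
    else sim$config$events$label
  } else character(0))
  origin <- nd$origin_class
  relocated <- !is.na(nd$reloc_time)
  truth <- origin
  in_burst <- if (is.null(burst)) rep(FALSE, nrow(nd)) else
    relocated & nd$reloc_time >= burst[1] & nd$reloc_time <= burst[2]
  sel <- origin %in% labels & in_burst
  truth[sel] <- paste0("relocated_", origin[sel])
  data.frame(gene = lay$gene, family = nd$family, origin_class = origin,
             origin_time = nd$origin_time, reloc_time = nd$reloc_time,
             reloc_count = nd$reloc_count, relocated = relocated,
             truth_origin = truth, stringsAsFactors = FALSE)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", length(x$genomes), "genomes;",
      nrow(x$nodes), "genealogy nodes;",
      nrow(x$event_log), "logged events\n")
  for (sp in names(x$genomes))
    cat(sprintf("  %-4s %5d genes on %d chromosomes\n", sp,
                sum(lengths(x$genomes[[sp]])), length(x$genomes[[sp]])))
  invisible(x)
}
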