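# Gene genealogy registry.
#
# Every gene copy ever created is a node with a parent pointer and a creation
# time (Mya). A parent lineage continues to exist alongside its children
# ("continuation" semantics), so the divergence time of two copies is the
# maximum creation time of the first node after their most recent common
# ancestor on each of the two paths.

new_node_registry <- function(n_init = 4096L) {
  reg <- new.env(parent = emptyenv())
  reg$n <- 0L
  reg$parent <- integer(n_init)
  reg$time <- numeric(n_init)
  reg$family <- integer(n_init)
  reg$origin_class <- character(n_init)
  reg$origin_time <- numeric(n_init)
  reg$reloc_time <- rep(NA_real_, n_init)
  reg$reloc_count <- integer(n_init)
  reg
}

reg_grow <- function(reg, need) {
  cap <- length(reg$parent)
  if (need <= cap) return(invisible(reg))
  new_cap <- cap
  while (new_cap < need) new_cap <- new_cap * 2L
  extra <- new_cap - cap
  reg$parent <- c(reg$parent, integer(extra))
  reg$time <- c(reg$time, numeric(extra))
  reg$family <- c(reg$family, integer(extra))
  reg$origin_class <- c(reg$origin_class, character(extra))
  reg$origin_time <- c(reg$origin_time, numeric(extra))
  reg$reloc_time <- c(reg$reloc_time, rep(NA_real_, extra))
  reg$reloc_count <- c(reg$reloc_count, integer(extra))
  invisible(reg)
}

reg_new_nodes <- function(reg, parent, time, family, origin_class,
                          origin_time = time) {
  k <- length(parent)
  ids <- reg$n + seq_len(k)
  reg_grow(reg, reg$n + k)
  reg$parent[ids] <- parent
  reg$time[ids] <- time
  reg$family[ids] <- family
  reg$origin_class[ids] <- origin_class
  reg$origin_time[ids] <- origin_time
  reg$reloc_time[ids] <- NA_real_
  reg$reloc_count[ids] <- 0L
  reg$n <- reg$n + k
  ids
}

node_path <- function(parent, id) {
  path <- integer(32L)
  i <- 0L
  while (id > 0L) {
    i <- i + 1L
    if (i > length(path)) path <- c(path, integer(length(path)))
    path[i] <- id
    id <- parent[id]
  }
  path[seq_len(i)]
}

# Divergence time (Mya) of two copies a, b (internal integer node ids).
node_divergence_one <- function(parent, time, a, b) {
  if (a == b) return(0)
  pa <- node_path(parent, a)
  # climb from b until we hit an ancestor of a
  prev <- 0L
  cur <- b
  m <- match(cur, pa)
  while (is.na(m)) {
    prev <- cur
    cur <- parent[cur]
    if (cur == 0L)
      stop("nodes share no common ancestor (different families?)")
    m <- match(cur, pa)
  }
  cand <- numeric(0)
  if (m > 1L) cand <- time[pa[m - 1L]]     # first node below MRCA on a's path
  if (prev > 0L) cand <- c(cand, time[prev]) # same on b's path
  max(cand)
}

#' Divergence times of gene-copy pairs
#'
#' Time (Mya) at which the lineages of two gene copies separated, read off
#' the simulated genealogy. Both genes must belong to the same family.
#'
#' @param sim a `sim_result`.
#' @param gene_a,gene_b character vectors of gene ids (recycled pairwise).
#' @return numeric vector of divergence times in Mya.
#' @export
pair_divergence <- function(sim, gene_a, gene_b) {
  a <- gene_to_id(gene_a)
  b <- gene_to_id(gene_b)
  parent <- sim$nodes$parent
  time <- sim$nodes$time
  vapply(seq_along(a), function(i)
    node_divergence_one(parent, time, a[i], b[i]), numeric(1))
}

gene_to_id <- function(gene) as.integer(sub("^g", "", gene))
id_to_gene <- function(id) sprintf("g%07d", id)
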