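# Independent oracles used against the package implementations.

# Exhaustive best-chain score via boolean reachability in the anchor DAG:
# chains of k+1 anchors exist iff the k-th boolean power of the valid-step
# adjacency matrix is nonzero. Applies the same shared-rank collapse the
# chainer documents, re-implemented from the contract.
oracle_chain_score <- function(rank_a, rank_b, max_gap) {
  # contract: reciprocal best per rank on both axes (unit scores, ties to
  # the smaller opposite rank), re-derived here by explicit per-group loops
  n0 <- length(rank_a)
  keep <- vapply(seq_len(n0), function(i) {
    ga <- which(rank_a == rank_a[i])
    gb <- which(rank_b == rank_b[i])
    rank_b[i] == min(rank_b[ga]) && rank_a[i] == min(rank_a[gb])
  }, logical(1))
  rank_a <- rank_a[keep]; rank_b <- rank_b[keep]
  n <- length(rank_a)
  if (n == 0L) return(0L)
  best <- 1L
  for (sgn in c(1, -1)) {
    rb <- sgn * rank_b
    A <- outer(rank_a, rank_a, function(x, y) y - x) # step a-gap
    B <- outer(rb, rb, function(x, y) y - x)
    ok <- A >= 1 & A <= max_gap & B >= 1 & B <= max_gap
    M <- ok
    k <- 1L
    while (any(M)) {
      k <- k + 1L
      M <- (M %*% ok) > 0
    }
    best <- max(best, k)
  }
  best
}

random_anchor_instance <- function(n = 20L, grid = 100L) {
  cells <- sample.int(grid * grid, n)
  ra <- (cells - 1L) %% grid
  rb <- (cells - 1L) %/% grid
  data.frame(gene_a = sprintf("a%03d", seq_len(n)),
             gene_b = sprintf("b%03d", seq_len(n)),
             chrom_a = "A1", chrom_b = "B1",
             rank_a = ra, rank_b = rb, score = 1,
             stringsAsFactors = FALSE)
}

# two-sided Fisher p by full hypergeometric enumeration over tables with
# fixed margins
oracle_fisher_p <- function(k, n_class, n_trait, n_bg) {
  lo <- max(0L, n_class + n_trait - n_bg)
  hi <- min(n_class, n_trait)
  probs <- stats::dhyper(lo:hi, n_trait, n_bg - n_trait, n_class)
  p_obs <- stats::dhyper(k, n_trait, n_bg - n_trait, n_class)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# permutation two-sided p for a difference in means
oracle_permutation_p <- function(a, b, n_perm = 4000L) {
  obs <- abs(mean(a) - mean(b))
  z <- c(a, b)
  na <- length(a)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(z), na)
    d <- abs(mean(z[idx]) - mean(z[-idx]))
    if (d >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / n_perm
}

# average-linkage merge heights computed naively from a distance matrix
oracle_average_linkage <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    bestv <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      v <- mean(d[clusters[[i]], clusters[[j]]])
      if (v < bestv) { bestv <- v; bi <- i; bj <- j }
    }
    heights <- c(heights, bestv)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# naive per-offset, both-strand PWM scorer
oracle_best_pwm_score <- function(sequence, pwm) {
  lo <- log2(pmax(pwm, 1e-9) / 0.25)
  score_one <- function(s) {
    ss <- strsplit(s, "")[[1]]
    L <- ncol(lo)
    if (length(ss) < L) return(-Inf)
    best <- -Inf
    for (off in 0:(length(ss) - L)) {
      sc <- 0
      ok <- TRUE
      for (j in seq_len(L)) {
        r <- match(ss[off + j], c("A", "C", "G", "T"))
        if (is.na(r)) { ok <- FALSE; break }
        sc <- sc + lo[r, j]
      }
      if (ok && sc > best) best <- sc
    }
    best
  }
  revcomp <- function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  max(score_one(sequence), score_one(revcomp(sequence)))
}
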