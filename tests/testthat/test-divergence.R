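test_that("Ks histograms bin and cap as specified", {
  d <- ks_distribution(0.1 * (1:10), bin_width = 0.5, cap = 3)
  expect_equal(d$counts[1:2], c(5L, 5L))
  expect_equal(sum(d$counts), 10L)
  expect_equal(d$n_excluded, 0L)
  expect_warning(d2 <- ks_distribution(c(4, 5, 6), cap = 3), "empty")
  expect_equal(d2$n_excluded, 3L)
  expect_null(d2$density)
  d3 <- ks_distribution(c(0.5, 1, 3.5), cap = 3)
  expect_equal(d3$n_excluded, 1L)
  expect_error(ks_distribution(1, cap = 0), "cap")
})

test_that("a constant-rate single-gene duplication process gives an L-shaped Ks distribution", {
  set.seed(21)
  # constant birth rate + constant loss: surviving ages are exponential
  mu <- 0.0076
  birth <- runif(20000, 0, 148)
  surv <- rbinom(20000, 1, exp(-0.02 * birth)) == 1
  ks <- 2 * mu * birth[surv] * exp(rnorm(sum(surv), 0, 0.15))
  d <- ks_distribution(ks, cap = 3)
  expect_null(detect_secondary_peak(d))
  expect_lt(d$density$x[which.max(d$density$y)], 0.3)
})

test_that("secondary-peak detection finds planted mixture peaks and nothing else", {
  set.seed(31)
  n <- 5000
  ks <- c(rexp(round(0.75 * n), 1), rnorm(round(0.25 * n), 2, 0.2))
  d <- ks_distribution(ks[ks >= 0], cap = 3)
  pk <- detect_secondary_peak(d)
  expect_false(is.null(pk))
  expect_gt(pk$location, 1.5)
  expect_lt(pk$location, 2.2)
  expect_lt(abs(pk$location - 2), d$density$bw * 2)
  # same mixture but bump at 0.5: out of the search range
  ks2 <- c(rexp(3000, 1), rnorm(1500, 0.5, 0.1))
  expect_null(detect_secondary_peak(ks_distribution(ks2[ks2 >= 0], cap = 3)))
  expect_error(detect_secondary_peak(d, search_range = c(2, 1)), "lo < hi")
})

test_that("group comparisons agree with a permutation oracle", {
  x <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(x$t, 0)
  expect_equal(x$p, 1)
  expect_error(compare_groups(c(1, 1), c(1, 2)), "degenerate")
  tiny <- compare_groups(c(1, 2), c(5, 9))
  expect_true(is.finite(tiny$p))
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(40, 0, 1)
    b <- rnorm(40, 0.4, 1)
    w <- compare_groups(a, b)$p
    p_perm <- oracle_permutation_p(a, b, 4000)
    mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
    expect_lt(abs(w - p_perm), 4 * mc_se + 0.02)
  }
})

test_that("expression divergence is 1 - Pearson r with its boundary cases", {
  a <- c(1, 2, 3, 4)
  expect_equal(expression_divergence(a, a), 0)
  expect_equal(expression_divergence(a, -a), 2)
  b <- c(1, 2, 3, 5)
  expect_equal(expression_divergence(a, b), 1 - cor(a, b))
  expect_equal(expression_divergence(a, b),
               1 - sum(scale(a) * scale(b)) / 3, tolerance = 1e-12)
  expect_warning(v <- expression_divergence(a, c(1, 1, 1, 1)), "zero-variance")
  expect_true(is.na(v))
  expect_error(expression_divergence(1:3, 1:4), "length")
  # symmetry, bounds, affine invariance on random profiles
  set.seed(51)
  for (i in 1:300) {
    x <- rnorm(10); y <- rnorm(10)
    d <- expression_divergence(x, y)
    expect_gte(d, 0); expect_lte(d, 2)
    expect_equal(d, expression_divergence(y, x))
    expect_equal(d, expression_divergence(2.5 * x + 3, y), tolerance = 1e-9)
  }
})

test_that("regulation divergence is the Jaccard distance", {
  expect_equal(regulation_divergence(c("m1", "m2"), c("m1", "m2")), 0)
  expect_equal(regulation_divergence(c("m1"), c("m2")), 1)
  expect_equal(regulation_divergence(c("m1", "m2", "m3"),
                                     c("m2", "m3", "m4")), 0.5)
  expect_warning(v <- regulation_divergence(character(0), character(0)),
                 "empty")
  expect_true(is.na(v))
  # metric axioms on random sets
  set.seed(61)
  universe <- sprintf("p%02d", 1:20)
  for (i in 1:500) {
    s <- lapply(1:3, function(k) sample(universe, rbinom(1, 20, 0.3)))
    if (any(lengths(s) == 0)) next
    dab <- regulation_divergence(s[[1]], s[[2]])
    dbc <- regulation_divergence(s[[2]], s[[3]])
    dac <- regulation_divergence(s[[1]], s[[3]])
    expect_equal(dab, regulation_divergence(s[[2]], s[[1]]))
    expect_lte(dac, dab + dbc + 1e-12)
    if (setequal(s[[1]], s[[2]])) expect_equal(dab, 0) else expect_gt(dab, 0)
  }
})

test_that("promoter windows are strand-aware and clipped", {
  w <- promoter_window(1000, "+")
  expect_equal(c(w$start, w$end), c(400, 1200))
  expect_false(w$clipped)
  w2 <- promoter_window(1000, "-")
  expect_equal(c(w2$start, w2$end), c(800, 1600))
  w3 <- promoter_window(100, "+")
  expect_equal(c(w3$start, w3$end), c(0, 300))
  expect_true(w3$clipped)
  expect_error(promoter_window(NA, "+"), "missing")
  expect_error(promoter_window(100, "x"), "strand")
})

test_that("the PWM scanner matches an exhaustive per-offset oracle", {
  # consensus indicator motif
  consensus <- function(s) {
    m <- matrix(1e-6, 4, nchar(s), dimnames = list(c("A", "C", "G", "T")))
    for (j in seq_len(nchar(s))) m[substr(s, j, j), j] <- 1
    sweep(m, 2, colSums(m), "/")
  }
  pwm <- consensus("ACGTAC")
  expect_equal(scan_pwms("TTACGTACTT", list(hit = pwm)), "hit")
  # reverse-complement match
  expect_equal(scan_pwms("TTGTACGTTT", list(hit = pwm)), "hit")
  expect_equal(scan_pwms("NNNNNNNNNN", list(hit = pwm)), character(0))
  expect_error(scan_pwms("ACGX", list(hit = pwm)), "alphabet")
  set.seed(71)
  for (i in 1:10) {
    pwm <- matrix(rexp(32), 4, 8, dimnames = list(c("A", "C", "G", "T")))
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    seqc <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    want <- oracle_best_pwm_score(seqc, pwm)
    lo <- log2(pmax(pwm, 1e-9) / 0.25)
    thr <- sum(apply(lo, 2, max))
    for (frac in c(0.3, 0.6, 0.9)) {
      got <- length(scan_pwms(seqc, list(m = pwm), threshold_frac = frac)) == 1
      expect_equal(got, want >= frac * thr, label = paste("frac", frac))
    }
  }
})

test_that("JASPAR and MEME motif files parse to column-stochastic matrices", {
  jf <- tempfile()
  writeLines(c(">M1 testmotif",
               "A [ 10  0  5 ]", "C [  0 10  5 ]",
               "G [  0  0  0 ]", "T [  0  0  0 ]"), jf)
  pw <- read_jaspar_pfm(jf)
  expect_named(pw, "M1")
  expect_equal(dim(pw$M1), c(4L, 3L))
  expect_equal(colSums(pw$M1), rep(1, 3), ignore_attr = TRUE)
  expect_gt(pw$M1["A", 1], 0.8)
  mf <- tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF MX", "letter-probability matrix: alength= 4 w= 2",
               " 0.7 0.1 0.1 0.1", " 0.25 0.25 0.25 0.25"), mf)
  pm <- read_meme_minimal(mf)
  expect_named(pm, "MX")
  expect_equal(unname(pm$MX["A", 1]), 0.7)
  expect_equal(colSums(pm$MX), rep(1, 2), ignore_attr = TRUE)
})

test_that("regulation and expression divergence grow with simulated pair age", {
  sim <- default_sim(1)
  ann <- default_annotations(1)
  pr <- emit_homolog_pairs(sim, top_k = 3, ks_cap = 5, seed = 9)
  set.seed(9)
  pr <- pr[sample(nrow(pr), 400), ]
  age <- pair_divergence(sim, pr$gene_a, pr$gene_b)
  hits <- split(ann$pwm_hits$pwm_id, ann$pwm_hits$gene)
  or_empty <- function(x) if (is.null(x)) character(0) else x
  reg <- vapply(seq_len(nrow(pr)), function(i) {
    a <- hits[[pr$gene_a[i]]]; b <- hits[[pr$gene_b[i]]]
    if (is.null(a) && is.null(b)) NA_real_
    else regulation_divergence(or_empty(a), or_empty(b))
  }, numeric(1))
  expr <- vapply(seq_len(nrow(pr)), function(i)
    expression_divergence(ann$expression[pr$gene_a[i], ],
                          ann$expression[pr$gene_b[i], ]), numeric(1))
  ok <- !is.na(reg)
  expect_gt(cor(age[ok], reg[ok], method = "spearman"), 0.1)
  expect_gt(cor(age, expr, method = "spearman"), 0.3)
})
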