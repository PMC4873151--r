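test_that("GO term selection applies the strict size cutoff per namespace", {
  ann <- data.frame(
    gene = c(sprintf("g%03d", 1:300), sprintf("g%03d", 1:301),
             sprintf("g%03d", 1:350)),
    term = c(rep("T.exact300", 300), rep("T.just301", 301),
             rep("T.mf350", 350)), stringsAsFactors = FALSE)
  ns <- data.frame(term = c("T.exact300", "T.just301", "T.mf350"),
                   namespace = c("BP", "BP", "MF"), stringsAsFactors = FALSE)
  got <- select_go_terms(ann, ns, "BP", 300)
  expect_equal(got, "T.just301")  # exactly 300 genes is excluded, MF ignored
  expect_warning(e <- select_go_terms(ann, ns, "BP", 1000), "no BP term")
  expect_equal(e, character(0))
})

test_that("the synthetic annotation bundle yields the configured number of big BP terms", {
  ann <- default_annotations(1)
  terms <- select_go_terms(ann$go, ann$namespaces, "BP", 300)
  expect_length(terms, 29L)
  expect_true(all(grepl("^GO:BP", terms)))
})

test_that("fold-enrichment profiles follow the ratio definition", {
  pooled <- sprintf("g%04d", 1:1000)
  ann <- data.frame(gene = pooled[1:50], term = "T1",
                    stringsAsFactors = FALSE)
  # class of 100 genes, 10 with the term; pooled 50/1000 -> ratio 2.0
  class_genes <- c(pooled[1:10], pooled[101:190])
  fe <- fold_enrichment_profile(class_genes, pooled, "T1", ann)
  expect_equal(unname(fe), 2.0)
  # self-enrichment identity is exactly all ones
  fe2 <- fold_enrichment_profile(pooled, pooled, "T1", ann)
  expect_identical(unname(fe2), 1)
  # no class gene annotated -> 0
  fe3 <- fold_enrichment_profile(pooled[201:300], pooled, "T1", ann)
  expect_equal(unname(fe3), 0)
  expect_warning(
    fe4 <- fold_enrichment_profile(pooled[1:10], pooled, c("T1", "T9"), ann),
    "absent")
  expect_true(is.na(fe4["T9"]))
  expect_error(fold_enrichment_profile("not_pooled", pooled, "T1", ann),
               "subset")
})

test_that("profile clustering reproduces average linkage on 1 - r distances", {
  p <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  cl <- cluster_profiles(p)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(cl$dist["a", "c"], 2)
  expect_error(cluster_profiles(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant")
  # planted 2+2 block structure splits at the top, heights match the naive
  # average-linkage computation
  set.seed(81)
  base1 <- rnorm(20); base2 <- rnorm(20)
  p4 <- rbind(w1 = base1 + rnorm(20, 0, 0.05),
              w2 = base1 + rnorm(20, 0, 0.05),
              s1 = base2 + rnorm(20, 0, 0.05),
              s2 = base2 + rnorm(20, 0, 0.05))
  cl4 <- cluster_profiles(p4)
  top <- cl4$hclust$merge[3, ]
  expect_true(all(top > 0))  # top merge joins the two planted pairs
  expect_equal(sort(cl4$hclust$height),
               sort(oracle_average_linkage(cl4$dist)), tolerance = 1e-9)
  # order invariance up to relabelling
  cl4b <- cluster_profiles(p4[c(3, 1, 4, 2), ])
  expect_equal(sort(cl4b$hclust$height), sort(cl4$hclust$height),
               tolerance = 1e-12)
  expect_equal(cl4b$order, cl4$order)
})

test_that("Fisher enrichment matches hypergeometric enumeration and is transpose-invariant", {
  bg <- sprintf("g%02d", 1:8)
  class_g <- bg[1:4]; trait_g <- bg[c(1, 2, 3, 5)]
  res <- fisher_enrichment(class_g, trait_g, bg)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$p, oracle_fisher_p(3, 4, 4, 8), tolerance = 1e-9)
  # transposing class and trait leaves p unchanged
  res_t <- fisher_enrichment(trait_g, class_g, bg)
  expect_equal(res$p, res_t$p, tolerance = 1e-12)
  # balanced null table
  bg2 <- sprintf("h%03d", 1:100)
  res2 <- fisher_enrichment(bg2[1:50], bg2[c(1:25, 51:75)], bg2)
  expect_equal(res2$fold_enrichment, 1)
  expect_equal(res2$p, 1)
  # class entirely inside a rare trait
  res3 <- fisher_enrichment(bg2[1:5], bg2[1:10], bg2)
  expect_equal(res3$fold_enrichment, length(bg2) / 10)
  expect_error(fisher_enrichment("a", "a", character(0)), "background")
  set.seed(91)
  for (i in 1:20) {
    n_bg <- 30L
    bgx <- sprintf("x%02d", 1:n_bg)
    cl <- sample(bgx, 12); tr <- sample(bgx, 9)
    res <- fisher_enrichment(cl, tr, bgx)
    expect_equal(res$p, oracle_fisher_p(res$n_overlap, 12L, 9L, n_bg),
                 tolerance = 1e-9)
  }
})

test_that("PPI enrichment restricts to the screened background", {
  screened <- sprintf("g%03d", 1:200)
  ppi <- screened[1:60]
  class_in <- screened[41:100]   # 20/60 in PPI vs 60/200 background
  res <- ppi_enrichment(class_in, ppi, screened)
  expect_false(res$untestable)
  expect_equal(res$fold_enrichment, (20 / 60) / (60 / 200))
  # genes outside the screen are ignored
  res2 <- ppi_enrichment(c(class_in, "outsider"), ppi, screened)
  expect_equal(res$p, res2$p)
  res3 <- ppi_enrichment("outsider", ppi, screened)
  expect_true(res3$untestable)
  res4 <- ppi_enrichment(screened, screened, screened)
  expect_equal(res4$fold_enrichment, 1)
})

test_that("planted essentiality enrichment is recovered from the synthetic annotations", {
  sim <- default_sim(1)
  ann <- default_annotations(1)
  cfg <- ann$config
  tt <- truth_table(sim)
  ess <- ann$essential[ann$essential$screened, ]
  rate_of <- function(cls) {
    g <- tt$gene[tt$truth_origin == cls]
    mean(ess$phenotype[ess$gene %in% g])
  }
  base <- cfg$essential_base
  for (cls in c("relocated_gamma", "tandem")) {
    want <- base * cfg$essential_mult[[cls]]
    n <- sum(ess$gene %in% tt$gene[tt$truth_origin == cls])
    se <- sqrt(want * (1 - want) / n)
    expect_lt(abs(rate_of(cls) - want), 4 * se + 0.01, label = cls)
  }
  # null configuration: class-independent essentiality
  cfg0 <- ann_config(essential_mult = c(gamma = 1, relocated_gamma = 1,
                                        tandem = 1, proximal = 1,
                                        transposed = 1, ancestral = 1))
  ann0 <- generate_annotations(sim, cfg0, seed = 3)
  ess0 <- ann0$essential[ann0$essential$screened, ]
  cls0 <- tt$truth_origin[match(ess0$gene, tt$gene)]
  big <- names(table(cls0))[table(cls0) > 50]
  chi <- suppressWarnings(
    chisq.test(table(cls0[cls0 %in% big], ess0$phenotype[cls0 %in% big])))
  expect_gt(chi$p.value, 1e-3)
})

test_that("annotation generation is deterministic and validates multipliers", {
  sim <- default_sim(1)
  a1 <- generate_annotations(sim, seed = 5)
  a2 <- generate_annotations(sim, seed = 5)
  expect_identical(a1$go, a2$go)
  expect_identical(a1$expression, a2$expression)
  expect_identical(a1$pwm_hits, a2$pwm_hits)
  expect_error(ann_config(essential_mult = c(gamma = -1)), "multipliers")
})

test_that("pairs born at the present have identical PWM sets and expression", {
  cfg <- sim_config(n_ancestral_genes = 100, n_chromosomes = 2,
                    outgroups = small_ladder(),
                    events = data.frame(time = 0.001, kind = "triplication",
                                        label = "gamma"),
                    rates = zero_rates(), seed = 17)
  sim <- simulate_genomes(cfg)
  ann <- generate_annotations(sim, seed = 17)
  pr <- emit_homolog_pairs(sim, ks_cap = 10, seed = 17)
  hits <- split(ann$pwm_hits$pwm_id, ann$pwm_hits$gene)
  for (i in seq_len(min(nrow(pr), 50))) {
    a <- hits[[pr$gene_a[i]]]; b <- hits[[pr$gene_b[i]]]
    if (is.null(a) && is.null(b)) next
    expect_equal(regulation_divergence(a, b), 0)
    expect_lt(expression_divergence(ann$expression[pr$gene_a[i], ],
                                    ann$expression[pr$gene_b[i], ]), 0.01)
  }
})
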