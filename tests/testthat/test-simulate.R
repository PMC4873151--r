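test_that("a triplication with all rates zero yields exactly three ordered copies", {
  cfg <- sim_config(n_ancestral_genes = 100, n_chromosomes = 2,
                    outgroups = small_ladder(),
                    events = data.frame(time = 80, kind = "triplication",
                                        label = "gamma"),
                    rates = zero_rates(), seed = 42)
  sim <- simulate_genomes(cfg)
  tt <- truth_table(sim)
  expect_equal(nrow(tt), 300L)
  expect_true(all(tt$truth_origin == "gamma"))
  expect_false(any(tt$relocated))
  # two extra chromosome sets, ancestral order preserved
  g <- sim$genomes$At
  expect_length(g, 6L)
  fam <- function(v) sim$nodes$family[as.integer(sub("^g", "", v))]
  expect_identical(fam(g[["chr03"]]), fam(g[["chr01"]]))
  expect_identical(fam(g[["chr05"]]), fam(g[["chr01"]]))
})

test_that("zero rates and no events reproduce the ancestor in every lineage", {
  cfg <- sim_config(n_ancestral_genes = 60, n_chromosomes = 3,
                    outgroups = small_ladder(),
                    events = data.frame(time = numeric(0), kind = character(0),
                                        label = character(0)),
                    rates = zero_rates(), seed = 5)
  sim <- simulate_genomes(cfg)
  fam <- function(v) sim$nodes$family[as.integer(sub("^g", "", v))]
  anc <- lapply(sim$genomes$At, fam)
  for (sp in names(sim$genomes)) {
    expect_identical(lapply(sim$genomes[[sp]], fam), anc, label = sp)
  }
  expect_equal(nrow(emit_homolog_pairs(sim, seed = 1)), 0L)
  expect_true(all(truth_table(sim)$truth_origin == "ancestral"))
})

test_that("gene counts reconcile with the event log (births - deaths = final - initial)", {
  for (s in c(2, 9)) {
    cfg <- sim_config(n_ancestral_genes = 300, n_chromosomes = 3,
                      outgroups = small_ladder(),
                      events = data.frame(time = 80, kind = "triplication",
                                          label = "gamma"),
                      rates = list(loss = 5e-4, loss_postpoly_mult = 5,
                                   loss_postpoly_span = 30,
                                   relocation = 3e-4,
                                   relocation_burst = c(50, 80),
                                   relocation_burst_mult = 10,
                                   tandem = 4e-4, proximal = 2e-4,
                                   transposed = 3e-4),
                      seed = s)
    sim <- simulate_genomes(cfg)
    final_total <- sum(vapply(sim$genomes, function(g) sum(lengths(g)),
                              numeric(1)))
    expect_equal(final_total,
                 cfg$n_ancestral_genes + sum(sim$event_log$n_change))
  }
})

test_that("relocation-burst truth labels stay inside the configured window", {
  tt <- truth_table(default_sim(1))
  rel <- tt[tt$truth_origin == "relocated_gamma", ]
  expect_gt(nrow(rel), 50)
  burst <- default_sim(1)$config$rates$relocation_burst
  expect_true(all(rel$reloc_time >= burst[1] & rel$reloc_time <= burst[2]))
  # and relocation can only postdate the copy's origin
  expect_true(all(rel$reloc_time <= rel$origin_time))
})

test_that("with noise off, Ks equals twice the clock rate times divergence time", {
  cfg <- sim_config(n_ancestral_genes = 200, n_chromosomes = 2,
                    outgroups = small_ladder(),
                    events = data.frame(time = 80, kind = "wgd",
                                        label = "alpha"),
                    rates = modifyList(zero_rates(),
                                       list(tandem = 5e-4, transposed = 5e-4)),
                    clock = list(mu = 0.005, ks_sd = 0), seed = 11)
  sim <- simulate_genomes(cfg)
  pr <- emit_homolog_pairs(sim, ks_cap = 10, seed = 1)
  expect_gt(nrow(pr), 100)
  div <- pair_divergence(sim, pr$gene_a, pr$gene_b)
  expect_equal(pr$ks, 2 * 0.005 * div, tolerance = 1e-12)
  # copies born of the WGD diverged exactly at the event
  expect_true(any(abs(div - 80) < 1e-9))
})

test_that("emit_homolog_pairs respects top_k, the Ks cap and symmetry", {
  sim <- default_sim(1)
  pr <- emit_homolog_pairs(sim, top_k = 5, ks_cap = 3, seed = 1)
  long <- c(pr$gene_a, pr$gene_b)
  # a gene can exceed top_k only through symmetric closure; the emitted list
  # must never contain duplicated unordered pairs and all Ks below the cap
  expect_false(any(duplicated(paste(pr$gene_a, pr$gene_b))))
  expect_true(all(pr$gene_a < pr$gene_b))
  expect_true(all(pr$ks < 3))
  expect_equal(pr$omega, pr$ka / pr$ks, tolerance = 1e-12)
  expect_equal(nrow(emit_homolog_pairs(sim, ks_cap = 0, seed = 1)), 0L)
  expect_error(emit_homolog_pairs(sim, top_k = 0), "top_k")
  # family of n copies emits <= top_k partners per gene before closure:
  # every gene's partner count is bounded by family size - 1 and closure
  # can at most double top_k
  cnt <- table(long)
  expect_true(all(cnt <= 10))
})

test_that("relocated fraction of surviving triplication copies matches the event log", {
  sim <- default_sim(1)
  tt <- truth_table(sim)
  gam <- tt[tt$origin_class == "gamma", ]
  p_hat <- mean(!is.na(gam$reloc_time))
  # expectation from the realized process: relocations on the focal lineage
  # after the event hit uniformly chosen genes
  el <- sim$event_log
  focal <- el[el$lineage == "At", ]
  relocs <- sum(focal$kind == "relocation" & focal$time < 125)
  # average focal genome size between the event and the present
  n_traj <- 3 * sim$config$n_ancestral_genes +
    cumsum(focal$n_change[focal$time < 125])
  p_exp <- 1 - exp(-relocs / mean(n_traj))
  se <- sqrt(p_exp * (1 - p_exp) / nrow(gam))
  expect_lt(abs(p_hat - p_exp), 4 * se + 0.01)
})

test_that("invalid configurations and extinction are rejected informatively", {
  expect_error(sim_config(events = data.frame(time = 200,
                                              kind = "triplication",
                                              label = "gamma")),
               "event time")
  expect_error(sim_config(rates = modifyList(zero_rates(),
                                             list(loss = -1))), ">= 0")
  expect_error(sim_config(rates = modifyList(zero_rates(),
                                             list(relocation_burst = c(150, 100)))),
               "window")
  err <- tryCatch(
    simulate_genomes(sim_config(n_ancestral_genes = 20, n_chromosomes = 2,
                                outgroups = small_ladder(),
                                events = data.frame(time = numeric(0),
                                                    kind = character(0),
                                                    label = character(0)),
                                rates = modifyList(zero_rates(),
                                                   list(loss = 5)),
                                seed = 1)),
    dupSimError = function(e) e)
  expect_s3_class(err, "dupSimError")
  expect_true(is.data.frame(err$event_log))
})

test_that("the same seed reproduces genomes and event log exactly", {
  cfgf <- function() sim_config(
    n_ancestral_genes = 300, n_chromosomes = 3,
    outgroups = small_ladder(), seed = 77,
    events = data.frame(time = 80, kind = "triplication", label = "gamma"),
    rates = modifyList(zero_rates(),
                       list(loss = 5e-4, relocation = 3e-4,
                            relocation_burst_mult = 10, tandem = 4e-4,
                            transposed = 3e-4)))
  s1 <- simulate_genomes(cfgf())
  s2 <- simulate_genomes(cfgf())
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$event_log, s2$event_log)
})
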