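# Shared simulation fixtures, built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

zero_rates <- function() {
  list(loss = 0, loss_postpoly_mult = 1, loss_postpoly_span = 50,
       relocation = 0, relocation_burst = c(50, 80),
       relocation_burst_mult = 1,
       tandem = 0, proximal = 0, transposed = 0)
}

# small ladder for cheap simulations
small_ladder <- function() {
  data.frame(species = c("O1", "O2", "O3"), divergence_mya = c(10, 60, 100),
             stringsAsFactors = FALSE)
}

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

default_sim <- function(seed = 1L) {
  cached(paste0("sim", seed), simulate_genomes(sim_config(seed = seed)))
}

default_pipeline <- function(seed = 1L) {
  cached(paste0("pl", seed),
         run_origin_pipeline(default_sim(seed), pair_seed = seed))
}

default_annotations <- function(seed = 1L) {
  cached(paste0("ann", seed),
         generate_annotations(default_sim(seed), seed = seed))
}

# the 20-seed recovery study used by the acceptance checks (computed once)
recovery_study <- function(seeds = 1:20) {
  cached("recovery", {
    rows <- lapply(seeds, function(s) {
      sim <- simulate_genomes(sim_config(seed = s))
      pl <- run_origin_pipeline(sim, pair_seed = s)
      ev <- evaluate_origins(pl$origins, truth_table(sim))
      wtp <- c("gamma", "tandem", "proximal")
      conf <- ev$confusion
      burst <- sim$config$rates$relocation_burst
      peak <- which.max(pl$retention$rate)
      peak_row <- pl$retention[peak, ]
      data.frame(
        seed = s,
        pooled_wtp = sum(diag(conf[wtp, wtp])) / sum(conf[wtp, ]),
        wgd = unname(ev$recall["gamma"]),
        tandem = unname(ev$recall["tandem"]),
        proximal = unname(ev$recall["proximal"]),
        rel_sens = unname(ev$recall["relocated_gamma"]),
        rel_prec = unname(ev$precision["relocated_gamma"]),
        peak_in_burst = peak_row$start >= burst[1] & peak_row$end <= burst[2])
    })
    do.call(rbind, rows)
  })
}
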