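#' Default outgroup ladder
#'
#' The focal lineage plus eight outgroups ordered from nearest to farthest,
#' with divergence times in million years (Mya): Al 5, Br 16, Cp 72, Tc 90,
#' Pt 107, Vv 113, St 125, Os 148. These mirror the divergence-time ladder
#' used throughout the package for epoch dating of dispersed duplicates.
#'
#' @return data.frame with columns `species` and `divergence_mya`.
#' @export
default_ladder <- function() {
  data.frame(
    species = c("Al", "Br", "Cp", "Tc", "Pt", "Vv", "St", "Os"),
    divergence_mya = c(5, 16, 72, 90, 107, 113, 125, 148),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Parameters of the forward-in-time genome evolution scenario: a focal
#' lineage and an ordered set of outgroups descending from a common ancestor,
#' a genome triplication on the shared stem (inherited by every outgroup that
#' diverged after it), a post-triplication burst of per-gene relocations, and
#' ongoing single-gene duplication and loss.
#'
#' All rates are per gene per million years. The relocation burst multiplies
#' the baseline relocation rate inside `relocation_burst` (an absolute Mya
#' window). After each polyploidy event the loss rate is multiplied by
#' `loss_postpoly_mult` for `loss_postpoly_span` My (fractionation).
#'
#' @param n_ancestral_genes number of genes in the ancestral genome.
#' @param n_chromosomes number of ancestral chromosomes.
#' @param outgroups data.frame(species, divergence_mya), nearest first,
#'   strictly increasing times. The root age is the farthest divergence.
#' @param focal name of the focal species.
#' @param events data.frame(time, kind, label) with kind in
#'   `c("wgd", "triplication")`; an event at time t is inherited by every
#'   outgroup with divergence time <= t.
#' @param rates named list: `loss`, `relocation`, `tandem`, `proximal`,
#'   `transposed` (per gene per My), `loss_postpoly_mult`,
#'   `loss_postpoly_span` (My), `relocation_burst` (length-2 Mya window),
#'   `relocation_burst_mult`.
#' @param clock list with `mu` (Ks per My per lineage) and `ks_sd`
#'   (lognormal sd of multiplicative Ks noise; 0 switches noise off).
#' @param omega list with `meanlog`, `sdlog` of the lognormal Ka/Ks
#'   distribution drawn per pair.
#' @param local_window rank window for proximal duplications.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_ancestral_genes = 2000L,
                       n_chromosomes = 10L,
                       outgroups = default_ladder(),
                       focal = "At",
                       events = data.frame(time = 125, kind = "triplication",
                                           label = "gamma",
                                           stringsAsFactors = FALSE),
                       rates = list(
                         loss = 2e-4,
                         loss_postpoly_mult = 20,
                         loss_postpoly_span = 50,
                         relocation = 1e-4,
                         relocation_burst = c(107, 148),
                         relocation_burst_mult = 25,
                         tandem = 3.6e-4,
                         proximal = 1.2e-4,
                         transposed = 2e-4
                       ),
                       clock = list(mu = 0.0076, ks_sd = 0.15),
                       omega = list(meanlog = log(0.2), sdlog = 0.5),
                       local_window = 10L,
                       seed = 1L) {
  cfg <- list(
    n_ancestral_genes = as.integer(n_ancestral_genes),
    n_chromosomes = as.integer(n_chromosomes),
    outgroups = outgroups, focal = focal, events = events,
    rates = rates, clock = clock, omega = omega,
    local_window = as.integer(local_window), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  og <- cfg$outgroups
  if (nrow(og) < 1) stop("at least one outgroup is required", call. = FALSE)
  if (any(diff(og$divergence_mya) <= 0) || any(og$divergence_mya <= 0))
    stop("outgroup divergence times must be positive and strictly increasing",
         call. = FALSE)
  root_age <- max(og$divergence_mya)
  ev <- cfg$events
  if (nrow(ev) > 0) {
    if (!all(ev$kind %in% c("wgd", "triplication")))
      stop("event kind must be 'wgd' or 'triplication'", call. = FALSE)
    if (any(ev$time > root_age) || any(ev$time <= 0))
      stop("event time outside the tree: events must lie on a branch, ",
           "i.e. in (0, root age]", call. = FALSE)
    if (is.null(ev$label)) ev$label <- ev$kind
  }
  r <- cfg$rates
  base <- c("loss", "relocation", "tandem", "proximal", "transposed")
  if (!all(base %in% names(r)))
    stop("rates must name: ", paste(base, collapse = ", "), call. = FALSE)
  if (any(unlist(r[base]) < 0)) stop("all rates must be >= 0", call. = FALSE)
  bw <- r$relocation_burst
  if (!is.null(bw)) {
    if (length(bw) != 2 || bw[1] >= bw[2])
      stop("relocation_burst must be an increasing Mya window", call. = FALSE)
    if (bw[2] > root_age || bw[1] < 0)
      stop("relocation burst window must lie within the tree's time span",
           call. = FALSE)
  }
  if (cfg$n_ancestral_genes < cfg$n_chromosomes)
    stop("need at least one gene per chromosome", call. = FALSE)
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds any subset of the `sim_config()` arguments; omitted fields
#' take the defaults. `outgroups` and `events` may be given as lists of
#' records.
#'
#' @param path YAML (or JSON, which YAML subsumes) file path.
#' @return `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_ancestral_genes", "n_chromosomes", "focal",
               "local_window", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$outgroups))
    args$outgroups <- do.call(rbind.data.frame, lapply(raw$outgroups, as.data.frame))
  if (!is.null(raw$events))
    args$events <- do.call(rbind.data.frame, lapply(raw$events, as.data.frame))
  for (nm in c("rates", "clock", "omega")) if (!is.null(raw[[nm]])) {
    dflt <- formals(sim_config)[[nm]]
    merged <- eval(dflt)
    merged[names(raw[[nm]])] <- raw[[nm]]
    if (!is.null(merged$relocation_burst))
      merged$relocation_burst <- as.numeric(unlist(merged$relocation_burst))
    args[[nm]] <- merged
  }
  do.call(sim_config, args)
}
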