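#' Configuration for the synthetic metacommunity generator
#'
#' Defaults emulate a high-plateau lake survey: 47 surface-water samples,
#' 2,000 OTUs rarefied to 2,210 reads each, a small pool of widespread and
#' aggregated core taxa (negative-binomial counts, high occupancy) against a
#' large pool of sparse satellite taxa (low-rate Poisson counts), moderate
#' environmental filtering on phylogenetically conserved optima, and a
#' spatially autocorrelated environment so community dissimilarity rises with
#' distance.
#'
#' @param n_samples number of samples (sites).
#' @param n_core,n_satellite numbers of designed core and satellite taxa.
#' @param depth reads per sample after rarefaction.
#' @param aggregation_k negative-binomial dispersion of core taxa; smaller
#'   values mean stronger spatial aggregation (default 0.3).
#' @param satellite_rate mean Poisson cell abundance of a satellite taxon
#'   where present (default 2). Raw abundances are cell counts far above the
#'   sequencing depth; the returned table is a thin multinomial sample of
#'   them, so satellite reads stay near-Poisson across samples.
#' @param occupancy_core,occupancy_satellite presence probabilities per
#'   sample (defaults 0.9 and 0.8). Satellite taxa are rare rather than
#'   absent: their detected occupancy is sampling-limited and ends up low
#'   even though the organisms are widespread.
#' @param core_meanlog,core_sdlog lognormal parameters of per-taxon core base
#'   cell abundances (defaults log(400) and 1), producing the right-skewed
#'   abundance-occupancy relationship.
#' @param env_gradient_sd spread of the standardized environmental variable
#'   across sites (default 1).
#' @param filtering_strength selection intensity on the squared mismatch
#'   between a taxon's optimum and the site environment; 0 disables selection
#'   (default 1).
#' @param spatial_decay e-folding distance (km) of the spatial smoothing
#'   kernel applied to site environments; 0 disables spatial autocorrelation
#'   (default 300 km).
#' @param lat_range,lon_range sampling window in decimal degrees (defaults
#'   cover a high-plateau lake district).
#' @param seed integer seed (default 1).
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 47, n_core = 300,
                             n_satellite = 1700, depth = 2210,
                             aggregation_k = 0.3, satellite_rate = 2,
                             occupancy_core = 0.9, occupancy_satellite = 0.8,
                             core_meanlog = log(400), core_sdlog = 1,
                             env_gradient_sd = 1, filtering_strength = 1,
                             spatial_decay = 300,
                             lat_range = c(28.3, 34.6),
                             lon_range = c(79.8, 96.8), seed = 1) {
  cfg <- list(
    n_samples = n_samples, n_core = n_core, n_satellite = n_satellite,
    depth = depth, aggregation_k = aggregation_k,
    satellite_rate = satellite_rate, occupancy_core = occupancy_core,
    occupancy_satellite = occupancy_satellite, core_meanlog = core_meanlog,
    core_sdlog = core_sdlog, env_gradient_sd = env_gradient_sd,
    filtering_strength = filtering_strength, spatial_decay = spatial_decay,
    lat_range = lat_range, lon_range = lon_range, seed = seed
  )
  if (n_core + n_satellite == 0) stop("no taxa requested", call. = FALSE)
  pos <- c("n_samples", "depth", "aggregation_k", "satellite_rate",
           "env_gradient_sd")
  for (p in pos) {
    if (cfg[[p]] <= 0) stop(p, " must be positive", call. = FALSE)
  }
  if (filtering_strength < 0) stop("filtering_strength must be >= 0",
                                   call. = FALSE)
  if (spatial_decay < 0) stop("spatial_decay must be >= 0", call. = FALSE)
  for (p in c("occupancy_core", "occupancy_satellite")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]",
                                           call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Simulate a phylogeny with Brownian trait optima
#'
#' Grows a pure-birth (Yule) tree, rescales its depth to 1, and evolves an
#' environmental optimum along it by Brownian motion so that close relatives
#' have similar optima — the phylogenetic signal that makes selection
#' detectable by betaNTI.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param tip_prefix prefix for tip labels (default "OTU").
#' @return list with `tree` (an ultrametric `phylo` with unit depth) and
#'   `optima` (named numeric vector of tip optima, Brownian with sigma 1).
#' @export
simulate_tree <- function(n_taxa, seed = NULL, tip_prefix = "OTU") {
  if (n_taxa < 2) stop("need at least 2 taxa", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- sprintf("%s%04d", tip_prefix, seq_len(n_taxa))
    optima <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    list(tree = tree, optima = optima)
  })
}

#' Simulate a metacommunity with known core/satellite structure
#'
#' Composes counts as presence (Bernoulli occupancy) times abundance
#' (negative binomial for core taxa, Poisson for satellite taxa), optionally
#' modulated by environmental filtering `exp(-filtering_strength * (optimum -
#' site_env)^2)` on Brownian optima, with site environments smoothed over a
#' spatial kernel `exp(-d / spatial_decay)` so turnover is spatially
#' autocorrelated. Raw counts are multinomially rarefied to `depth`, so the
#' returned table is even-depth.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (rarefied `comm_table`), `metadata` (sample
#'   coordinates and environment), `tree` (the `phylo`), and `truth` (list:
#'   per-OTU `designed_label` and `optimum`, per-sample `env`, and the
#'   generating `regime` tag).
#' @export
simulate_metacommunity <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_taxa <- cfg$n_core + cfg$n_satellite
  sim <- simulate_tree(n_taxa, seed = derive_seed(cfg$seed, "tree"))
  tree <- sim$tree
  optima <- scale(sim$optima)[, 1] * cfg$env_gradient_sd
  with_seed(derive_seed(cfg$seed, "community"), {
    is_core <- rep(FALSE, n_taxa)
    is_core[sample.int(n_taxa, cfg$n_core)] <- TRUE

    lat <- runif(cfg$n_samples, cfg$lat_range[1], cfg$lat_range[2])
    lon <- runif(cfg$n_samples, cfg$lon_range[1], cfg$lon_range[2])
    meta <- data.frame(sample_id = sprintf("S%02d", seq_len(cfg$n_samples)),
                       latitude = lat, longitude = lon,
                       stringsAsFactors = FALSE)
    z <- rnorm(cfg$n_samples)
    if (cfg$spatial_decay > 0) {
      dk <- as.matrix(geo_distance(meta))
      kern <- exp(-dk / cfg$spatial_decay)
      env <- as.vector(kern %*% z) / rowSums(kern)
    } else {
      env <- z
    }
    env <- scale(env)[, 1] * cfg$env_gradient_sd

    base_mean <- numeric(n_taxa)
    base_mean[is_core] <- rlnorm(cfg$n_core, cfg$core_meanlog, cfg$core_sdlog)
    base_mean[!is_core] <- cfg$satellite_rate

    counts <- matrix(0L, cfg$n_samples, n_taxa,
                     dimnames = list(meta$sample_id, tree$tip.label))
    for (i in seq_len(cfg$n_samples)) {
      w <- if (cfg$filtering_strength > 0) {
        exp(-cfg$filtering_strength * (optima - env[i])^2)
      } else {
        rep(1, n_taxa)
      }
      present <- rbinom(n_taxa, 1, ifelse(is_core, cfg$occupancy_core,
                                          cfg$occupancy_satellite))
      mu <- base_mean * w
      raw <- numeric(n_taxa)
      raw[is_core] <- rnbinom(cfg$n_core, mu = mu[is_core],
                              size = cfg$aggregation_k)
      raw[!is_core] <- rpois(cfg$n_satellite, mu[!is_core])
      raw <- raw * present
      if (sum(raw) == 0) raw[sample.int(n_taxa, 1)] <- 1
      counts[i, ] <- rmultinom(1, cfg$depth, prob = raw)[, 1]
    }

    truth <- list(
      designed_label = setNames(ifelse(is_core, "core", "satellite"),
                                tree$tip.label),
      optimum = setNames(as.numeric(optima), tree$tip.label),
      env = setNames(as.numeric(env), meta$sample_id),
      regime = if (cfg$filtering_strength > 0) "selection"
               else if (cfg$spatial_decay > 0) "dispersal_limited"
               else "neutral"
    )
    meta$environment <- as.numeric(env)
    list(table = community_table(counts), metadata = meta, tree = tree,
         truth = truth)
  })
}

#' Write a simulated metacommunity to disk
#'
#' Writes the community table, metadata, Newick tree and truth table in the
#' same plain-text formats the readers consume.
#'
#' @param sim result of [simulate_metacommunity()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_metacommunity <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_community_table(sim$table, file.path(dir, "community.tsv"))
  write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  truth <- data.frame(otu_id = names(sim$truth$designed_label),
                      designed_label = sim$truth$designed_label,
                      optimum = sim$truth$optimum,
                      row.names = NULL, stringsAsFactors = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
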