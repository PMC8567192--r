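#' Build and validate a pipeline configuration
#'
#' Exactly one of `paths` (input files) or `simulation` (a
#' [synthetic_config()]) must be supplied.
#'
#' @param paths named list with elements `table`, `metadata` and optionally
#'   `tree`, `taxonomy` (file paths), or NULL.
#' @param simulation a `synthetic_config`, or NULL.
#' @param depth rarefaction depth applied to file inputs (simulated tables
#'   arrive already rarefied); NULL uses the minimum sample total.
#' @param alpha_tail chi-square tail for the partition (default 0.025).
#' @param n_perm permutations for distance-decay tests (default 999).
#' @param n_null randomizations for the assembly null models (default 999).
#' @param min_prevalence,rho_threshold,q_threshold network filters.
#' @param er_graphs size of the random-graph null ensemble (default 1000).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, simulation = NULL, depth = NULL,
                            alpha_tail = 0.025, n_perm = 999, n_null = 999,
                            min_prevalence = 5, rho_threshold = 0.6,
                            q_threshold = 0.01, er_graphs = 1000, seed = 1) {
  if (is.null(paths) == is.null(simulation)) {
    stop("supply exactly one of 'paths' or 'simulation'", call. = FALSE)
  }
  if (!is.null(paths)) {
    req <- c("table", "metadata")
    if (!all(req %in% names(paths))) {
      stop("paths must name at least: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    missing <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation,
                                               "synthetic_config"))
  structure(
    list(paths = paths, simulation = simulation, depth = depth,
         alpha_tail = alpha_tail, n_perm = n_perm, n_null = n_null,
         min_prevalence = min_prevalence, rho_threshold = rho_threshold,
         q_threshold = q_threshold, er_graphs = er_graphs, seed = seed),
    class = "pipeline_config"
  )
}

stage_msg <- function(stage) message(sprintf("[%s] %s", format(Sys.time(),
                                                               "%H:%M:%S"),
                                             stage))

#' Run the full core/satellite study workflow
#'
#' Ingests (or simulates) a community table, rarefies, partitions OTUs into
#' core and satellite sub-communities, and contrasts the two by alpha
#' diversity, distance-decay regressions, assembly-process fractions, niche
#' breadth and a co-occurrence network with a random-graph null, robustness
#' and vulnerability. Artifacts are written under `out_dir` when given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for stage artifacts.
#' @return list of class `study_report` holding every stage's result plus a
#'   provenance block (seed, config, package version).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  stage_msg("input")
  if (!is.null(config$simulation)) {
    sim <- simulate_metacommunity(config$simulation)
    tab <- sim$table; meta <- sim$metadata; tree <- sim$tree
    taxonomy <- NULL; truth <- sim$truth
  } else {
    tab <- read_community_table(config$paths$table)
    meta <- read_sample_metadata(config$paths$metadata)
    tree <- if (!is.null(config$paths$tree)) {
      ape::read.tree(config$paths$tree)
    }
    taxonomy <- if (!is.null(config$paths$taxonomy)) {
      read_taxonomy(config$paths$taxonomy)
    }
    truth <- NULL
    depth <- if (is.null(config$depth)) min(rowSums(tab)) else config$depth
    tab <- rarefy(tab, depth, seed = derive_seed(seed, "rarefy"))
    meta <- meta[match(rownames(tab), meta$sample_id), ]
    if (anyNA(meta$sample_id)) {
      stop("metadata missing for samples: ",
           paste(setdiff(rownames(tab), meta$sample_id), collapse = ", "),
           call. = FALSE)
    }
  }

  stage_msg("partition")
  part <- classify_core_satellite(tab, alpha_tail = config$alpha_tail)
  psum <- partition_summary(part, tab)
  ao <- abundance_occupancy(tab)
  groups <- c("core", "satellite")
  subset_of <- function(g) part$otus$otu_id[part$otus$label == g]

  stage_msg("diversity")
  div <- alpha_diversity(tab)
  div_groups <- lapply(groups, function(g) {
    sub <- unclass(tab)[, subset_of(g), drop = FALSE]
    alpha_diversity(community_table(sub))
  })
  names(div_groups) <- groups
  div_tests <- lapply(c("chao1", "shannon"), function(m) {
    kw <- kruskal_wallis(list(core = div_groups$core[[m]],
                              satellite = div_groups$satellite[[m]]))
    data.frame(metric = m, kw_h = kw$statistic, kw_p = kw$p_value)
  })
  div_tests <- do.call(rbind, div_tests)

  stage_msg("distance-decay")
  geo <- geo_distance(meta)
  bc <- lapply(groups, function(g) bray_curtis(tab, subset_of(g)))
  names(bc) <- groups
  ddr <- lapply(groups, function(g) {
    ddr_fit(geo, bc[[g]], n_perm = config$n_perm,
            seed = derive_seed(seed, paste0("ddr_", g)))
  })
  names(ddr) <- groups
  slope_diff <- slope_difference_test(ddr$core$pairs, ddr$satellite$pairs,
                                      n_perm = config$n_perm,
                                      seed = derive_seed(seed, "slopes"))

  assembly <- ddr_by_process <- NULL
  if (!is.null(tree)) {
    stage_msg("assembly null models")
    assembly <- lapply(groups, function(g) {
      sub <- community_table(unclass(tab)[, subset_of(g), drop = FALSE])
      assembly_analysis(sub, tree, n_null = config$n_null,
                        seed = derive_seed(seed, paste0("assembly_", g)))
    })
    names(assembly) <- groups
    ddr_by_process <- lapply(groups, function(g) {
      out <- list()
      for (pr in c("heterogeneous_selection", "dispersal_limitation")) {
        out[[pr]] <- tryCatch(
          process_conditioned_ddr(assembly[[g]], geo, bc[[g]], pr,
                                  n_perm = config$n_perm,
                                  seed = derive_seed(seed, paste0(g, pr))),
          error = function(e) NULL)
      }
      out
    })
    names(ddr_by_process) <- groups
  }

  stage_msg("niche breadth")
  nb <- lapply(groups, function(g) niche_breadth(tab, subset_of(g)))
  names(nb) <- groups
  nb_test <- kruskal_wallis(list(core = nb$core$per_otu$B,
                                 satellite = nb$satellite$per_otu$B))

  stage_msg("network")
  net <- build_network(tab, partition = part,
                       min_prevalence = config$min_prevalence,
                       rho_threshold = config$rho_threshold,
                       q_threshold = config$q_threshold)
  topo <- ntop <- er <- robust <- vuln <- NULL
  if (igraph::ecount(net$graph) > 0) {
    topo <- graph_topology(net, seed = derive_seed(seed, "modularity"))
    ntop <- node_topology(net)
    er <- er_ensemble(topo$n_nodes, topo$n_edges,
                      n_graphs = config$er_graphs,
                      seed = derive_seed(seed, "er"))
    subnet <- function(g) {
      ids <- net$nodes$otu_id[net$nodes$label %in% g]
      igraph::induced_subgraph(net$graph, ids)
    }
    robust <- vuln <- list()
    for (g in groups) {
      sg <- subnet(g)
      if (igraph::vcount(sg) >= 3) {
        robust[[g]] <- robustness_curve(sg, removal = "random",
                                        seed = derive_seed(seed,
                                                           paste0("rob", g)))
        vuln[[g]] <- vulnerability(sg)
      }
    }
  }

  report <- structure(
    list(table = tab, metadata = meta, taxonomy = taxonomy, truth = truth,
         partition = part, partition_summary = psum,
         abundance_occupancy = ao[c("slope", "r_squared", "p_value")],
         diversity = div, diversity_groups = div_groups,
         diversity_tests = div_tests,
         ddr = ddr, slope_difference = slope_diff,
         assembly = assembly, ddr_by_process = ddr_by_process,
         niche_breadth = nb, niche_breadth_test = nb_test,
         network = net, graph_topology = topo, node_topology = ntop,
         er_null = er, robustness = robust, vulnerability = vuln,
         provenance = list(seed = seed,
                           package_version =
                             as.character(utils::packageVersion("coresat")),
                           r_version = R.version.string,
                           timestamp = format(Sys.time()))),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_community_table(report$table, file.path(out_dir, "table.tsv"))
  tsv(report$partition$otus, "partition.tsv")
  tsv(report$diversity, "diversity.tsv")
  for (g in names(report$ddr)) tsv(report$ddr[[g]]$pairs,
                                   paste0("ddr_pairs_", g, ".tsv"))
  if (!is.null(report$assembly)) {
    for (g in names(report$assembly)) {
      tsv(report$assembly[[g]]$pairs, paste0("assembly_pairs_", g, ".tsv"))
    }
  }
  if (!is.null(report$network)) tsv(report$network$edges, "edges.tsv")
  summary_json <- list(
    partition = report$partition_summary,
    abundance_occupancy = report$abundance_occupancy,
    ddr_slopes = lapply(report$ddr, function(f) f$slope),
    slope_difference = report$slope_difference,
    assembly_fractions = lapply(report$assembly, function(a) {
      as.list(a$fractions)
    }),
    niche_breadth = lapply(report$niche_breadth, function(x) x$mean_B),
    graph_topology = if (!is.null(report$graph_topology)) {
      as.list(report$graph_topology)
    },
    er_null = if (!is.null(report$er_null)) report$er_null$summary,
    vulnerability = report$vulnerability,
    provenance = report$provenance
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Core/satellite study report\n")
  print(x$partition)
  for (g in names(x$ddr)) {
    cat(g, "DDR slope:", round(x$ddr[[g]]$slope, 4), "\n")
  }
  if (!is.null(x$assembly)) {
    for (g in names(x$assembly)) {
      cat(g, "dominant process:",
          names(which.max(x$assembly[[g]]$fractions)), "\n")
    }
  }
  invisible(x)
}

#' Side-by-side core vs satellite contrasts
#'
#' Collects the headline quantities of every stage into one table with the
#' core value, satellite value and (where available) the test p-value.
#'
#' @param report a `study_report` from [run_pipeline()].
#' @return data.frame with columns `quantity`, `core`, `satellite`,
#'   `p_value`.
#' @export
compare_groups <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- list()
  add <- function(q, co, sa, p = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = q, core = co, satellite = sa, p_value = p,
      stringsAsFactors = FALSE)
  }
  ps <- report$partition_summary
  add("n_otus", ps$counts[["core"]], ps$counts[["satellite"]])
  add("read_pct", ps$read_pct[["core"]], ps$read_pct[["satellite"]])
  dt <- report$diversity_tests
  for (m in dt$metric) {
    add(paste0("mean_", m),
        mean(report$diversity_groups$core[[m]], na.rm = TRUE),
        mean(report$diversity_groups$satellite[[m]], na.rm = TRUE),
        dt$kw_p[dt$metric == m])
  }
  add("ddr_slope", report$ddr$core$slope, report$ddr$satellite$slope,
      report$slope_difference$p_value)
  add("mantel_r", report$ddr$core$mantel_r, report$ddr$satellite$mantel_r)
  if (!is.null(report$assembly)) {
    for (pr in names(report$assembly$core$fractions)) {
      add(paste0("fraction_", pr), report$assembly$core$fractions[[pr]],
          report$assembly$satellite$fractions[[pr]])
    }
  }
  add("niche_breadth", report$niche_breadth$core$mean_B,
      report$niche_breadth$satellite$mean_B,
      report$niche_breadth_test$p_value)
  if (!is.null(report$vulnerability) &&
      !is.null(report$vulnerability$core) &&
      !is.null(report$vulnerability$satellite)) {
    add("vulnerability", report$vulnerability$core,
        report$vulnerability$satellite)
  }
  do.call(rbind, rows)
}
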