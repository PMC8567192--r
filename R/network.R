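#' Build a Spearman co-occurrence network
#'
#' Computes pairwise Spearman rank correlations (midranks, zeros included)
#' between OTUs that occur in at least `min_prevalence` samples, derives
#' p-values from the t approximation, applies Benjamini-Hochberg FDR over all
#' tested pairs, and keeps an edge when `|rho| > rho_threshold` and the
#' adjusted p is below `q_threshold`. Isolated nodes are dropped.
#'
#' @param table a rarefied `comm_table`.
#' @param partition optional `core_satellite_partition` used to label nodes.
#' @param min_prevalence minimum number of samples an OTU must occupy
#'   (default 5).
#' @param rho_threshold absolute correlation threshold (default 0.6). Both
#'   signs pass; set `positive_only = TRUE` to keep positive correlations
#'   only.
#' @param q_threshold FDR-adjusted p threshold (default 0.01).
#' @param positive_only keep only rho > rho_threshold (default FALSE).
#' @return object of class `co_network`: list with `graph` (igraph), `edges`
#'   (otu_a, otu_b, rho, p, q), `nodes` (otu_id, label), and the filter
#'   parameters.
#' @export
build_network <- function(table, partition = NULL, min_prevalence = 5,
                          rho_threshold = 0.6, q_threshold = 0.01,
                          positive_only = FALSE) {
  x <- unclass(table)
  keep <- colSums(x > 0) >= min_prevalence
  x <- x[, keep, drop = FALSE]
  cv <- apply(x, 2, var)
  if (any(cv == 0)) {
    warning(sum(cv == 0), " constant OTU vector(s) excluded", call. = FALSE)
    x <- x[, cv > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 OTUs pass the prevalence filter",
                        call. = FALSE)
  n <- nrow(x)
  rho <- cor(x, method = "spearman")
  ut <- upper.tri(rho)
  rho_v <- rho[ut]
  # two-sided p from the t approximation on n - 2 df
  tstat <- rho_v * sqrt((n - 2) / pmax(1 - rho_v^2, 1e-300))
  p_v <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p_v[abs(rho_v) >= 1] <- 0
  q_v <- p.adjust(p_v, method = "BH")
  pass <- if (positive_only) rho_v > rho_threshold else
    abs(rho_v) > rho_threshold
  pass <- pass & q_v < q_threshold
  ij <- which(ut, arr.ind = TRUE)[pass, , drop = FALSE]
  edges <- data.frame(
    otu_a = colnames(x)[ij[, 1]], otu_b = colnames(x)[ij[, 2]],
    rho = rho_v[pass], p = p_v[pass], q = q_v[pass],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges[, c("otu_a", "otu_b")],
                                     directed = FALSE)
  igraph::E(g)$rho <- edges$rho
  node_ids <- igraph::V(g)$name
  labels <- rep(NA_character_, length(node_ids))
  if (!is.null(partition)) {
    labels <- setNames(partition$otus$label,
                       partition$otus$otu_id)[node_ids]
  }
  structure(
    list(graph = g, edges = edges,
         nodes = data.frame(otu_id = node_ids, label = unname(labels),
                            stringsAsFactors = FALSE),
         params = list(min_prevalence = min_prevalence,
                       rho_threshold = rho_threshold,
                       q_threshold = q_threshold,
                       positive_only = positive_only)),
    class = "co_network"
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (|rho| > %.2f, q < %.3g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$params$rho_threshold, x$params$q_threshold))
  invisible(x)
}

#' Node-level topology with core/satellite comparison
#'
#' Degree, betweenness (unnormalized shortest-path counts), closeness
#' (within each connected component), local clustering (transitivity) and
#' eigenvector centrality (scaled to max 1) per node, on the unweighted
#' graph. When node labels are available, each metric is compared between
#' core and satellite nodes with a Kruskal-Wallis test.
#'
#' @param net a `co_network`.
#' @return list with `nodes` (per-node metrics) and `tests` (per-metric H and
#'   p for core vs satellite; NULL when labels are absent).
#' @export
node_topology <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network", call. = FALSE)
  nodes <- data.frame(
    otu_id = igraph::V(g)$name,
    label = net$nodes$label,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE),
    closeness = suppressWarnings(igraph::closeness(g, mode = "all")),
    transitivity = igraph::transitivity(g, type = "localundirected",
                                        isolates = "zero"),
    eigenvector = igraph::eigen_centrality(g)$vector,
    row.names = NULL, stringsAsFactors = FALSE
  )
  tests <- NULL
  if (any(nodes$label %in% "core") && any(nodes$label %in% "satellite")) {
    metrics <- c("degree", "betweenness", "closeness", "transitivity",
                 "eigenvector")
    tests <- do.call(rbind, lapply(metrics, function(m) {
      a <- nodes[[m]][nodes$label %in% "core"]
      b <- nodes[[m]][nodes$label %in% "satellite"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      kw <- kruskal_wallis(list(core = a, satellite = b))
      data.frame(metric = m, mean_core = mean(a), mean_satellite = mean(b),
                 kw_h = kw$statistic, kw_p = kw$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(nodes = nodes, tests = tests)
}

#' Graph-level topology
#'
#' Node/edge counts, average degree (2E/N), average local clustering
#' coefficient, average shortest path length and diameter (on the largest
#' connected component when the graph is disconnected, with a message),
#' Louvain modularity (best of seeded restarts) and the R-squared of a
#' power-law fit to the degree distribution (OLS on log10 frequency vs log10
#' degree).
#'
#' @param net a `co_network` or an igraph graph.
#' @param modularity_restarts number of Louvain restarts (default 10).
#' @param seed integer seed for the Louvain restarts.
#' @return data.frame with one row of graph metrics.
#' @export
graph_topology <- function(net, modularity_restarts = 10, seed = NULL) {
  g <- if (inherits(net, "co_network")) net$graph else net
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  gc <- g
  if (comp$no > 1) {
    message("graph disconnected; path metrics on largest component (",
            max(comp$csize), " nodes)")
    gc <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
  }
  mod <- with_seed(seed, {
    max(vapply(seq_len(modularity_restarts), function(k) {
      igraph::modularity(igraph::cluster_louvain(g))
    }, numeric(1)))
  })
  deg <- igraph::degree(g)
  tab <- base::table(deg[deg > 0])
  plr2 <- NA_real_
  if (length(tab) >= 3) {
    fit <- lm(log10(as.numeric(tab)) ~ log10(as.numeric(names(tab))))
    plr2 <- summary(fit)$r.squared
  }
  data.frame(
    n_nodes = n, n_edges = m, avg_degree = 2 * m / n,
    avg_clustering = mean(igraph::transitivity(g, type = "localundirected",
                                               isolates = "zero")),
    avg_path_length = igraph::mean_distance(gc),
    diameter = igraph::diameter(gc),
    modularity = mod, power_law_r2 = plr2
  )
}

#' Erdos-Renyi G(n, m) null ensemble
#'
#' Generates uniform random simple graphs with the same node and edge counts
#' as an observed network and summarizes the metrics used for the empirical
#' graph, giving the random expectation that observed topology is compared
#' against.
#'
#' @param n_nodes,n_edges size of each random graph.
#' @param n_graphs ensemble size (default 10000; a few hundred suffice for
#'   2-decimal means).
#' @param seed integer seed.
#' @param metrics subset of `c("clustering", "path_length", "modularity")`.
#' @param modularity_restarts Louvain restarts per graph (default 3).
#' @return list with `per_graph` (data.frame) and `summary` (mean and sd per
#'   metric).
#' @export
er_ensemble <- function(n_nodes, n_edges, n_graphs = 10000, seed = NULL,
                        metrics = c("clustering", "path_length",
                                    "modularity"),
                        modularity_restarts = 3) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("n_edges exceeds the simple-graph maximum", call. = FALSE)
  }
  res <- with_seed(seed, {
    out <- vector("list", n_graphs)
    for (i in seq_len(n_graphs)) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      row <- list()
      if ("clustering" %in% metrics) {
        row$clustering <- mean(igraph::transitivity(
          g, type = "localundirected", isolates = "zero"))
      }
      if ("path_length" %in% metrics) {
        row$path_length <- igraph::mean_distance(g)
      }
      if ("modularity" %in% metrics) {
        row$modularity <- max(vapply(seq_len(modularity_restarts),
                                     function(k) {
          igraph::modularity(igraph::cluster_louvain(g))
        }, numeric(1)))
      }
      out[[i]] <- as.data.frame(row)
    }
    do.call(rbind, out)
  })
  list(per_graph = res,
       summary = data.frame(metric = names(res),
                            mean = vapply(res, mean, numeric(1)),
                            sd = vapply(res, sd, numeric(1)),
                            row.names = NULL, stringsAsFactors = FALSE))
}

# Natural connectivity ln(mean(exp(lambda_i))) of a graph's adjacency
# spectrum; a spectral robustness measure.
natural_connectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(NA_real_)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

#' Robustness under node removal
#'
#' Tracks natural connectivity (normalized to the intact graph) as growing
#' fractions of nodes are removed, either uniformly at random (averaged over
#' `n_rep` draws) or targeting the highest-degree nodes first. Flatter curves
#' indicate a more robust network.
#'
#' @param net a `co_network` or igraph graph.
#' @param removal `"random"` or `"degree"` (targeted).
#' @param fraction_grid fractions of nodes to remove, all < 1.
#' @param n_rep random-removal replicates per fraction (default 10).
#' @param seed integer seed.
#' @return data.frame with `fraction`, `natural_connectivity`,
#'   `relative_connectivity` (and `sd` for random removal).
#' @export
robustness_curve <- function(net, removal = c("random", "degree"),
                             fraction_grid = seq(0, 0.8, by = 0.1),
                             n_rep = 10, seed = NULL) {
  removal <- match.arg(removal)
  g <- if (inherits(net, "co_network")) net$graph else net
  if (any(fraction_grid >= 1)) stop("fractions must be < 1", call. = FALSE)
  n <- igraph::vcount(g)
  base_nc <- natural_connectivity(g)
  deg_order <- order(igraph::degree(g), decreasing = TRUE)
  with_seed(seed, {
    rows <- lapply(fraction_grid, function(f) {
      k <- floor(f * n)
      if (removal == "degree") {
        nc <- natural_connectivity(igraph::delete_vertices(
          g, deg_order[seq_len(k)]))
        data.frame(fraction = f, natural_connectivity = nc,
                   relative_connectivity = nc / base_nc, sd = 0)
      } else {
        vals <- vapply(seq_len(n_rep), function(r) {
          natural_connectivity(igraph::delete_vertices(
            g, sample.int(n, k)))
        }, numeric(1))
        data.frame(fraction = f, natural_connectivity = mean(vals),
                   relative_connectivity = mean(vals) / base_nc,
                   sd = sd(vals))
      }
    })
    do.call(rbind, rows)
  })
}

# Global efficiency: mean over ordered node pairs of 1/shortest-path length,
# 0 for disconnected pairs.
global_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability
#'
#' The maximal relative drop in global efficiency caused by deleting a single
#' node: `max_i (E - E_{-i}) / E`. 0 means no single node matters (for
#' example a complete graph); values near 1 flag a network held together by
#' one hub.
#'
#' @param net a `co_network` or igraph graph with at least 3 nodes.
#' @return scalar in [0, 1].
#' @export
vulnerability <- function(net) {
  g <- if (inherits(net, "co_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  e <- global_efficiency(g)
  if (e == 0) return(0)
  drops <- vapply(seq_len(n), function(i) {
    (e - global_efficiency(igraph::delete_vertices(g, i))) / e
  }, numeric(1))
  max(drops)
}
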