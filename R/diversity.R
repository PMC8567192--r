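#' Per-sample alpha diversity and coverage
#'
#' Computes observed OTU richness, the bias-corrected Chao1 estimator,
#' the Shannon index and Good's coverage for every sample.
#'
#' Chao1 uses the bias-corrected form `S_obs + F1(F1-1)/(2(F2+1))` with F1/F2
#' the singleton/doubleton counts, so it is defined when no doubletons exist.
#' Good's coverage is `1 - F1/N` with N the sample's read total. Shannon is
#' computed on relative abundances with natural log by default.
#'
#' @param table a `comm_table` of integer counts.
#' @param shannon_base base of the logarithm for the Shannon index (default
#'   natural log).
#' @return data.frame with one row per sample: `sample_id`, `n_reads`,
#'   `observed_otus`, `chao1`, `shannon`, `goods_coverage`. Empty samples get
#'   NA with a warning.
#' @export
alpha_diversity <- function(table, shannon_base = exp(1)) {
  x <- unclass(table)
  n_reads <- rowSums(x)
  if (any(n_reads == 0)) {
    warning("empty sample(s): ", paste(rownames(x)[n_reads == 0],
                                       collapse = ", "), call. = FALSE)
  }
  s_obs <- rowSums(x > 0)
  f1 <- rowSums(x == 1)
  f2 <- rowSums(x == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- vegan::diversity(x, index = "shannon", base = shannon_base)
  coverage <- 1 - f1 / n_reads
  empty <- n_reads == 0
  chao1[empty] <- shannon[empty] <- coverage[empty] <- NA_real_
  data.frame(
    sample_id = rownames(x), n_reads = n_reads, observed_otus = s_obs,
    chao1 = chao1, shannon = as.numeric(shannon), goods_coverage = coverage,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Kruskal-Wallis H with midranks and tie correction; used by the exact
# enumeration path where stats::kruskal.test would be needlessly slow.
kw_h_stat <- function(values, group_sizes) {
  n <- length(values)
  r <- rank(values)
  ends <- cumsum(group_sizes)
  starts <- c(1, head(ends, -1) + 1)
  h <- 0
  for (g in seq_along(group_sizes)) {
    rs <- sum(r[starts[g]:ends[g]])
    h <- h + rs^2 / group_sizes[g]
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(r)
  tiecor <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tiecor == 0) return(0)
  h / tiecor
}

#' Kruskal-Wallis rank-sum test
#'
#' Wraps [stats::kruskal.test()] (midranks, tie correction, chi-square
#' approximation with k-1 degrees of freedom). With `exact = TRUE` and two or
#' more small groups, the p-value is instead computed by full enumeration of
#' all assignments of the pooled observations to groups, which is preferable
#' when the total sample size is tiny (the chi-square approximation is
#' anticonservative there).
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @param exact logical; enumerate the exact permutation null (total n <= 8).
#' @return list with elements `statistic` (H), `p_value`, `df`, `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L,
                method = "degenerate"))
  }
  h_obs <- kw_h_stat(values, sizes)
  if (exact) {
    n <- length(values)
    if (n > 8) stop("exact enumeration limited to total n <= 8",
                     call. = FALSE)
    perms <- permute_indices(n)
    hs <- apply(perms, 1, function(idx) kw_h_stat(values[idx], sizes))
    p <- mean(hs >= h_obs - 1e-10)
    return(list(statistic = h_obs, p_value = p, df = length(groups) - 1L,
                method = "exact permutation"))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), method = "chi-square approximation")
}

# All n! orderings of 1..n as a matrix (rows). Small n only.
permute_indices <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permute_indices(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Rank-level taxonomic profiles of the core and satellite sub-communities
#'
#' Aggregates reads to a taxonomic rank within each sub-community, computes
#' relative abundances within each sub-community's reads, and flags taxa whose
#' per-sample within-group relative abundances differ between core and
#' satellite by a Kruskal-Wallis test at p < 0.05.
#'
#' @param table a `comm_table`.
#' @param taxonomy data.frame from [read_taxonomy()].
#' @param rank name of a rank column in `taxonomy`.
#' @param partition a [classify_core_satellite()] result.
#' @param p_threshold significance threshold for flagging (default 0.05).
#' @return data.frame with one row per taxon at `rank`: relative abundance in
#'   each sub-community, Kruskal-Wallis H and p, and a significance flag.
#' @export
taxon_abundance_profile <- function(table, taxonomy, rank, partition,
                                    p_threshold = 0.05) {
  if (!rank %in% names(taxonomy)) {
    stop("rank '", rank, "' not present in taxonomy", call. = FALSE)
  }
  x <- unclass(table)
  lab <- setNames(partition$otus$label, partition$otus$otu_id)[colnames(x)]
  tax <- setNames(as.character(taxonomy[[rank]]), taxonomy$otu_id)[colnames(x)]
  tax[is.na(tax) | tax == ""] <- "Unclassified"
  groups <- c("core", "satellite")
  taxa <- sort(unique(tax[lab %in% groups]))
  if (length(taxa) == 0) stop("no classified OTUs carry rank information",
                              call. = FALSE)
  # per-sample relative abundance of each taxon within each sub-community
  rel <- list()
  for (g in groups) {
    sub <- x[, lab == g & !is.na(lab), drop = FALSE]
    gtot <- rowSums(sub)
    agg <- sapply(taxa, function(tx) {
      rowSums(sub[, tax[lab == g & !is.na(lab)] == tx, drop = FALSE])
    })
    agg <- matrix(agg, nrow = nrow(x), dimnames = list(rownames(x), taxa))
    rel[[g]] <- sweep(agg, 1, pmax(gtot, 1), "/")
  }
  res <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  read_core <- colSums(x[, lab == "core" & !is.na(lab), drop = FALSE])
  read_sat <- colSums(x[, lab == "satellite" & !is.na(lab), drop = FALSE])
  res$rel_abund_core <- sapply(taxa, function(tx) {
    sum(read_core[tax[lab == "core" & !is.na(lab)] == tx]) / sum(read_core)
  })
  res$rel_abund_satellite <- sapply(taxa, function(tx) {
    sum(read_sat[tax[lab == "satellite" & !is.na(lab)] == tx]) / sum(read_sat)
  })
  kw <- lapply(taxa, function(tx) {
    kruskal_wallis(list(rel$core[, tx], rel$satellite[, tx]))
  })
  res$kw_h <- sapply(kw, `[[`, "statistic")
  res$kw_p <- sapply(kw, `[[`, "p_value")
  res$significant <- res$kw_p < p_threshold
  res
}
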