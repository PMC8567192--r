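# Patristic tip-pair distances ordered to the community table's OTU columns.
cophenetic_for <- function(table, tree) {
  tips <- colnames(table)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)",
                                          length(missing) - 5),
         call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  d[tips, tips, drop = FALSE]
}

# Fast column-parallel minima of a matrix, by row and by column.
row_mins <- function(m) do.call(pmin, lapply(seq_len(ncol(m)),
                                             function(j) m[, j]))
col_mins <- function(m) do.call(pmin, lapply(seq_len(nrow(m)),
                                             function(i) m[i, ]))

# betaMNTD for one pair given the patristic matrix and per-sample
# indices/weights. ia/ib index into d's rows/cols; wa/wb are relative
# abundances over those indices (summing to 1) or NULL for unweighted.
bmntd_pair <- function(d, ia, ib, wa, wb) {
  if (!length(ia) || !length(ib)) return(NA_real_)
  sub <- d[ia, ib, drop = FALSE]
  mins_a <- row_mins(sub)  # nearest taxon in B for each taxon in A
  mins_b <- col_mins(sub)  # nearest taxon in A for each taxon in B
  if (is.null(wa)) {
    (mean(mins_a) + mean(mins_b)) / 2
  } else {
    (sum(wa * mins_a) + sum(wb * mins_b)) / 2
  }
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For every taxon in one community, the patristic distance to its nearest
#' relative in the other community is found (0 for taxa shared by both);
#' betaMNTD averages these nearest-taxon distances over both directions,
#' weighting each taxon by its relative abundance when `weighted = TRUE`
#' (the Stegen convention).
#'
#' @param table a `comm_table`; all OTUs present in the pair must be tree tips.
#' @param tree a rooted `phylo` with branch lengths.
#' @param pair length-2 vector of sample ids (or row indices).
#' @param weighted abundance-weight the taxon contributions (default TRUE).
#' @return non-negative scalar; 0 for identical communities.
#' @export
beta_mntd <- function(table, tree, pair, weighted = TRUE) {
  x <- unclass(table)
  d <- cophenetic_for(x, tree)
  a <- x[pair[1], ]; b <- x[pair[2], ]
  ia <- which(a > 0); ib <- which(b > 0)
  if (!length(ia) || !length(ib)) stop("empty community in pair",
                                       call. = FALSE)
  wa <- wb <- NULL
  if (weighted) {
    wa <- a[ia] / sum(a[ia]); wb <- b[ib] / sum(b[ib])
  }
  bmntd_pair(d, ia, ib, wa, wb)
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardizes the observed betaMNTD of a sample pair against a null
#' distribution obtained by shuffling taxon labels across the tips of the
#' whole tree (which preserves both community matrices exactly):
#' `betaNTI = (obs - mean(null)) / sd(null)`. Values at or beyond +/-2
#' indicate phylogenetic turnover more extreme than expected by chance,
#' i.e. selection.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip-shuffle randomizations (default 999).
#' @param seed integer seed.
#' @return scalar betaNTI; NA with a warning when the null has zero spread.
#' @export
beta_nti <- function(table, tree, pair, n_null = 999, seed = NULL,
                     weighted = TRUE) {
  x <- unclass(table)
  d <- cophenetic_for(x, tree)
  a <- x[pair[1], ]; b <- x[pair[2], ]
  ia <- which(a > 0); ib <- which(b > 0)
  wa <- wb <- NULL
  if (weighted) {
    wa <- a[ia] / sum(a[ia]); wb <- b[ib] / sum(b[ib])
  }
  obs <- bmntd_pair(d, ia, ib, wa, wb)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      p <- sample.int(ncol(d))
      bmntd_pair(d, p[ia], p[ib], wa, wb)
    }, numeric(1))
  })
  s <- sd(nulls)
  if (!is.finite(s) || s == 0) {
    warning("null betaMNTD has zero spread; betaNTI undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (obs - mean(nulls)) / s
}

# Draw one null community: observed richness and read total are preserved;
# membership drawn with probability proportional to metacommunity occupancy,
# then reads filled with probability proportional to metacommunity relative
# abundance (each member keeps at least one read).
rc_null_sample <- function(richness, n_reads, occ_w, ab_w) {
  n_taxa <- length(occ_w)
  members <- sample.int(n_taxa, richness, prob = occ_w)
  counts <- numeric(n_taxa)
  counts[members] <- 1
  extra <- n_reads - richness
  if (extra > 0) {
    add <- rmultinom(1, extra, prob = ab_w[members])[, 1]
    counts[members] <- counts[members] + add
  }
  counts
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' Compares the observed Bray-Curtis dissimilarity of a sample pair against a
#' null distribution built by repeatedly reassembling both samples at their
#' observed richness and read totals, drawing members with probability
#' proportional to metacommunity occupancy and filling reads proportionally
#' to metacommunity relative abundance. The rank of the observation within
#' the null is rescaled to
#' `RC = 2 * ((n_below + 0.5 * n_ties) / n_null) - 1`, bounded in [-1, 1];
#' values at or above 0.95 (with |betaNTI| < 2) indicate dispersal limitation
#' and values below -0.95 homogenizing dispersal.
#'
#' @param table a rarefied `comm_table` (the metacommunity for the null).
#' @param pair length-2 vector of sample ids (or row indices).
#' @param n_null number of null draws (>= 99; default 999).
#' @param seed integer seed.
#' @return scalar in [-1, 1].
#' @export
raup_crick_bray <- function(table, pair, n_null = 999, seed = NULL) {
  if (n_null < 99) stop("n_null must be at least 99", call. = FALSE)
  x <- unclass(table)
  occ_w <- colSums(x > 0)
  ab_w <- colSums(x)
  a <- x[pair[1], ]; b <- x[pair[2], ]
  obs <- bc_pair(a, b)
  ra <- sum(a > 0); rb <- sum(b > 0)
  na <- sum(a); nb <- sum(b)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      bc_pair(rc_null_sample(ra, na, occ_w, ab_w),
              rc_null_sample(rb, nb, occ_w, ab_w))
    }, numeric(1))
  })
  rc_from_rank(obs, nulls)
}

bc_pair <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  sum(abs(a - b)) / s
}

rc_from_rank <- function(obs, nulls) {
  eps <- 1e-12
  n_lt <- sum(nulls < obs - eps)
  n_eq <- sum(abs(nulls - obs) <= eps)
  2 * ((n_lt + 0.5 * n_eq) / length(nulls)) - 1
}

#' Classify assembly processes from betaNTI and Raup-Crick values
#'
#' Applies the standard two-step decision rule per sample pair:
#' betaNTI <= -2 homogeneous selection; betaNTI >= +2 heterogeneous
#' selection; otherwise RC >= 0.95 dispersal limitation, RC < -0.95
#' homogenizing dispersal, and |RC| < 0.95 undominated. Pairs with a missing
#' metric are excluded from the fractions (with a message).
#'
#' @param beta_nti numeric vector of betaNTI values, one per sample pair.
#' @param rc_bray numeric vector of Raup-Crick values, same length.
#' @param pairs optional data.frame of pair identifiers to carry through.
#' @return object of class `assembly_result`: list with `pairs` (per-pair
#'   metrics and process label) and `fractions` (named proportions over
#'   classified pairs, summing to 1).
#' @export
classify_processes <- function(beta_nti, rc_bray, pairs = NULL) {
  stopifnot(length(beta_nti) == length(rc_bray))
  process <- rep(NA_character_, length(beta_nti))
  ok <- is.finite(beta_nti) & is.finite(rc_bray)
  if (any(!ok)) message(sum(!ok), " pair(s) with missing metrics excluded")
  process[ok & beta_nti <= -2] <- "homogeneous_selection"
  process[ok & beta_nti >= 2] <- "heterogeneous_selection"
  mid <- ok & abs(beta_nti) < 2
  process[mid & rc_bray >= 0.95] <- "dispersal_limitation"
  process[mid & rc_bray < -0.95] <- "homogenizing_dispersal"
  process[mid & abs(rc_bray) < 0.95] <- "undominated"
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "undominated")
  tab <- base::table(factor(process, levels = lev))
  fractions <- as.vector(tab) / max(sum(tab), 1)
  names(fractions) <- lev
  out <- data.frame(beta_nti = beta_nti, rc_bray = rc_bray,
                    process = process, stringsAsFactors = FALSE)
  if (!is.null(pairs)) out <- cbind(pairs, out)
  structure(list(pairs = out, fractions = fractions),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly processes over", nrow(x$pairs), "sample pairs\n")
  f <- x$fractions[x$fractions > 0]
  if (length(f) == 0) cat("  (no process classification)\n")
  for (nm in names(f)) cat(sprintf("  %-24s %5.1f%%\n", nm, 100 * f[nm]))
  invisible(x)
}

#' Per-pair assembly analysis over a whole table
#'
#' Computes betaMNTD, betaNTI and Raup-Crick for every unordered sample pair
#' and classifies the assembly process of each. Null randomizations are
#' shared across pairs for efficiency: each tip-shuffle (betaNTI) and each
#' per-sample null assembly (Raup-Crick) is drawn once per replicate and
#' reused for all pairs, which leaves every pair's marginal null distribution
#' unchanged.
#'
#' @param table a rarefied `comm_table`.
#' @param tree a rooted `phylo` covering all OTUs.
#' @param n_null randomizations for both null models (default 999).
#' @param seed integer seed.
#' @param weighted abundance-weight betaMNTD (default TRUE).
#' @param include_rc also run the Raup-Crick null (default TRUE). When FALSE
#'   only betaMNTD/betaNTI are computed, `rc_bray` is NA, and no process
#'   classification is attempted — useful when only the selection signal is
#'   of interest.
#' @return an `assembly_result` whose `pairs` element also carries
#'   `beta_mntd` and the sample ids.
#' @export
assembly_analysis <- function(table, tree, n_null = 999, seed = NULL,
                              weighted = TRUE, include_rc = TRUE) {
  x <- unclass(table)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  d <- cophenetic_for(x, tree)
  idx <- lapply(seq_len(n), function(i) which(x[i, ] > 0))
  wts <- lapply(seq_len(n), function(i) {
    if (!weighted) return(NULL)
    v <- x[i, idx[[i]]]; v / sum(v)
  })
  pr <- pair_indices(n)
  obs <- vapply(seq_len(nrow(pr)), function(k) {
    bmntd_pair(d, idx[[pr[k, 1]]], idx[[pr[k, 2]]],
               wts[[pr[k, 1]]], wts[[pr[k, 2]]])
  }, numeric(1))

  with_seed(seed, {
    # betaNTI: one tip permutation per replicate, applied to every pair
    null_sum <- numeric(nrow(pr))
    null_sq <- numeric(nrow(pr))
    for (r in seq_len(n_null)) {
      p <- sample.int(ncol(d))
      nb <- vapply(seq_len(nrow(pr)), function(k) {
        bmntd_pair(d, p[idx[[pr[k, 1]]]], p[idx[[pr[k, 2]]]],
                   wts[[pr[k, 1]]], wts[[pr[k, 2]]])
      }, numeric(1))
      null_sum <- null_sum + nb
      null_sq <- null_sq + nb^2
    }
    null_mean <- null_sum / n_null
    null_sd <- sqrt(pmax(null_sq / n_null - null_mean^2, 0) *
                      n_null / (n_null - 1))
    bnti <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, NA_real_)

    pairs_df <- data.frame(
      sample_a = rownames(x)[pr[, 1]], sample_b = rownames(x)[pr[, 2]],
      beta_mntd = obs, stringsAsFactors = FALSE
    )
    if (!include_rc) {
      return(structure(
        list(pairs = cbind(pairs_df,
                           data.frame(beta_nti = bnti, rc_bray = NA_real_,
                                      process = NA_character_,
                                      stringsAsFactors = FALSE)),
             fractions = NULL),
        class = "assembly_result"))
    }

    # Raup-Crick: n_null null versions of each sample, paired per replicate
    occ_w <- colSums(x > 0)
    ab_w <- colSums(x)
    rich <- rowSums(x > 0)
    reads <- rowSums(x)
    rc_ge <- matrix(0, nrow(pr), 2,
                    dimnames = list(NULL, c("lt", "eq")))
    obs_bc <- vapply(seq_len(nrow(pr)), function(k) {
      bc_pair(x[pr[k, 1], ], x[pr[k, 2], ])
    }, numeric(1))
    eps <- 1e-12
    for (r in seq_len(n_null)) {
      nullx <- vapply(seq_len(n), function(i) {
        rc_null_sample(rich[i], reads[i], occ_w, ab_w)
      }, numeric(ncol(x)))
      nbc <- vapply(seq_len(nrow(pr)), function(k) {
        bc_pair(nullx[, pr[k, 1]], nullx[, pr[k, 2]])
      }, numeric(1))
      rc_ge[, "lt"] <- rc_ge[, "lt"] + (nbc < obs_bc - eps)
      rc_ge[, "eq"] <- rc_ge[, "eq"] + (abs(nbc - obs_bc) <= eps)
    }
    rc <- 2 * ((rc_ge[, "lt"] + 0.5 * rc_ge[, "eq"]) / n_null) - 1
    classify_processes(bnti, rc, pairs = pairs_df)
  })
}

#' Distance-decay fit restricted to pairs under one assembly process
#'
#' Refits the distance-decay regression using only the sample pairs assigned
#' to a given process (for example dispersal limitation), so the spatial
#' signal of each process can be inspected separately. Restricting to all
#' pairs reproduces the unconditioned [ddr_fit()].
#'
#' @param assembly an `assembly_result` from [assembly_analysis()].
#' @param geo,bc distance matrices as in [ddr_fit()].
#' @param process process label to keep, or `"all"`.
#' @param n_perm,seed passed to [ddr_fit()].
#' @return a `ddr_fit`.
#' @export
process_conditioned_ddr <- function(assembly, geo, bc, process,
                                    n_perm = 999, seed = NULL) {
  pairs <- assembly$pairs
  labels <- attr(geo, "Labels")
  n <- attr(geo, "Size")
  pos <- function(a, b) {
    i <- match(a, labels); j <- match(b, labels)
    lo <- pmin(i, j); hi <- pmax(i, j)
    n * (lo - 1) - lo * (lo - 1) / 2 + hi - lo
  }
  keep <- if (identical(process, "all")) {
    rep(TRUE, nrow(pairs))
  } else {
    !is.na(pairs$process) & pairs$process == process
  }
  if (sum(keep) < 3) {
    stop("fewer than 3 pairs with process '", process, "'", call. = FALSE)
  }
  ddr_fit(geo, bc, n_perm = n_perm, seed = seed,
          pair_subset = pos(pairs$sample_a[keep], pairs$sample_b[keep]))
}

#' Levins habitat niche breadth
#'
#' `B_j = 1 / sum_i P_ij^2` with `P_ij` the proportion of OTU j's reads found
#' in sample i (so the proportions sum to 1 over samples). B ranges from 1
#' (all reads in one sample: perfect habitat specialist) to the number of
#' samples (perfectly even occupancy: generalist).
#'
#' @param table a `comm_table`.
#' @param otu_subset optional OTU ids to restrict to (for example the core
#'   members); OTUs with zero total reads are excluded with a warning.
#' @return list with `per_otu` (data.frame of `otu_id`, `B`) and `mean_B`.
#' @export
niche_breadth <- function(table, otu_subset = NULL) {
  x <- unclass(table)
  if (!is.null(otu_subset)) x <- x[, otu_subset, drop = FALSE]
  tot <- colSums(x)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " OTU(s) with zero reads excluded", call. = FALSE)
    x <- x[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- sweep(x, 2, tot, "/")
  b <- 1 / colSums(p^2)
  list(per_otu = data.frame(otu_id = colnames(x), B = as.numeric(b),
                            row.names = NULL, stringsAsFactors = FALSE),
       mean_B = mean(b))
}
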