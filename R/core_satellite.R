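#' Index of dispersion of a taxon's counts across samples
#'
#' The variance-to-mean ratio of a taxon's counts over all samples (zeros
#' included), with the sample variance (n-1 denominator). Values near 1 are
#' consistent with random (Poisson) placement across sites; values above the
#' chi-square confidence limit indicate spatial aggregation.
#'
#' @param counts non-negative integer vector of a taxon's counts across all
#'   samples (length >= 2, not all zero).
#' @return the dispersion index, a non-negative real.
#' @examples
#' dispersion_index(c(20, 0, 20, 0)) # 13.33
#' @export
dispersion_index <- function(counts) {
  if (length(counts) < 2) stop("need counts from at least 2 samples",
                               call. = FALSE)
  if (all(counts == 0)) {
    stop("all-zero vector: dispersion undefined", call. = FALSE)
  }
  var(counts) / mean(counts)
}

#' Partition OTUs into core and satellite sub-communities
#'
#' Tests each OTU's index of dispersion against the upper tail of the
#' chi-square distribution: with n samples the confidence limit is
#' `qchisq(1 - alpha_tail, df) / df` with `df = n - 1`. OTUs whose dispersion
#' exceeds the limit are non-randomly aggregated "core" taxa; the remaining
#' classified OTUs are randomly distributed "satellite" taxa. OTUs occurring
#' in at most one sample have no spatial variance to test and are excluded.
#'
#' @param table a rarefied `comm_table` with at least 3 samples.
#' @param alpha_tail upper-tail probability of the chi-square limit
#'   (default 0.025, the conventional 2.5% confidence line).
#' @param df_mode `"global"` uses df = n_samples - 1 for every OTU (one
#'   confidence line); `"occurrence"` uses each OTU's occurrence - 1.
#' @return object of class `core_satellite_partition`: list with `otus` (a
#'   data.frame of occurrence, mean abundance, variance, dispersion index and
#'   label per OTU), `chi2_limit`, `n_samples`, `alpha_tail`.
#' @examples
#' tab <- community_table(matrix(c(20, 0, 20, 0, 1, 1, 1, 0), 4, 2,
#'   dimnames = list(paste0("s", 1:4), c("agg", "rand"))))
#' classify_core_satellite(tab)
#' @export
classify_core_satellite <- function(table, alpha_tail = 0.025,
                                    df_mode = c("global", "occurrence")) {
  df_mode <- match.arg(df_mode)
  x <- unclass(table)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  occurrence <- colSums(x > 0)
  mean_ab <- colMeans(x)
  variance <- apply(x, 2, var)
  disp <- ifelse(mean_ab > 0, variance / mean_ab, NA_real_)
  chi2_limit <- qchisq(1 - alpha_tail, df = n - 1) / (n - 1)
  limit <- if (df_mode == "global") {
    rep(chi2_limit, ncol(x))
  } else {
    ifelse(occurrence > 1, qchisq(1 - alpha_tail, df = occurrence - 1) /
             (occurrence - 1), NA_real_)
  }
  label <- ifelse(occurrence <= 1, "excluded",
                  ifelse(disp > limit, "core", "satellite"))
  otus <- data.frame(
    otu_id = colnames(x), occurrence = occurrence, mean_abundance = mean_ab,
    variance = variance, dispersion_index = disp, label = label,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(otus = otus, chi2_limit = chi2_limit, n_samples = n,
         alpha_tail = alpha_tail, df_mode = df_mode),
    class = "core_satellite_partition"
  )
}

#' @export
print.core_satellite_partition <- function(x, ...) {
  s <- partition_summary(x)
  cat(sprintf(
    paste0("Core/satellite partition of %d OTUs over %d samples\n",
           "  chi-square limit (upper %.3g%%): %.4f\n",
           "  core: %d (%.2f%%)  satellite: %d (%.2f%%)  excluded: %d\n"),
    s$n_otus, x$n_samples, 100 * x$alpha_tail, x$chi2_limit,
    s$counts[["core"]], s$pct_of_all[["core"]],
    s$counts[["satellite"]], s$pct_of_all[["satellite"]],
    s$counts[["excluded"]]
  ))
  invisible(x)
}

#' Summarise a partition (counts, read totals, percentages)
#'
#' Reports OTU counts and read totals per label, with percentages both of all
#' OTUs/reads and of the classified (non-excluded) subset.
#'
#' @param partition a `core_satellite_partition`.
#' @param table optional `comm_table` to compute read totals per label; when
#'   omitted, mean abundances stored in the partition are used (equivalent for
#'   percentages).
#' @return list with `n_otus`, `counts`, `pct_of_all`, `pct_of_classified`,
#'   `reads`, `read_pct`.
#' @export
partition_summary <- function(partition, table = NULL) {
  lab <- factor(partition$otus$label,
                levels = c("core", "satellite", "excluded"))
  counts <- base::table(lab)
  n_otus <- nrow(partition$otus)
  reads_per_otu <- if (!is.null(table)) {
    colSums(unclass(table))[partition$otus$otu_id]
  } else {
    partition$otus$mean_abundance * partition$n_samples
  }
  reads <- tapply(reads_per_otu, lab, sum, default = 0)
  classified <- sum(counts[c("core", "satellite")])
  list(
    n_otus = n_otus,
    counts = as.vector(counts) |> setNames(levels(lab)),
    pct_of_all = round(100 * as.vector(counts) / n_otus, 2) |>
      setNames(levels(lab)),
    pct_of_classified = round(100 * as.vector(counts) / classified, 2) |>
      setNames(levels(lab)),
    reads = as.vector(reads) |> setNames(levels(lab)),
    read_pct = round(100 * as.vector(reads) / sum(reads_per_otu), 2) |>
      setNames(levels(lab))
  )
}

#' Abundance-occupancy relationship
#'
#' Ordinary least squares regression of occupancy (number of samples an OTU
#' occupies) on log10 mean relative abundance — the classic positive
#' abundance-occupancy relationship of metacommunity ecology.
#'
#' @param table a `comm_table`.
#' @return list with `points` (per-OTU occurrence and mean relative
#'   abundance), `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
abundance_occupancy <- function(table) {
  x <- unclass(table)
  occurrence <- colSums(x > 0)
  keep <- occurrence >= 1
  if (sum(keep) < 3) stop("need at least 3 OTUs with occurrence >= 1",
                          call. = FALSE)
  rel <- sweep(x, 1, rowSums(x), "/")
  mean_rel <- colMeans(rel)[keep]
  occ <- occurrence[keep]
  fit <- lm(occ ~ log10(mean_rel))
  sm <- summary(fit)
  list(
    points = data.frame(otu_id = colnames(x)[keep], occurrence = occ,
                        mean_relative_abundance = mean_rel, row.names = NULL,
                        stringsAsFactors = FALSE),
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared, p_value = sm$coefficients[2, 4]
  )
}
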