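#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity `sum|a_i - b_i| / sum(a_i + b_i)` over a
#' subset of OTUs (for example the core or satellite members). A sample with
#' zero reads within the subset is assigned dissimilarity 1 to every other
#' sample, with a message.
#'
#' @param table a rarefied `comm_table`.
#' @param otu_subset character vector of OTU ids to restrict to; NULL uses all.
#' @return a [stats::dist] object labelled by sample ids.
#' @export
bray_curtis <- function(table, otu_subset = NULL) {
  x <- unclass(table)
  if (!is.null(otu_subset)) {
    missing <- setdiff(otu_subset, colnames(x))
    if (length(missing)) {
      stop("OTUs not in table: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    x <- x[, otu_subset, drop = FALSE]
  }
  empty <- rowSums(x) == 0
  # empty rows are handled below (dissimilarity 1 by contract); silence
  # vegdist's complaint about them
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (any(empty)) {
    message(sum(empty), " sample(s) with zero reads in subset; ",
            "dissimilarity to them set to 1")
    m <- as.matrix(d)
    m[empty, ] <- 1
    m[, empty] <- 1
    diag(m) <- 0
    d <- as.dist(m)
  }
  d
}

#' Great-circle distances between samples
#'
#' Haversine distances in kilometres (Earth radius 6371.0 km) from decimal
#' latitude/longitude coordinates.
#'
#' @param meta data.frame with `sample_id`, `latitude`, `longitude`.
#' @return a [stats::dist] object of distances in km, labelled by sample id.
#' @export
geo_distance <- function(meta) {
  meta <- validate_metadata(meta)
  bad <- !is.finite(meta$latitude) | !is.finite(meta$longitude)
  if (any(bad)) {
    stop("missing coordinates for: ",
         paste(meta$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  m <- geosphere::distm(cbind(meta$longitude, meta$latitude),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = 6371000)
                        }) / 1000
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  as.dist(m)
}

# Indices (i, j), i < j, of the unordered pairs behind a dist object, in the
# order dist stores them (column-major lower triangle).
pair_indices <- function(n) {
  j <- rep(seq_len(n - 1), times = (n - 1):1)
  i <- unlist(lapply(seq_len(n - 1), function(k) seq(k + 1, n)))
  cbind(first = j, second = i)
}

check_same_labels <- function(a, b) {
  la <- attr(a, "Labels"); lb <- attr(b, "Labels")
  if (!identical(la, lb)) {
    stop("distance matrices have mismatched sample labels", call. = FALSE)
  }
}

ols_slope <- function(x, y) {
  cov(x, y) / var(x)
}

#' Distance-decay regression with Mantel test
#'
#' Regresses ln(Bray-Curtis dissimilarity) on ln(geographic distance + 1) over
#' all unordered sample pairs, and tests the matrix association with a
#' one-tailed Mantel permutation test (rows/columns of the geographic matrix
#' permuted jointly). Pairs with zero dissimilarity are dropped from both the
#' regression and the Mantel vectors (their log is undefined); a message
#' reports how many.
#'
#' @param geo `dist` of geographic distances in km (see [geo_distance()]).
#' @param bc `dist` of Bray-Curtis dissimilarities with matching labels.
#' @param n_perm number of Mantel permutations (>= 99; default 999).
#' @param seed integer seed for the permutations.
#' @param pair_subset optional logical/integer index into the pair vector
#'   (dist order) restricting the fit to a subset of pairs, for example pairs
#'   assigned to one assembly process.
#' @return object of class `ddr_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `mantel_r`, `mantel_p`, `n_pairs`, and `pairs` (a data.frame
#'   of the pair vectors used).
#' @export
ddr_fit <- function(geo, bc, n_perm = 999, seed = NULL, pair_subset = NULL) {
  check_same_labels(geo, bc)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  n <- attr(geo, "Size")
  idx <- pair_indices(n)
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(pair_subset)) {
    sel <- rep(FALSE, nrow(idx))
    sel[pair_subset] <- TRUE
    keep <- keep & sel
  }
  gvec <- as.vector(geo)
  bvec <- as.vector(bc)
  zero <- bvec == 0
  if (any(zero & keep)) {
    message("dropping ", sum(zero & keep),
            " pair(s) with zero dissimilarity (ln undefined)")
  }
  keep <- keep & !zero
  if (sum(keep) < 3) stop("fewer than 3 usable pairs", call. = FALSE)
  x <- log(gvec[keep] + 1)
  y <- log(bvec[keep])
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in a pair vector; fit undefined", call. = FALSE)
  }
  slope <- ols_slope(x, y)
  intercept <- mean(y) - slope * mean(x)
  r <- cor(x, y)
  # Mantel: permute sample labels of the geographic matrix, keep the pair set
  gm <- as.matrix(geo)
  ik <- idx[keep, , drop = FALSE]
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      xp <- log(gm[cbind(p[ik[, 1]], p[ik[, 2]])] + 1)
      if (var(xp) == 0) return(-Inf)
      cor(xp, y)
    }, numeric(1))
  })
  mantel_p <- (1 + sum(perm_r >= r)) / (n_perm + 1)
  structure(
    list(slope = slope, intercept = intercept, r_squared = r^2,
         mantel_r = r, mantel_p = mantel_p, n_pairs = sum(keep),
         pairs = data.frame(
           sample_a = attr(geo, "Labels")[ik[, 1]],
           sample_b = attr(geo, "Labels")[ik[, 2]],
           geo_km = gvec[keep], bray_curtis = bvec[keep],
           ln_geo = x, ln_bc = y, stringsAsFactors = FALSE
         )),
    class = "ddr_fit"
  )
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat(sprintf(
    "Distance-decay fit over %d pairs\n  slope %.4f  R2 %.3f  Mantel r %.3f (p = %.4g)\n",
    x$n_pairs, x$slope, x$r_squared, x$mantel_r, x$mantel_p
  ))
  invisible(x)
}

#' Permutation test for a difference between two distance-decay slopes
#'
#' Tests whether the regression slopes of two pair sets differ, by randomly
#' reassigning pairs between the two groups (preserving group sizes),
#' refitting both slopes each time, and comparing |delta slope| against the
#' permutation distribution (two-sided, +1-corrected).
#'
#' @param pairs_a,pairs_b data.frames with columns `ln_geo` and `ln_bc` (as
#'   produced in a [ddr_fit()]'s `pairs` element).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `delta_slope` (slope_a - slope_b), `p_value`, `n_perm`.
#' @export
slope_difference_test <- function(pairs_a, pairs_b, n_perm = 999,
                                  seed = NULL) {
  xa <- pairs_a$ln_geo; ya <- pairs_a$ln_bc
  xb <- pairs_b$ln_geo; yb <- pairs_b$ln_bc
  na <- length(xa)
  x <- c(xa, xb); y <- c(ya, yb)
  obs <- ols_slope(xa, ya) - ols_slope(xb, yb)
  if (isTRUE(all.equal(c(xa, ya), c(xb, yb)))) {
    return(list(delta_slope = 0, p_value = 1, n_perm = n_perm))
  }
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      take <- sample.int(length(x), na)
      ols_slope(x[take], y[take]) - ols_slope(x[-take], y[-take])
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(delta_slope = obs, p_value = p, n_perm = n_perm)
}
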