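# Small builders shared across test files. Everything is generated in code;
# no fixture files.

make_table <- function(counts, samples = NULL, otus = NULL) {
  m <- matrix(counts$values, nrow = counts$n_samples, byrow = TRUE)
  community_table(m,
                  sample_ids = samples %||% paste0("s", seq_len(nrow(m))),
                  otu_ids = otus %||% paste0("o", seq_len(ncol(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# counts helper: list(n_samples, values by row)
tbl <- function(n_samples, ...) {
  make_table(list(n_samples = n_samples, values = c(...)))
}

# two-tip cherry with patristic distance 0.8 between t1 and t2
cherry_tree <- function() ape::read.tree(text = "(t1:0.4,t2:0.4);")

random_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = paste0("s", seq_len(n)),
             latitude = runif(n, 29, 34), longitude = runif(n, 80, 96),
             stringsAsFactors = FALSE)
}

# independent brute-force betaMNTD: explicit double loops, no shared code
# with the package's vectorized implementation
bmntd_brute <- function(xa, xb, d, weighted = TRUE) {
  ia <- which(xa > 0); ib <- which(xb > 0)
  mins_a <- numeric(length(ia)); mins_b <- numeric(length(ib))
  for (u in seq_along(ia)) {
    best <- Inf
    for (v in seq_along(ib)) best <- min(best, d[ia[u], ib[v]])
    mins_a[u] <- best
  }
  for (v in seq_along(ib)) {
    best <- Inf
    for (u in seq_along(ia)) best <- min(best, d[ia[u], ib[v]])
    mins_b[v] <- best
  }
  if (weighted) {
    wa <- xa[ia] / sum(xa[ia]); wb <- xb[ib] / sum(xb[ib])
    (sum(wa * mins_a) + sum(wb * mins_b)) / 2
  } else {
    (mean(mins_a) + mean(mins_b)) / 2
  }
}

# exact two-group Kruskal-Wallis permutation p via the Wilcoxon rank-sum
# null distribution (independent of the package's enumeration)
kw_exact_wilcox <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                      correct = FALSE))$p.value
}
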