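test_that("betaMNTD matches hand cases and is symmetric", {
  tree <- cherry_tree()
  tab <- community_table(matrix(c(3L, 0L, 0L, 5L), 2, 2, byrow = TRUE,
                                dimnames = list(c("sa", "sb"),
                                                c("t1", "t2"))))
  expect_equal(beta_mntd(tab, tree, c("sa", "sb")), 0.8)
  expect_equal(beta_mntd(tab, tree, c("sb", "sa")), 0.8)
  # identical communities: every nearest neighbour is self
  tab2 <- community_table(matrix(c(2L, 4L, 2L, 4L), 2, 2, byrow = TRUE,
                                 dimnames = list(c("sa", "sb"),
                                                 c("t1", "t2"))))
  expect_equal(beta_mntd(tab2, tree, c("sa", "sb")), 0)
  # taxa missing from the tree are reported
  tab3 <- community_table(matrix(1L, 2, 2,
                                 dimnames = list(c("sa", "sb"),
                                                 c("t1", "zz"))))
  expect_error(beta_mntd(tab3, tree, c("sa", "sb")), "zz")
})

test_that("betaMNTD equals an independent brute-force double loop", {
  set.seed(21)
  tree <- ape::rtree(16)
  d <- ape::cophenetic.phylo(tree)
  for (rep in 1:50) {
    xa <- rpois(16, 2); xb <- rpois(16, 2)
    xa[sample(16, 1)] <- xa[sample(16, 1)] + 1  # non-empty
    xb[sample(16, 1)] <- xb[sample(16, 1)] + 1
    tab <- community_table(matrix(c(xa, xb), 2, byrow = TRUE,
                                  dimnames = list(c("A", "B"),
                                                  tree$tip.label)))
    for (w in c(TRUE, FALSE)) {
      got <- beta_mntd(tab, tree, c("A", "B"), weighted = w)
      want <- bmntd_brute(xa, xb, d[tree$tip.label, tree$tip.label],
                          weighted = w)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("betaMNTD agrees with picante's comdistnt", {
  set.seed(22)
  tree <- ape::rtree(12)
  x <- matrix(rpois(60, 3), 5, 12, dimnames = list(paste0("s", 1:5),
                                                   tree$tip.label))
  x[cbind(1:5, sample(12, 5))] <- x[cbind(1:5, sample(12, 5))] + 1L
  tab <- community_table(x)
  ref <- as.matrix(picante::comdistnt(x, ape::cophenetic.phylo(tree),
                                      abundance.weighted = TRUE))
  for (pr in list(c(1, 2), c(2, 5), c(3, 4))) {
    expect_equal(beta_mntd(tab, tree, pr),
                 ref[pr[1], pr[2]], tolerance = 1e-10)
  }
})

test_that("betaNTI is deterministic, scale-invariant, and flags degenerate nulls", {
  set.seed(23)
  tree <- ape::rtree(14)
  # sparse, partially overlapping communities so the null has spread
  x <- matrix(0L, 2, 14, dimnames = list(c("A", "B"), tree$tip.label))
  x[1, 1:6] <- c(3L, 1L, 4L, 2L, 1L, 5L)
  x[2, 5:11] <- c(2L, 3L, 1L, 4L, 1L, 2L, 3L)
  tab <- community_table(x)
  b1 <- beta_nti(tab, tree, c("A", "B"), n_null = 199, seed = 9)
  b2 <- beta_nti(tab, tree, c("A", "B"), n_null = 199, seed = 9)
  expect_true(is.finite(b1))
  expect_identical(b1, b2)
  # uniform branch-length scaling leaves betaNTI unchanged
  tree2 <- tree; tree2$edge.length <- tree2$edge.length * 7
  b3 <- beta_nti(tab, tree2, c("A", "B"), n_null = 199, seed = 9)
  expect_equal(b1, b3, tolerance = 1e-10)
  # star tree: all inter-tip distances equal, null spread is zero
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  xs <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L), 2, 4, byrow = TRUE,
               dimnames = list(c("A", "B"), paste0("t", 1:4)))
  expect_warning(bs <- beta_nti(community_table(xs), star, c("A", "B"),
                                n_null = 99, seed = 1), "zero spread")
  expect_true(is.na(bs))
})

test_that("Raup-Crick hits its bounds and degenerate cases", {
  set.seed(24)
  # extreme rank: two disjoint specialists against a metacommunity in which
  # most samples share the dominant taxa
  x <- rbind(A = c(40L, 0L, 0L, 10L), B = c(0L, 40L, 0L, 10L),
             C = c(20L, 20L, 5L, 5L), D = c(20L, 18L, 6L, 6L),
             E = c(19L, 21L, 5L, 5L))
  colnames(x) <- paste0("o", 1:4)
  tab <- community_table(x)
  rc <- raup_crick_bray(tab, c("A", "B"), n_null = 199, seed = 3)
  expect_true(rc >= -1 && rc <= 1)
  # degenerate single-taxon metacommunity: every null equals the observation
  one <- community_table(matrix(c(30L, 30L), 2, 1,
                                dimnames = list(c("A", "B"), "o1")))
  expect_equal(raup_crick_bray(one, c("A", "B"), n_null = 99, seed = 1), 0)
  expect_error(raup_crick_bray(tab, c("A", "B"), n_null = 9), "99")
})

test_that("Raup-Crick rank rescaling is antisymmetric and bounded", {
  nulls <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  low <- coresat:::rc_from_rank(0.1, nulls)   # below all nulls
  high <- coresat:::rc_from_rank(0.9, nulls)  # above all nulls
  expect_equal(low, -1)
  expect_equal(high, 1)
  expect_equal(low, -high)
  expect_equal(coresat:::rc_from_rank(0.4, nulls), 2 * (2.5 / 5) - 1)
})

test_that("process classification applies the threshold rules", {
  bnti <- c(2.5, -2.0, 0.0, 1.9, -1.0, 0.5, NA)
  rc <- c(0.1, 0.2, 0.96, -0.96, 0.5, 0.95, 0.1)
  expect_message(res <- classify_processes(bnti, rc), "excluded")
  expect_equal(res$pairs$process[1], "heterogeneous_selection")
  expect_equal(res$pairs$process[2], "homogeneous_selection")  # boundary -2
  expect_equal(res$pairs$process[3], "dispersal_limitation")
  expect_equal(res$pairs$process[4], "homogenizing_dispersal")
  expect_equal(res$pairs$process[5], "undominated")
  expect_equal(res$pairs$process[6], "dispersal_limitation")  # RC = 0.95
  expect_true(is.na(res$pairs$process[7]))
  expect_equal(sum(res$fractions), 1)
  # each classified pair lands in exactly one class
  expect_equal(sum(!is.na(res$pairs$process)), 6)
})

test_that("whole-table assembly analysis matches the per-pair operations", {
  set.seed(25)
  cfg <- synthetic_config(n_samples = 6, n_core = 15, n_satellite = 45,
                          depth = 300, seed = 5)
  sim <- simulate_metacommunity(cfg)
  asm <- assembly_analysis(sim$table, sim$tree, n_null = 99, seed = 11)
  expect_equal(nrow(asm$pairs), 15)
  expect_equal(sum(asm$fractions), 1)
  # observed betaMNTD values equal the standalone operation
  for (k in c(1, 7, 15)) {
    pr <- c(asm$pairs$sample_a[k], asm$pairs$sample_b[k])
    expect_equal(asm$pairs$beta_mntd[k], beta_mntd(sim$table, sim$tree, pr),
                 tolerance = 1e-12)
  }
  # skipping RC leaves betaNTI identical
  asm2 <- assembly_analysis(sim$table, sim$tree, n_null = 99, seed = 11,
                            include_rc = FALSE)
  expect_equal(asm2$pairs$beta_nti, asm$pairs$beta_nti)
  expect_null(asm2$fractions)
})

test_that("process-conditioned DDR restricted to all pairs is the plain fit", {
  set.seed(26)
  cfg <- synthetic_config(n_samples = 7, n_core = 15, n_satellite = 40,
                          depth = 300, seed = 6)
  sim <- simulate_metacommunity(cfg)
  geo <- geo_distance(sim$metadata)
  bc <- bray_curtis(sim$table)
  asm <- assembly_analysis(sim$table, sim$tree, n_null = 99, seed = 2)
  full <- suppressMessages(ddr_fit(geo, bc, n_perm = 99, seed = 3))
  cond <- suppressMessages(process_conditioned_ddr(asm, geo, bc, "all",
                                                   n_perm = 99, seed = 3))
  expect_equal(cond$slope, full$slope, tolerance = 1e-12)
  expect_equal(cond$r_squared, full$r_squared, tolerance = 1e-12)
  expect_error(process_conditioned_ddr(asm, geo, bc, "no_such_process"),
               "fewer than 3")
})

test_that("Levins niche breadth spans specialist to generalist", {
  x <- rbind(s1 = c(5L, 9L, 0L), s2 = c(5L, 0L, 0L), s3 = c(5L, 0L, 0L),
             s4 = c(5L, 0L, 0L))
  colnames(x) <- c("even", "spread", "zero")
  tab <- community_table(x)
  expect_warning(nb <- niche_breadth(tab), "zero reads")
  b <- setNames(nb$per_otu$B, nb$per_otu$otu_id)
  expect_equal(b[["even"]], 4)    # perfectly even: B = N
  expect_equal(b[["spread"]], 1)  # single sample: B = 1
  expect_equal(nb$mean_B, mean(c(4, 1)))
  set.seed(27)
  tabr <- community_table(matrix(rpois(60, 3), 6, 10))
  nbr <- suppressWarnings(niche_breadth(tabr))
  expect_true(all(nbr$per_otu$B >= 1 - 1e-9 & nbr$per_otu$B <= 6 + 1e-9))
})
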