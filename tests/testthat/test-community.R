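# UniFrac, PCoA, permutational pseudo-F, Kruskal-Wallis + BH

two_sample_table <- function(vals, sgb_ids) {
  meta <- data.frame(sample_id = colnames(vals),
                     group = c("g1", "g2"), total_reads = 1e6)
  rownames(vals) <- sgb_ids
  abundance_table(vals, meta)
}

test_that("unifrac reproduces closed-form small cases", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  vals <- matrix(c(3, 0, 0, 5), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  tab <- two_sample_table(vals, c("A", "B"))
  # disjoint supports on a two-leaf tree: unweighted distance is 1
  expect_equal(unifrac(tab, tree, weighted = FALSE)["s1", "s2"], 1)

  # identical samples: zero for both variants
  vals2 <- matrix(c(3, 1, 3, 1), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  tab2 <- two_sample_table(vals2, c("A", "B"))
  expect_equal(unifrac(tab2, tree, FALSE)["s1", "s2"], 0)
  expect_equal(unifrac(tab2, tree, TRUE)["s1", "s2"], 0)

  # proportional samples: weighted distance 0
  vals3 <- matrix(c(3, 1, 6, 2), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  tab3 <- two_sample_table(vals3, c("A", "B"))
  expect_equal(unifrac(tab3, tree, TRUE)["s1", "s2"], 0)
  expect_gt(unifrac(tab3, tree, FALSE)["s1", "s2"], -1e-12)

  # abundant SGB missing from the tree is an error
  tab4 <- two_sample_table(matrix(c(1, 1, 1, 1), 2, 2,
                                  dimnames = list(NULL, c("s1", "s2"))),
                           c("A", "Z"))
  expect_error(unifrac(tab4, tree), "missing from tree")
})

test_that("unifrac satisfies metric axioms on random fixtures", {
  skip_if_not_installed("ape")
  set.seed(202)
  for (rep in 1:100) {
    fx <- random_unifrac_fixture(n_sgbs = sample(4:8, 1),
                                 n_samples = sample(3:5, 1))
    for (w in c(FALSE, TRUE)) {
      d <- unifrac(fx$table, fx$tree, weighted = w)
      expect_true(all(d >= -1e-12))
      expect_equal(max(abs(d - t(d))), 0)
      expect_equal(max(abs(diag(d))), 0)
      if (!w) {
        # the presence-based variant is a metric; the normalized weighted
        # variant is a dissimilarity whose pair-dependent normalizer can
        # break the triangle inequality, so only symmetry/identity hold
        n <- nrow(d)
        for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
          expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
      }
    }
  }
})

test_that("unifrac agrees with the phyloseq reference on a random fixture", {
  skip_if_not_installed("phyloseq")
  set.seed(7)
  fx <- random_unifrac_fixture(n_sgbs = 8, n_samples = 5)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(fx$table$values, taxa_are_rows = TRUE),
    phyloseq::phy_tree(fx$tree))
  d_uw <- unifrac(fx$table, fx$tree, weighted = FALSE)
  ref_uw <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(unclass(d_uw)[rownames(ref_uw), colnames(ref_uw)], ref_uw,
               tolerance = 1e-8, ignore_attr = TRUE)
  d_w <- unifrac(fx$table, fx$tree, weighted = TRUE)
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(unclass(d_w)[rownames(ref_w), colnames(ref_w)], ref_w,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pcoa recovers closed-form embeddings", {
  ids <- c("p", "q")
  d <- distance_matrix(matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(ids, ids)))
  ord <- suppressWarnings(pcoa(d, n_axes = 2))
  expect_equal(ncol(ord$coordinates), 1)
  expect_equal(unname(sort(ord$coordinates[, 1])), c(-1, 1))

  # zero matrix: no positive axes, all coordinates absent/zero
  dz <- distance_matrix(matrix(0, 3, 3,
                               dimnames = list(letters[1:3], letters[1:3])))
  ordz <- suppressWarnings(pcoa(dz, 2))
  expect_equal(ncol(ordz$coordinates), 0)

  # points on a line: embedding reproduces the input distances
  x <- c(0, 1, 3, 7)
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ordl <- suppressWarnings(pcoa(distance_matrix(dm), 3))
  rec <- as.matrix(dist(ordl$coordinates))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-8)
  # coordinates are centered and eigenvalues non-increasing
  expect_lt(max(abs(colMeans(ordl$coordinates))), 1e-8)
  expect_true(all(diff(ordl$eigenvalues) <= 1e-8))
})

test_that("permanova matches exhaustive enumeration and its Monte-Carlo error", {
  ids <- paste0("s", 1:4)
  set.seed(31)
  pts <- c(0, 0.2, 1.1, 1.4)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(ids, ids)
  d <- distance_matrix(d)
  groups <- c("a", "a", "b", "b")
  perms <- do.call(rbind, combinat_perms(4))
  exact <- permanova(d, groups, permutations = perms)
  # all 24 relabelings; the 4!/(2!2!) = 6 distinct group splits appear
  # each 4 times, so the exact p is a multiple of 1/6
  expect_equal(exact$p_value * 6, round(exact$p_value * 6), tolerance = 1e-12)
  mc <- permanova(d, groups, n_perm = 10000, seed = 9)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 10000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 2 / 10000)

  # two well-separated clouds at n_perm = 999 reach the p floor 0.001
  # (groups of 10 so that partition-preserving label swaps are negligible)
  set.seed(42)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  dd <- as.matrix(dist(x))
  ids2 <- paste0("t", 1:20); dimnames(dd) <- list(ids2, ids2)
  res <- permanova(distance_matrix(dd), rep(c("a", "b"), each = 10),
                   n_perm = 999, seed = 5)
  expect_equal(res$p_value, 0.001)

  # degenerate input: zero within-group distance makes pseudo-F undefined
  de <- matrix(0, 4, 4); dimnames(de) <- list(ids, ids)
  expect_error(permanova(distance_matrix(de), groups, n_perm = 9),
               "undefined")
  expect_error(permanova(d, c("a", "a", "a", "b"), n_perm = 9),
               "at least two samples")
})

test_that("permanova pseudo-F agrees with vegan's adonis2", {
  skip_if_not_installed("vegan")
  set.seed(77)
  x <- matrix(rnorm(60), 10, 6)
  d <- as.matrix(dist(x))
  ids <- paste0("s", 1:10); dimnames(d) <- list(ids, ids)
  groups <- rep(c("a", "b"), each = 5)
  ours <- permanova(distance_matrix(d), groups, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("kruskal-wallis per SGB matches the rank-formula oracle and BH", {
  # hand case: 3 groups {1,2},{3,4},{5,6}
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                 dimnames = list("SGB_1", paste0("s", 1:6)))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     group = rep(c("a", "b", "c"), each = 2),
                     total_reads = 1e6)
  tab <- abundance_table(vals, meta)
  res <- kruskal_wallis_per_sgb(tab)
  expect_equal(res$statistic, oracle_kw_h(vals[1, ], meta$group))
  expect_equal(res$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21)

  # constant SGB gets p = 1 by convention
  vals2 <- rbind(vals, SGB_2 = rep(3, 6))
  res2 <- kruskal_wallis_per_sgb(abundance_table(vals2, meta))
  expect_equal(res2$p_value[2], 1)

  # randomized agreement with the oracle, with ties
  set.seed(12)
  for (rep in 1:20) {
    x <- sample(0:5, 9, replace = TRUE)
    g <- rep(c("a", "b", "c"), each = 3)
    m <- matrix(x, 1, 9, dimnames = list("S", paste0("s", 1:9)))
    mt <- data.frame(sample_id = paste0("s", 1:9), group = g,
                     total_reads = 1e6)
    r <- kruskal_wallis_per_sgb(abundance_table(m, mt))
    if (length(unique(x)) > 1)
      expect_equal(r$statistic, oracle_kw_h(x, g), tolerance = 1e-12)
  }

  # BH q-values equal the step-up definition; q >= p and monotone in rank
  set.seed(13)
  m <- matrix(rpois(50 * 9, 5), 50, 9,
              dimnames = list(sprintf("S%02d", 1:50), paste0("s", 1:9)))
  mt <- data.frame(sample_id = paste0("s", 1:9),
                   group = rep(c("a", "b", "c"), each = 3), total_reads = 1e6)
  r <- kruskal_wallis_per_sgb(abundance_table(m, mt))
  expect_equal(r$q_value, oracle_bh(r$p_value))
  expect_true(all(r$q_value >= r$p_value - 1e-12))
  ord <- order(r$p_value)
  expect_true(all(diff(r$q_value[ord]) >= -1e-12))
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
})
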