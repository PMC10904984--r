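# Co-abundance network: filtering, Kendall tau, clustering, graph,
# centralities, keystone calls, cluster abundance

make_table <- function(vals, groups = NULL) {
  if (is.null(groups)) groups <- rep(c("g1", "g2"), length.out = ncol(vals))
  meta <- data.frame(sample_id = colnames(vals), group = groups,
                     total_reads = 1e6)
  abundance_table(vals, meta)
}

test_that("abundance_filter keeps SGBs by the min-gcpm/min-samples rule", {
  vals <- rbind(keep = c(12, 11, 0), drop = c(12, 0, 0))
  colnames(vals) <- paste0("s", 1:3)
  tab <- make_table(vals)
  out <- abundance_filter(tab, min_gcpm = 10, min_samples = 2)
  expect_equal(rownames(out$values), "keep")

  set.seed(21)
  vals2 <- matrix(rexp(200, 0.05), 20, 10,
                  dimnames = list(sprintf("S%02d", 1:20), paste0("s", 1:10)))
  out2 <- abundance_filter(make_table(vals2))
  keep <- rowSums(vals2 >= 10) >= 2
  expect_equal(rownames(out2$values), rownames(vals2)[keep])
})

test_that("kendall tau matrix matches pair-counting oracle", {
  vals <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1),
                d = c(1, 3, 2))
  colnames(vals) <- paste0("s", 1:3)
  tau <- kendall_tau_matrix(make_table(vals))
  expect_equal(tau["a", "b"], 1)
  expect_equal(tau["a", "c"], -1)
  expect_equal(tau["a", "d"], 1 / 3)

  set.seed(8)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    vals <- matrix(sample(0:6, 3 * n, replace = TRUE), 3, n,
                   dimnames = list(c("x", "y", "z"), paste0("s", seq_len(n))))
    vals[1, ] <- vals[1, ] + seq_len(n) * 0.01  # avoid constant rows
    vals[2, ] <- vals[2, ] + rev(seq_len(n)) * 0.01
    vals[3, ] <- vals[3, ] + sample(n) * 0.01
    tau <- kendall_tau_matrix(make_table(vals))
    for (i in 1:2) for (j in (i + 1):3)
      expect_equal(tau[i, j], oracle_kendall(vals[i, ], vals[j, ]),
                   tolerance = 1e-12)
  }

  # constant SGB: tau recorded as 0 with a warning
  vals <- rbind(a = c(1, 2, 3), b = c(2, 2, 2))
  colnames(vals) <- paste0("s", 1:3)
  expect_warning(tau <- kendall_tau_matrix(make_table(vals)), "constant")
  expect_equal(tau["a", "b"], 0)
  expect_equal(diag(tau), c(a = 1, b = 1))
})

test_that("cluster_sgbs recovers planted blocks and is order-invariant", {
  set.seed(3)
  base1 <- cumsum(rnorm(12))
  vals <- rbind(a1 = exp(base1), a2 = exp(base1 + rnorm(12, 0, 1e-6)),
                b1 = exp(-base1), b2 = exp(-base1 + rnorm(12, 0, 1e-6)))
  colnames(vals) <- paste0("s", 1:12)
  tau <- kendall_tau_matrix(make_table(vals))
  cl <- cluster_sgbs(tau, n_clusters = 2)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_false(cl[["a1"]] == cl[["b1"]])

  # permuting SGB order leaves the partition invariant
  perm <- c("b2", "a1", "b1", "a2")
  cl_p <- cluster_sgbs(tau[perm, perm], n_clusters = 2)
  expect_true(all((cl[perm] == cl[perm][1]) == (cl_p == cl_p[1])))

  # as many clusters as SGBs: singletons
  cl_s <- cluster_sgbs(tau, n_clusters = 4)
  expect_equal(sort(unname(cl_s)), 1:4)
})

test_that("build_graph thresholds edges by |tau|", {
  ids <- letters[1:4]
  tau <- diag(4); dimnames(tau) <- list(ids, ids)
  tau["a", "b"] <- tau["b", "a"] <- 0.6
  tau["c", "d"] <- tau["d", "c"] <- -0.55
  tau["a", "c"] <- tau["c", "a"] <- 0.2
  expect_equal(nrow(build_graph(tau, 1.01)), 0)
  expect_equal(nrow(build_graph(tau, 0)), 6)
  e <- build_graph(tau, 0.5)
  expect_equal(nrow(e), 2)
  expect_setequal(paste(e$from, e$to), c("a b", "c d"))
  expect_equal(e$sign[paste(e$from, e$to) == "c d"], -1)
})

test_that("centralities match closed forms and the BFS oracle", {
  # star K1,3: center has degree 3, betweenness 1, closeness 1
  star <- data.frame(from = c("c", "c", "c"), to = c("l1", "l2", "l3"))
  cent <- centralities(star, c("c", "l1", "l2", "l3"))
  ctr <- cent[cent$sgb_id == "c", ]
  expect_equal(ctr$degree, 3)
  expect_equal(ctr$betweenness, 1)
  expect_equal(ctr$closeness, 1)

  # isolated node: degree 0, closeness 0
  cent2 <- centralities(star, c("c", "l1", "l2", "l3", "iso"))
  expect_equal(cent2[cent2$sgb_id == "iso", c("degree", "closeness")],
               data.frame(degree = 0, closeness = 0),
               ignore_attr = TRUE)

  # path P3: middle node betweenness 1
  p3 <- data.frame(from = c("a", "b"), to = c("b", "c"))
  cent3 <- centralities(p3, c("a", "b", "c"))
  expect_equal(cent3[cent3$sgb_id == "b", "betweenness"], 1)

  # random graphs: degree and closeness from brute-force shortest paths
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    nodes <- sprintf("v%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    sel <- runif(nrow(pairs)) < 0.25
    edges <- data.frame(from = pairs[sel, 1], to = pairs[sel, 2])
    cent <- centralities(edges, nodes)
    sp <- oracle_apsp(nodes, edges)
    for (v in nodes) {
      di <- sp[v, setdiff(nodes, v)]
      reach <- di[is.finite(di)]
      nc <- length(reach) + 1
      want <- if (nc == 1) 0 else ((nc - 1) / sum(reach)) * ((nc - 1) / (n - 1))
      expect_equal(cent$closeness[cent$sgb_id == v], want, tolerance = 1e-12)
      expect_equal(cent$degree[cent$sgb_id == v],
                   sum(edges$from == v | edges$to == v))
    }
  }
})

test_that("keystone_call combines centrality gates with the abundance gate", {
  cent <- data.frame(sgb_id = c("k", "lowab"),
                     closeness = c(0.50, 0.9), betweenness = c(0.03, 0.9),
                     degree = c(29, 50))
  vals <- rbind(k = rep(60, 4), lowab = rep(10, 4))
  colnames(vals) <- paste0("s", 1:4)
  out <- keystone_call(cent, make_table(vals),
                       c_min = 0.45, b_min = 0.02, d_min = 20, a_min = 50)
  expect_true(out$is_keystone[out$sgb_id == "k"])
  # abundance below the >50 gcpm gate vetoes any centrality profile
  expect_false(out$is_keystone[out$sgb_id == "lowab"])

  out0 <- keystone_call(cent, make_table(vals), 0, 0, 0, 0)
  expect_true(all(out0$is_keystone))
})

test_that("cluster cumulative abundance conserves totals and tests groups", {
  set.seed(4)
  vals <- matrix(rexp(60, 0.1), 6, 10,
                 dimnames = list(sprintf("S%d", 1:6), paste0("s", 1:10)))
  groups <- rep(c("g1", "g2"), each = 5)
  tab <- make_table(vals, groups)
  # single cluster: per-sample sums equal column totals
  cl_all <- setNames(rep(1L, 6), rownames(vals))
  res <- cluster_cumulative_abundance(tab, cl_all)
  expect_equal(res$sums[1, ], colSums(vals))

  # two clusters: sums add up to the column totals (conservation)
  cl2 <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(vals))
  res2 <- cluster_cumulative_abundance(tab, cl2)
  expect_equal(colSums(res2$sums), colSums(vals))

  # planted group-1 shift in cluster 1 is detected
  vals3 <- vals
  vals3[1:3, groups == "g1"] <- vals3[1:3, groups == "g1"] * 50
  res3 <- cluster_cumulative_abundance(make_table(vals3, groups), cl2)
  p1 <- res3$tests$p_value[res3$tests$cluster == 1]
  expect_lt(p1, 0.05)

  expect_error(cluster_cumulative_abundance(tab, setNames(1L, "nope")),
               "absent")
})
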