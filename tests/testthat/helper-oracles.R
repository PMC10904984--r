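# Independent brute-force reference implementations used to check the
# package's statistics and algorithms. They deliberately share no code
# with the implementations under test.

# Kendall tau-b by explicit pair counting with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Kruskal-Wallis H by the rank formula with tie correction
oracle_kw_h <- function(x, g) {
  g <- factor(g)
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# connected components of the graph joining pairs at distance <= threshold
oracle_components <- function(d, threshold) {
  n <- nrow(d)
  adj <- d <= threshold
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & comp == 0)
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# all-pairs shortest paths by BFS on an adjacency list
oracle_apsp <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(nodes, function(v)
    c(edges$to[edges$from == v], edges$from[edges$to == v]))
  names(adj) <- nodes
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    names(dist) <- nodes
    dist[s] <- 0
    frontier <- nodes[s]
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  d
}

# naive repeat-until-stable network expansion
oracle_scope <- function(networks, species_subset, seeds) {
  rxns <- list()
  for (s in species_subset) rxns <- c(rxns, networks[[s]]$reactions)
  reached <- unique(seeds)
  repeat {
    before <- length(reached)
    for (r in rxns)
      if (all(r$substrates %in% reached))
        reached <- union(reached, r$products)
    if (length(reached) == before) break
  }
  sort(reached)
}

# exhaustive inclusion-minimal covering subsets over the full powerset
oracle_minimal_communities <- function(networks, profile) {
  species <- names(networks)
  n <- length(species)
  targets <- intersect(profile$target_metabolites,
                       oracle_scope(networks, species, profile$seed_metabolites))
  if (!length(targets)) return(list())
  covering <- list()
  for (mask in seq_len(2^n - 1)) {
    subset <- species[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    reach <- oracle_scope(networks, subset, profile$seed_metabolites)
    if (all(targets %in% reach)) covering <- c(covering, list(sort(subset)))
  }
  is_minimal <- vapply(covering, function(s)
    !any(vapply(covering, function(t)
      length(t) < length(s) && all(t %in% s), logical(1))), logical(1))
  covering[is_minimal]
}

# exhaustive scan of pooled-midpoint thresholds for Youden calibration
oracle_threshold_scan <- function(related, unrelated, fdr_bound = 0.05) {
  pooled <- sort(unique(c(related, unrelated)))
  cand <- (pooled[-length(pooled)] + pooled[-1]) / 2
  best_t <- NA_real_; best_j <- -Inf
  for (t in cand) {
    fsr <- mean(unrelated <= t)
    if (fsr > fdr_bound) next
    j <- mean(related <= t) + mean(unrelated > t) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, youden_J = best_j)
}

# all permutations of 1..n (for exhaustive permutation tests)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (k in 0:(n - 1))
    out <- c(out, list(append(p, n, after = k)))
  out
}

# random small abundance-table + tree fixture for UniFrac property tests
random_unifrac_fixture <- function(n_sgbs = 5, n_samples = 4) {
  sgb_ids <- sprintf("SGB_%02d", seq_len(n_sgbs))
  tree <- ape::rtree(n_sgbs, tip.label = sgb_ids)
  vals <- matrix(stats::rpois(n_sgbs * n_samples, 4) *
                   stats::rbinom(n_sgbs * n_samples, 1, 0.7),
                 n_sgbs, n_samples,
                 dimnames = list(sgb_ids, sprintf("s%d", seq_len(n_samples))))
  vals[1, colSums(vals) == 0] <- 1    # no empty samples
  meta <- data.frame(sample_id = colnames(vals),
                     group = rep(c("g1", "g2"), length.out = n_samples),
                     total_reads = 1e6)
  list(table = abundance_table(vals, meta), tree = tree)
}

# small toy networks used across metabolic tests
toy_networks <- function() {
  list(
    A = metabolic_network("A", list(list(substrates = "seed", products = "i1"))),
    B = metabolic_network("B", list(list(substrates = "i1", products = "tgt"))),
    C = metabolic_network("C", list(list(substrates = "i1", products = "tgt"))),
    D = metabolic_network("D", list(list(substrates = "x1", products = "x2")))
  )
}
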