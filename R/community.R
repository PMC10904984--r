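# Community-level statistics: phylogeny-aware UniFrac distances between
# samples, classical principal coordinates, the permutational pseudo-F test
# on a distance matrix, and per-SGB Kruskal-Wallis tests with
# Benjamini-Hochberg correction.

# Edge-by-leaf incidence of a rooted tree: M[e, t] is TRUE when tip t lies
# below edge e. Branch lengths ride along as an attribute.
edge_leaf_matrix <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  ne <- nrow(tr$edge)
  M <- matrix(FALSE, ne, ntip)
  for (e in seq_len(ne)) {
    child <- tr$edge[e, 2]
    if (child > ntip)
      below[[child]] <- unlist(below[tr$edge[tr$edge[, 1] == child, 2]])
    M[e, below[[child]]] <- TRUE
  }
  colnames(M) <- tr$tip.label
  attr(M, "edge_length") <- tr$edge.length
  M
}

#' UniFrac distances between samples
#'
#' Unweighted UniFrac is the branch length unique to one sample's leaf
#' presence set divided by the branch length covered by either sample.
#' Weighted UniFrac is the normalized variant,
#' `sum(len * |pA - pB|) / sum(len * (pA + pB))`, where `p` is the relative
#' abundance subtended by each branch; it is 0 for proportional samples and
#' bounded by 1.
#'
#' @param table An [abundance_table()].
#' @param tree A rooted `phylo` tree whose leaves cover every SGB with
#'   nonzero abundance. Extra leaves are pruned.
#' @param weighted Logical; `FALSE` gives unweighted (presence) UniFrac.
#' @return A sample-by-sample [distance_matrix()].
#' @export
unifrac <- function(table, tree, weighted = FALSE) {
  tree <- validate_tree(tree)
  vals <- table$values
  abundant <- rownames(vals)[rowSums(vals) > 0]
  missing <- setdiff(abundant, tree$tip.label)
  if (length(missing))
    stop("abundant SGBs missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- intersect(tree$tip.label, rownames(vals))
  if (length(keep) < 2)
    stop("need at least two SGBs shared between table and tree", call. = FALSE)
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  M <- edge_leaf_matrix(tree)
  len <- attr(M, "edge_length")
  x <- vals[colnames(M), , drop = FALSE]
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  if (weighted) {
    tot <- colSums(x)
    rel <- sweep(x, 2, ifelse(tot > 0, tot, 1), "/")
    P <- M %*% rel                       # branch-subtended proportions
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      num <- sum(len * abs(P[, i] - P[, j]))
      den <- sum(len * (P[, i] + P[, j]))
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  } else {
    B <- (M %*% (x > 0)) > 0             # branch covered by sample?
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      either <- B[, i] | B[, j]
      uniq <- xor(B[, i], B[, j])
      den <- sum(len[either])
      d[i, j] <- d[j, i] <- if (den > 0) sum(len[uniq]) / den else 0
    }
  }
  distance_matrix(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigen-decomposition of the double-centered squared-distance matrix.
#' Axes with positive eigenvalues are returned in non-increasing eigenvalue
#' order with centered coordinates; negative eigenvalues are reported but
#' their axes dropped.
#'
#' @param d A [distance_matrix()].
#' @param n_axes Number of axes requested; reduced with a warning if the
#'   embedding has lower rank.
#' @return An object of class `ordination`: list with `sample_ids`,
#'   `coordinates` (samples x axes), and `eigenvalues` (all, including
#'   negative ones).
#' @export
pcoa <- function(d, n_axes = 2) {
  m <- unclass(d)
  n <- nrow(m)
  sc <- suppressWarnings(stats::cmdscale(m, k = max(1, n - 1), eig = TRUE))
  eig <- sc$eig
  pos <- sum(eig > max(eig[1], 0) * 1e-10 & eig > 0)
  k <- min(n_axes, pos)
  if (k < n_axes)
    warning(sprintf("only %d positive axes available (%d requested)", pos, n_axes),
            call. = FALSE)
  coords <- sc$points[, seq_len(k), drop = FALSE]
  if (k > 0) {
    coords <- sweep(coords, 2, colMeans(coords))
    colnames(coords) <- paste0("PCo", seq_len(k))
  }
  rownames(coords) <- rownames(m)
  structure(list(sample_ids = rownames(m), coordinates = coords,
                 eigenvalues = eig),
            class = "ordination")
}

# pseudo-F for a squared-distance matrix and a grouping factor
pseudo_f_stat <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    dd <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dd[upper.tri(dd)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  if (ss_within <= 1e-12 * max(1, ss_total)) return(Inf)
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

#' Permutational multivariate test with pseudo-F ratio
#'
#' Distance-based one-way test in Anderson's formulation:
#' `SS_total = sum(d^2)/n` over all pairs, `SS_within` from within-group
#' pairs, `F = (SS_among/(a-1)) / (SS_within/(n-a))`. The p-value uses the
#' add-one correction `p = (1 + #permuted F >= observed) / (1 + n_perm)`
#' so a permutation p-value is never exactly zero.
#'
#' @param d A [distance_matrix()] over samples.
#' @param groups Group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm Number of random label permutations.
#' @param seed Integer seed for the permutation stream.
#' @param permutations Optional integer matrix of explicit permutations
#'   (rows index samples); when supplied it replaces the Monte-Carlo stream
#'   and the p-value is the plain fraction `#(F_perm >= F_obs) / n`, for
#'   exact tests by full enumeration.
#' @return List with `pseudo_F`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  m <- unclass(d)
  groups <- factor(groups)
  if (length(groups) != nrow(m))
    stop("one group label per sample required", call. = FALSE)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least two samples", call. = FALSE)
  d2 <- m^2
  f_obs <- pseudo_f_stat(d2, groups)
  if (!is.finite(f_obs))
    stop("within-group sum of squares is zero; pseudo-F undefined", call. = FALSE)
  tol <- 1e-10 * max(1, abs(f_obs))
  if (!is.null(permutations)) {
    f_perm <- apply(permutations, 1, function(p)
      pseudo_f_stat(d2, groups[p]))
    p_value <- mean(f_perm >= f_obs - tol)
    n_perm <- nrow(permutations)
  } else {
    if (!is.null(seed)) set.seed(seed)
    n <- length(groups)
    count <- 0L
    for (b in seq_len(n_perm)) {
      f_b <- pseudo_f_stat(d2, groups[sample.int(n)])
      if (f_b >= f_obs - tol) count <- count + 1L
    }
    p_value <- (1 + count) / (1 + n_perm)
  }
  list(pseudo_F = f_obs, p_value = p_value, n_perm = n_perm)
}

#' Per-SGB Kruskal-Wallis tests with Benjamini-Hochberg correction
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k - 1
#' degrees of freedom, per SGB, followed by BH q-values over all tested
#' SGBs. An SGB constant across all samples has no rank information and is
#' assigned p = 1 by convention. With exactly two groups the ranking is
#' equivalent to a Wilcoxon rank-sum test (up to the tie convention), so
#' two-group comparisons reuse this function.
#'
#' @param table An [abundance_table()] with >= 2 groups in its metadata.
#' @return Data frame with columns `sgb_id`, `statistic`, `p_value`,
#'   `q_value`, ordered as the table rows.
#' @export
kruskal_wallis_per_sgb <- function(table) {
  g <- factor(table$meta$group)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  vals <- table$values
  res <- t(vapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, ]
    if (length(unique(x)) == 1) return(c(0, 1))
    kt <- stats::kruskal.test(x, g)
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2)))
  data.frame(sgb_id = rownames(vals),
             statistic = res[, 1],
             p_value = res[, 2],
             q_value = stats::p.adjust(res[, 2], method = "BH"),
             stringsAsFactors = FALSE)
}
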