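# Co-abundance network analysis: abundance filtering, Kendall tau-b
# correlation matrix, average-linkage clustering of SGBs, a signed
# thresholded graph, node centralities, keystone-taxon calls, and
# per-cluster cumulative abundance comparisons between groups.

#' Filter SGBs by minimum abundance in a minimum number of samples
#'
#' Keeps SGBs reaching at least `min_gcpm` genome copies per million reads
#' in at least `min_samples` samples (defaults 10 gcpm in 2 samples, the
#' usual gate before correlation-network construction).
#'
#' @param table An [abundance_table()].
#' @param min_gcpm Abundance threshold (inclusive).
#' @param min_samples Minimum number of qualifying samples (inclusive).
#' @return The filtered [abundance_table()].
#' @export
abundance_filter <- function(table, min_gcpm = 10, min_samples = 2) {
  keep <- rowSums(table$values >= min_gcpm) >= min_samples
  abundance_table(table$values[keep, , drop = FALSE], table$meta)
}

#' Kendall tau-b correlation matrix between SGBs
#'
#' Tie-corrected Kendall correlation for every SGB pair across samples.
#' SGBs constant across samples have undefined tau; their correlations are
#' recorded as 0 with a warning (diagonal stays 1).
#'
#' @param table An [abundance_table()] with >= 3 samples.
#' @return Symmetric SGB-by-SGB matrix in `[-1, 1]` with unit diagonal.
#' @export
kendall_tau_matrix <- function(table) {
  x <- t(table$values)
  if (nrow(x) < 3) stop("need at least three samples", call. = FALSE)
  constant <- apply(x, 2, function(v) length(unique(v)) == 1)
  tau <- suppressWarnings(stats::cor(x, method = "kendall"))
  if (any(constant)) {
    warning(sum(constant), " constant SGB(s): tau undefined, recorded as 0",
            call. = FALSE)
    tau[constant, ] <- 0
    tau[, constant] <- 0
  }
  tau[is.na(tau)] <- 0
  diag(tau) <- 1
  tau
}

#' Cluster SGBs from a correlation matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - tau`,
#' cut either to a requested number of clusters (default 7) or at a given
#' height. SGBs are ordered lexicographically before clustering so the
#' partition does not depend on input order.
#'
#' @param tau Symmetric correlation matrix with SGB dimnames.
#' @param n_clusters Number of clusters to cut to (ignored when
#'   `cut_height` is given).
#' @param cut_height Optional dendrogram cut height on the `1 - tau` scale.
#' @return Named integer vector of cluster ids, in the original SGB order.
#' @export
cluster_sgbs <- function(tau, n_clusters = 7, cut_height = NULL) {
  ids <- rownames(tau)
  if (is.null(ids)) stop("tau matrix needs SGB dimnames", call. = FALSE)
  ord <- order(ids)
  dis <- stats::as.dist(1 - tau[ord, ord])
  hc <- stats::hclust(dis, method = "average")
  ct <- if (is.null(cut_height)) stats::cutree(hc, k = min(n_clusters, length(ids)))
        else stats::cutree(hc, h = cut_height)
  ct[ids]
}

#' Build a signed co-abundance graph
#'
#' Retains an edge `(i, j, sign(tau_ij))` for every SGB pair with
#' `|tau_ij| >= abs_tau_min`.
#'
#' @param tau Symmetric correlation matrix with SGB dimnames.
#' @param abs_tau_min Minimum absolute correlation for an edge.
#' @return Data frame with columns `from`, `to`, `tau`, `sign`.
#' @export
build_graph <- function(tau, abs_tau_min = 0.3) {
  ids <- rownames(tau)
  idx <- which(upper.tri(tau) & abs(tau) >= abs_tau_min, arr.ind = TRUE)
  data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
             tau = tau[idx], sign = sign(tau[idx]),
             stringsAsFactors = FALSE)
}

#' Node centralities of the co-abundance graph
#'
#' Treats the thresholded graph as undirected and unweighted (edge signs
#' are reporting metadata, not path semantics). Closeness uses the
#' per-component form `(n_c - 1) / sum(d)` scaled by the component-size
#' factor `(n_c - 1) / (n - 1)` (Wasserman-Faust correction), so values are
#' comparable across components and isolated nodes score 0. Betweenness is
#' normalized by `(n - 1)(n - 2) / 2`.
#'
#' @param edges Edge data frame from [build_graph()].
#' @param nodes Character vector of all node ids (isolated nodes included).
#' @return Data frame with `sgb_id`, `closeness`, `betweenness`, `degree`.
#' @export
centralities <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  n <- length(nodes)
  deg <- igraph::degree(g)
  btw <- if (n > 2) igraph::betweenness(g, directed = FALSE, normalized = TRUE)
         else stats::setNames(rep(0, n), nodes)
  sp <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    di <- sp[i, -i]
    reach <- di[is.finite(di)]
    nc <- length(reach) + 1        # component size
    if (nc == 1 || sum(reach) == 0) return(0)
    ((nc - 1) / sum(reach)) * ((nc - 1) / (n - 1))
  }, numeric(1))
  data.frame(sgb_id = nodes, closeness = clo,
             betweenness = unname(btw[nodes]), degree = unname(deg[nodes]),
             stringsAsFactors = FALSE)
}

#' Call keystone taxa from centralities and abundance
#'
#' A keystone taxon combines high closeness, betweenness, and degree with a
#' mean abundance above `a_min` gcpm (strict, matching the ">50 gcpm" gate
#' conventionally applied). The centrality cut-offs are inclusive.
#'
#' @param cent Centrality data frame from [centralities()].
#' @param table An [abundance_table()] covering the network nodes.
#' @param c_min,b_min,d_min Minimum closeness, betweenness, degree
#'   (inclusive).
#' @param a_min Mean-abundance gate in gcpm (strict `>`).
#' @return `cent` with added columns `mean_abundance` and `is_keystone`.
#' @export
keystone_call <- function(cent, table, c_min = 0.45, b_min = 0.02,
                          d_min = 20, a_min = 50) {
  missing <- setdiff(cent$sgb_id, rownames(table$values))
  if (length(missing))
    stop("network nodes absent from abundance table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mean_ab <- rowMeans(table$values)[cent$sgb_id]
  cent$mean_abundance <- unname(mean_ab)
  cent$is_keystone <- cent$closeness >= c_min & cent$betweenness >= b_min &
    cent$degree >= d_min & cent$mean_abundance > a_min
  cent
}

#' Per-cluster cumulative abundance and pairwise group tests
#'
#' Sums abundance over the SGBs of each cluster per sample, then compares
#' every pair of groups per cluster with a Wilcoxon rank-sum test.
#'
#' @param table An [abundance_table()].
#' @param clusters Named integer vector (SGB -> cluster id) over the table
#'   SGBs; every cluster must be non-empty.
#' @return List with `sums` (cluster-by-sample matrix) and `tests` (data
#'   frame `cluster`, `group_a`, `group_b`, `p_value`).
#' @export
cluster_cumulative_abundance <- function(table, clusters) {
  if (is.null(names(clusters)))
    stop("clusters must be a named SGB -> cluster vector", call. = FALSE)
  missing <- setdiff(names(clusters), rownames(table$values))
  if (length(missing))
    stop("cluster SGBs absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ids <- sort(unique(clusters))
  sums <- t(vapply(ids, function(cl) {
    members <- names(clusters)[clusters == cl]
    if (!length(members)) stop("empty cluster: ", cl, call. = FALSE)
    colSums(table$values[members, , drop = FALSE])
  }, numeric(ncol(table$values))))
  rownames(sums) <- as.character(ids)
  groups <- table$meta$group
  glev <- sort(unique(groups))
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(ids, function(cl) {
    do.call(rbind, lapply(pairs, function(pr) {
      xa <- sums[as.character(cl), groups == pr[1]]
      xb <- sums[as.character(cl), groups == pr[2]]
      p <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
      data.frame(cluster = cl, group_a = pr[1], group_b = pr[2],
                 p_value = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  list(sums = sums, tests = tests)
}
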