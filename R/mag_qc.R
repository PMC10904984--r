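# MAG quality filtering and dereplication into species-level genome bins
# (SGBs). Genomes passing QC are clustered by single linkage on pairwise
# genome distance at a 5% threshold (the conventional species boundary for
# MAG collections); one representative per cluster is chosen by a
# completeness/contamination quality score.

#' Filter MAGs by completeness and contamination
#'
#' Retains genomes with completeness strictly above 50% and contamination
#' strictly below 5%. The boundaries are strict: a genome at exactly 50%
#' completeness or 5% contamination is removed.
#'
#' @param mags A [mag_records()] data frame.
#' @param min_completeness,max_contamination Strict QC bounds (percent).
#' @return The subset of `mags` passing QC (possibly empty).
#' @export
qc_filter <- function(mags, min_completeness = 50, max_contamination = 5) {
  keep <- mags$completeness > min_completeness &
    mags$contamination < max_contamination
  out <- mags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mash-style k-mer sketch distance between two genomes
#'
#' Computes `d = -(1/k) * log(2j / (1 + j))` where `j` is the Jaccard index
#' of the two k-mer sets, the usual sketch estimate of mutation distance.
#' Identical sets give 0; disjoint sets (j = 0) are capped at 1, as is any
#' distance exceeding 1.
#'
#' @param kmers_a,kmers_b Non-empty character vectors of k-mers (any
#'   hashable tokens).
#' @param k K-mer length used to build the sets.
#' @return A distance in `[0, 1]`.
#' @export
sketch_distance <- function(kmers_a, kmers_b, k = 21) {
  a <- unique(kmers_a); b <- unique(kmers_b)
  if (!length(a) || !length(b)) stop("k-mer sets must be non-empty", call. = FALSE)
  j <- length(intersect(a, b)) / length(union(a, b))
  if (j == 1) return(0)
  if (j == 0) return(1)
  min(1, -(1 / k) * log(2 * j / (1 + j)))
}

#' Dereplicate MAGs into species-level genome bins
#'
#' Single-linkage clustering of QC-passing MAGs at a genome-distance
#' threshold (default 0.05, i.e. clusters spanning 5% genetic diversity).
#' Clusters are the connected components of the graph joining genome pairs
#' at distance `<= threshold`. Within each cluster the representative
#' maximizes the quality score `Q = completeness - 5 * contamination`, with
#' ties broken by larger genome size, then lexicographically smaller MAG id.
#'
#' @param mags A [mag_records()] data frame (already QC-filtered).
#' @param dist A [distance_matrix()] covering every MAG in `mags`.
#' @param threshold Maximum within-cluster linkage distance.
#' @return A data frame with one row per SGB: `sgb_id`,
#'   `representative_mag_id`, `n_members`, and a `members` list-column of
#'   MAG ids. SGB ids are assigned in order of representative id.
#' @export
dereplicate <- function(mags, dist, threshold = 0.05) {
  ids <- mags$mag_id
  missing <- setdiff(ids, rownames(dist))
  if (length(missing))
    stop("MAGs absent from distance matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- unclass(dist)[ids, ids, drop = FALSE]
  # union-find over pairs within threshold (single linkage == components)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  n <- length(ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (jj in seq(i + 1, n)) {
      if (d[i, jj] <= threshold) {
        ri <- find(i); rj <- find(jj)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  q <- mags$completeness - 5 * mags$contamination
  gsize <- mags$genome_size
  gsize[is.na(gsize)] <- 0
  reps <- vapply(groups, function(idx) {
    ord <- order(-q[idx], -gsize[idx], ids[idx])
    ids[idx[ord[1]]]
  }, character(1))
  ord <- order(reps)
  groups <- groups[ord]; reps <- reps[ord]
  out <- data.frame(sgb_id = sprintf("SGB_%04d", seq_along(groups)),
                    representative_mag_id = reps,
                    n_members = lengths(groups),
                    stringsAsFactors = FALSE)
  out$members <- lapply(groups, function(idx) sort(ids[idx]))
  rownames(out) <- NULL
  out
}
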