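# Strain-sharing detection: eligibility of SGBs for strain-level analysis,
# marker-gene selection from core-gene coverage statistics, normalized
# phylogenetic distances (nGD) on marker trees, threshold calibration by
# Youden's index under a false-sharing bound, and sharing-event calls.

#' SGBs eligible for strain-level analysis
#'
#' An SGB qualifies when it is represented by at least `min_mags` MAGs and
#' its abundance exceeds `min_gcpm` (strict) in at least one sample of
#' each of the two designated groups — the two populations between which
#' strain exchange is being tested.
#'
#' @param mags_per_sgb Named integer vector (SGB -> MAG count).
#' @param table An [abundance_table()].
#' @param groups Character vector of the two group labels to require.
#' @param min_mags Minimum MAG count (inclusive).
#' @param min_gcpm Abundance threshold (strict `>`).
#' @return Sorted character vector of eligible SGB ids.
#' @export
select_eligible_wpsgbs <- function(mags_per_sgb, table,
                                   groups = c("baka_settled", "nzime_village"),
                                   min_mags = 5, min_gcpm = 5) {
  if (length(groups) != 2)
    stop("exactly two designated groups required", call. = FALSE)
  if (!all(groups %in% table$meta$group))
    stop("designated groups absent from metadata: ",
         paste(setdiff(groups, table$meta$group), collapse = ", "),
         call. = FALSE)
  sgbs <- intersect(names(mags_per_sgb), rownames(table$values))
  ok <- vapply(sgbs, function(s) {
    if (mags_per_sgb[s] < min_mags) return(FALSE)
    all(vapply(groups, function(g)
      any(table$values[s, table$meta$group == g] > min_gcpm), logical(1)))
  }, logical(1))
  sort(sgbs[ok])
}

#' Select marker genes for an SGB from coverage statistics
#'
#' Candidate markers are the SGB's core genes that are absent from every
#' other SGB. A candidate is accepted when at least `min_frac_mags` of the
#' SGB's MAGs map against it covering strictly more than `min_cov` of the
#' gene's length (defaults: 90% of MAGs, >50% coverage).
#'
#' @param presence A [gene_presence()] object over all SGBs.
#' @param sgb The SGB id.
#' @param coverage Gene-by-MAG matrix of coverage fractions for this SGB's
#'   MAGs (rows may cover any superset of the candidate genes).
#' @param min_frac_mags Minimum fraction of MAGs passing (inclusive).
#' @param min_cov Per-MAG coverage bound (strict `>`).
#' @return List with `sgb_id`, `marker_gene_ids`, and `stats` (data frame
#'   `gene_id`, `fraction_mags_mapped`, `is_marker`).
#' @export
select_markers <- function(presence, sgb, coverage,
                           min_frac_mags = 0.90, min_cov = 0.50) {
  pm <- presence$presence
  if (!sgb %in% colnames(pm)) stop("unknown SGB: ", sgb, call. = FALSE)
  other <- setdiff(colnames(pm), sgb)
  exclusive <- rownames(pm)[pm[, sgb] == 1 &
                            rowSums(pm[, other, drop = FALSE]) == 0]
  cand <- intersect(exclusive, rownames(coverage))
  frac <- vapply(cand, function(g) mean(coverage[g, ] > min_cov), numeric(1))
  is_marker <- frac >= min_frac_mags
  list(sgb_id = sgb,
       marker_gene_ids = sort(cand[is_marker]),
       stats = data.frame(gene_id = cand,
                          fraction_mags_mapped = unname(frac),
                          is_marker = unname(is_marker),
                          stringsAsFactors = FALSE))
}

#' Normalized phylogenetic distance between two leaves
#'
#' Leaf-to-leaf path length divided by the total branch length of the
#' tree; a pseudometric bounded by 1.
#'
#' @param tree A `phylo` tree with positive total branch length.
#' @param leaf_a,leaf_b Leaf labels.
#' @return nGD in `[0, 1]`.
#' @export
ngd <- function(tree, leaf_a, leaf_b) {
  tree <- validate_tree(tree)
  if (!all(c(leaf_a, leaf_b) %in% tree$tip.label))
    stop("leaves not in tree: ",
         paste(setdiff(c(leaf_a, leaf_b), tree$tip.label), collapse = ", "),
         call. = FALSE)
  total <- sum(tree$edge.length)
  if (total <= 0) stop("tree has zero total branch length", call. = FALSE)
  if (leaf_a == leaf_b) return(0)
  ia <- match(leaf_a, tree$tip.label)
  ib <- match(leaf_b, tree$tip.label)
  path <- ape::dist.nodes(tree)[ia, ib]
  path / total
}

#' Calibrate a strain-sharing nGD threshold
#'
#' Scans the midpoints of the sorted pooled nGD values. At threshold `t`,
#' sensitivity is the fraction of related pairs with `nGD <= t` and
#' specificity the fraction of unrelated pairs with `nGD > t`; Youden's
#' index is `J = sensitivity + specificity - 1`. The chosen threshold
#' maximizes J subject to the false-sharing constraint that at most
#' `fdr_bound` of unrelated pairs fall at or below it; ties favor the
#' smaller threshold. When no midpoint satisfies the constraint, the
#' threshold falls back below the smallest observed value and the result
#' is flagged `constrained`.
#'
#' @param related,unrelated Non-empty numeric vectors of nGD values for
#'   related (same-strain expectation) and unrelated pairs.
#' @param fdr_bound Maximum tolerated fraction of unrelated pairs called
#'   as sharing.
#' @return List with `threshold`, `youden_J`, `sensitivity`,
#'   `specificity`, `false_sharing_rate`, `constrained`.
#' @export
calibrate_threshold <- function(related, unrelated, fdr_bound = 0.05) {
  if (!length(related) || !length(unrelated))
    stop("both nGD lists must be non-empty", call. = FALSE)
  pooled <- sort(unique(c(related, unrelated)))
  cand <- if (length(pooled) >= 2)
    (pooled[-length(pooled)] + pooled[-1]) / 2 else pooled
  eval_t <- function(t) {
    sens <- mean(related <= t)
    spec <- mean(unrelated > t)
    # direct count, not 1 - spec: keeps boundary cases exactly at the bound
    fsr <- mean(unrelated <= t)
    c(sens = sens, spec = spec, J = sens + spec - 1, fsr = fsr)
  }
  stats <- vapply(cand, eval_t, numeric(4))
  ok <- stats["fsr", ] <= fdr_bound
  if (any(ok)) {
    j_ok <- stats["J", ok]
    best <- which(ok)[which(j_ok == max(j_ok))[1]]  # smallest t among ties
    t <- cand[best]; st <- stats[, best]; constrained <- FALSE
  } else {
    t <- min(pooled) / 2
    st <- eval_t(t); constrained <- TRUE
  }
  list(threshold = unname(t), youden_J = unname(st["J"]),
       sensitivity = unname(st["sens"]), specificity = unname(st["spec"]),
       false_sharing_rate = unname(st["fsr"]), constrained = constrained)
}

#' Call strain-sharing events
#'
#' A query pair shares a strain when its nGD is at or below the calibrated
#' threshold of its SGB (inclusive: the threshold is the maximal accepted
#' distance).
#'
#' @param query_pairs Data frame with columns `sgb_id`, `sample_a`,
#'   `sample_b`, `ngd`.
#' @param thresholds Named list (SGB -> result of
#'   [calibrate_threshold()]) or named numeric vector of thresholds
#'   covering every query SGB.
#' @return List with `events` (the sharing rows of `query_pairs`) and
#'   `counts` (named per-SGB event counts over all query SGBs).
#' @export
call_sharing <- function(query_pairs, thresholds) {
  need <- c("sgb_id", "sample_a", "sample_b", "ngd")
  if (!all(need %in% names(query_pairs)))
    stop("query_pairs needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  thr <- if (is.list(thresholds))
    vapply(thresholds, `[[`, numeric(1), "threshold") else thresholds
  missing <- setdiff(unique(query_pairs$sgb_id), names(thr))
  if (length(missing))
    stop("no calibrated threshold for SGBs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  shared <- query_pairs$ngd <= thr[query_pairs$sgb_id]
  events <- query_pairs[shared, , drop = FALSE]
  rownames(events) <- NULL
  counts <- vapply(split(shared, query_pairs$sgb_id), sum, numeric(1))
  list(events = events, counts = counts)
}
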