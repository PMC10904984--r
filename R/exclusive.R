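# Screening for genes (and BGCs) exclusive to the wild-plant module SGBs,
# restricted to degradation-relevant annotation categories, and their
# prevalence across external metagenome panels after RPKM normalization.

#' Genes exclusive to the module SGBs
#'
#' Returns the genes present in at least one module SGB, absent from every
#' SGB outside the module, and annotated in one of the screen categories
#' (by default carbohydrate-active and xenobiotic-degradation annotations,
#' the categories relevant to plant-substrate breakdown).
#'
#' @param presence A [gene_presence()] object.
#' @param module Character vector of module SGB ids (must be a subset of
#'   the matrix columns).
#' @param categories Annotation categories admitted by the screen.
#' @return Data frame with `feature_id`, `category`, `length_bp`,
#'   `n_owners`, and an `owners` list-column of module SGB ids.
#' @export
exclusive_genes <- function(presence, module,
                            categories = c("CAZy-like", "xenobiotic-like")) {
  pm <- presence$presence
  bad <- setdiff(module, colnames(pm))
  if (length(bad))
    stop("module SGBs absent from presence matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  in_mod <- colnames(pm) %in% module
  hits <- rowSums(pm[, in_mod, drop = FALSE]) >= 1 &
    rowSums(pm[, !in_mod, drop = FALSE]) == 0 &
    presence$annotation_category %in% categories
  ids <- rownames(pm)[hits]
  out <- data.frame(feature_id = ids,
                    category = unname(presence$annotation_category[ids]),
                    length_bp = unname(presence$gene_length_bp[ids]),
                    n_owners = rowSums(pm[ids, in_mod, drop = FALSE]),
                    stringsAsFactors = FALSE)
  out$owners <- lapply(ids, function(g)
    colnames(pm)[in_mod][pm[g, in_mod] == 1])
  rownames(out) <- NULL
  out
}

#' RPKM normalization of mapping counts
#'
#' Reads per kilobase of reference per million mapped reads:
#' `rpkm = counts / ((length_bp / 1000) * (total_mapped_reads / 1e6))`,
#' elementwise over the feature-by-metagenome count matrix.
#'
#' @param counts A [mapping_counts()] object.
#' @return Numeric matrix with the same dimnames as the counts.
#' @export
rpkm <- function(counts) {
  counts$counts /
    outer(counts$feature_length_bp / 1000, counts$total_mapped_reads / 1e6)
}

#' Feature prevalence across populations
#'
#' Declares a feature present in a metagenome when its RPKM exceeds
#' `presence_threshold` (default 0: any aligned read), then averages
#' presence within each population label.
#'
#' @param rpkm_matrix Feature-by-metagenome RPKM matrix.
#' @param population_labels Named character vector (metagenome ->
#'   population) covering every column.
#' @param presence_threshold Strict RPKM cut-off for presence.
#' @return List with `rpkm`, `presence` (binary matrix), and `prevalence`
#'   (feature-by-population fraction matrix).
#' @export
prevalence <- function(rpkm_matrix, population_labels, presence_threshold = 0) {
  mg <- colnames(rpkm_matrix)
  if (!all(mg %in% names(population_labels)))
    stop("population labels must cover all metagenomes", call. = FALSE)
  pop <- factor(population_labels[mg])
  pres <- (rpkm_matrix > presence_threshold) * 1
  prev <- vapply(levels(pop), function(lv)
    rowMeans(pres[, pop == lv, drop = FALSE]), numeric(nrow(pres)))
  prev <- matrix(prev, nrow = nrow(pres),
                 dimnames = list(rownames(pres), levels(pop)))
  list(rpkm = rpkm_matrix, presence = pres, prevalence = prev)
}

#' BGC prevalence across populations, grouped by product class
#'
#' Identical computation to gene [prevalence()] applied to a biosynthetic
#' gene cluster count table, with an additional per-product-class summary
#' (mean prevalence over the BGCs of each class).
#'
#' @param bgc_counts A [mapping_counts()] whose features are BGCs.
#' @param population_labels Named metagenome -> population vector.
#' @param product_class Named character vector (BGC -> product class, e.g.
#'   arylpolyene, terpene, ranthipeptide) covering every feature.
#' @param presence_threshold Strict RPKM cut-off for presence.
#' @return The [prevalence()] list plus `product_class` and
#'   `class_prevalence` (class-by-population matrix).
#' @export
bgc_prevalence <- function(bgc_counts, population_labels, product_class,
                           presence_threshold = 0) {
  feats <- rownames(bgc_counts$counts)
  if (!all(feats %in% names(product_class)))
    stop("product classes must cover all BGC features", call. = FALSE)
  res <- prevalence(rpkm(bgc_counts), population_labels, presence_threshold)
  cls <- factor(product_class[feats])
  res$product_class <- stats::setNames(as.character(cls), feats)
  res$class_prevalence <- apply(res$prevalence, 2, function(col)
    tapply(col, cls, mean))
  res
}
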