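#' Construct a validated SGB abundance table
#'
#' An abundance table holds per-sample genome abundances of species-level
#' genome bins (SGBs) in genome copies per million sequenced reads (gcpm),
#' together with the sample metadata (group label and sequencing depth) that
#' every downstream statistical stage needs.
#'
#' @param values Numeric matrix, SGB rows by sample columns, non-negative,
#'   with unique row names (SGB ids) and column names (sample ids).
#' @param meta Data frame with columns `sample_id`, `group`, `total_reads`;
#'   one row per column of `values`.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix, samples ordered as in `meta`) and `meta`.
#' @examples
#' m <- matrix(c(10, 0, 5, 20), 2, 2,
#'             dimnames = list(c("SGB_1", "SGB_2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"),
#'                    group = c("baka_forest", "nzime_village"),
#'                    total_reads = c(8e6, 8e6))
#' tab <- abundance_table(m, meta)
#' @export
abundance_table <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have SGB row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated SGB ids in abundance table", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in abundance table", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("abundance values must be non-negative and non-missing", call. = FALSE)
  meta <- validate_sample_meta(meta)
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "abundance_table")
}

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "group", "total_reads")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("metadata must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- as.character(meta$group)
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample ids in metadata", call. = FALSE)
  if (anyNA(meta$total_reads) || any(meta$total_reads <= 0))
    stop("total_reads must be positive", call. = FALSE)
  meta
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d SGBs x %d samples (gcpm)\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s (%d)", names(table(x$meta$group)),
                               table(x$meta$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a table of MAG quality records
#'
#' One row per metagenome-assembled genome (MAG) with the CheckM-style
#' quality statistics used for filtering and representative selection.
#'
#' @param mag_id,completeness,contamination,genome_size,n_contigs,n50,source_sample
#'   Vectors of equal length; `completeness` and `contamination` are
#'   percentages, `genome_size` and `n50` are in bp.
#' @return A data frame of class `mag_records`.
#' @export
mag_records <- function(mag_id, completeness, contamination,
                        genome_size = NA_real_, n_contigs = NA_integer_,
                        n50 = NA_real_, source_sample = NA_character_) {
  mag_id <- as.character(mag_id)
  if (anyDuplicated(mag_id)) stop("duplicated MAG ids", call. = FALSE)
  if (anyNA(completeness) || any(completeness < 0 | completeness > 100))
    stop("completeness must lie in [0, 100]", call. = FALSE)
  if (anyNA(contamination) || any(contamination < 0))
    stop("contamination must be >= 0", call. = FALSE)
  out <- data.frame(mag_id = mag_id, completeness = completeness,
                    contamination = contamination, genome_size = genome_size,
                    n_contigs = n_contigs, n50 = n50,
                    source_sample = source_sample,
                    stringsAsFactors = FALSE)
  class(out) <- c("mag_records", class(out))
  out
}

#' Construct a validated symmetric distance matrix
#'
#' Used both for pairwise genome distances (dereplication) and sample-level
#' UniFrac distances.
#'
#' @param d Square numeric matrix with matching row/column names, zero
#'   diagonal and symmetric within `tol`.
#' @param tol Symmetry tolerance.
#' @return The matrix with class `distance_matrix` prepended.
#' @export
distance_matrix <- function(d, tol = 1e-9) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix needs row/column ids", call. = FALSE)
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (!identical(rownames(d), colnames(d)))
    stop("row and column ids disagree", call. = FALSE)
  if (anyNA(d) || any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal must be zero", call. = FALSE)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  class(d) <- c("distance_matrix", class(d))
  d
}

#' Construct a gene presence/absence matrix with annotations
#'
#' Pangenome-style matrix of gene occurrence across SGBs, with a per-gene
#' length and functional annotation category. Categories distinguish genes
#' annotated in carbohydrate-active enzyme databases (`"CAZy-like"`),
#' xenobiotic-degradation databases (`"xenobiotic-like"`), other annotations,
#' or none.
#'
#' @param presence Binary (0/1) matrix, gene rows by SGB columns, with
#'   unique dimnames.
#' @param gene_length_bp Positive numeric vector, one per gene.
#' @param annotation_category Character vector, one per gene, drawn from
#'   `c("CAZy-like", "xenobiotic-like", "other", "none")`.
#' @return An object of class `gene_presence`.
#' @export
gene_presence <- function(presence, gene_length_bp, annotation_category) {
  if (!is.matrix(presence) || !all(presence %in% c(0, 1)))
    stop("presence must be a 0/1 matrix", call. = FALSE)
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix needs gene and SGB ids as dimnames", call. = FALSE)
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence)))
    stop("duplicated gene or SGB ids", call. = FALSE)
  if (length(gene_length_bp) != nrow(presence) || any(gene_length_bp <= 0))
    stop("gene_length_bp must be positive, one per gene", call. = FALSE)
  allowed <- c("CAZy-like", "xenobiotic-like", "other", "none")
  if (length(annotation_category) != nrow(presence) ||
      !all(annotation_category %in% allowed))
    stop("annotation_category must be one of ",
         paste(allowed, collapse = ", "), ", one per gene", call. = FALSE)
  structure(list(presence = presence,
                 gene_length_bp = stats::setNames(as.numeric(gene_length_bp),
                                                  rownames(presence)),
                 annotation_category = stats::setNames(as.character(annotation_category),
                                                       rownames(presence))),
            class = "gene_presence")
}

#' Construct a per-species metabolic reaction network
#'
#' Boolean (topological) representation of a genome-scale metabolic model:
#' each reaction converts a non-empty substrate set into a non-empty product
#' set. Reversible reactions are encoded by listing both directions.
#'
#' @param species_id Character scalar.
#' @param reactions List of lists with character elements `substrates` and
#'   `products`, both non-empty.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(species_id, reactions) {
  if (!is.character(species_id) || length(species_id) != 1 || !nzchar(species_id))
    stop("species_id must be a non-empty string", call. = FALSE)
  reactions <- lapply(reactions, function(r) {
    s <- unique(as.character(r$substrates))
    p <- unique(as.character(r$products))
    if (!length(s) || !length(p) || !all(nzchar(c(s, p))))
      stop("every reaction needs non-empty substrate and product sets",
           call. = FALSE)
    list(substrates = s, products = p)
  })
  structure(list(species_id = species_id, reactions = reactions),
            class = "metabolic_network")
}

#' Construct a plant substrate profile
#'
#' Seed metabolites are the compounds a wild plant food contributes to the
#' gut environment; target metabolites are the degradation end points whose
#' producibility defines substrate usage.
#'
#' @param plant_name Character scalar.
#' @param seed_metabolites,target_metabolites Disjoint, non-empty character
#'   vectors of metabolite ids.
#' @return An object of class `substrate_profile`.
#' @export
substrate_profile <- function(plant_name, seed_metabolites, target_metabolites) {
  seed_metabolites <- unique(as.character(seed_metabolites))
  target_metabolites <- unique(as.character(target_metabolites))
  if (!length(seed_metabolites) || !length(target_metabolites))
    stop("seed and target metabolite sets must be non-empty", call. = FALSE)
  if (length(intersect(seed_metabolites, target_metabolites)))
    stop("seed and target metabolite sets must be disjoint", call. = FALSE)
  structure(list(plant_name = as.character(plant_name),
                 seed_metabolites = seed_metabolites,
                 target_metabolites = target_metabolites),
            class = "substrate_profile")
}

#' Construct per-feature read-mapping counts
#'
#' Aligned-read counts of genes or biosynthetic gene clusters (BGCs) across
#' metagenomes, with the feature lengths and per-metagenome total mapped
#' reads needed for RPKM normalization.
#'
#' @param counts Non-negative count matrix, feature rows by metagenome
#'   columns, with dimnames.
#' @param feature_length_bp Positive numeric vector, one per feature.
#' @param total_mapped_reads Positive numeric vector, one per metagenome.
#' @return An object of class `mapping_counts`.
#' @export
mapping_counts <- function(counts, feature_length_bp, total_mapped_reads) {
  if (!is.matrix(counts) || anyNA(counts) || any(counts < 0))
    stop("counts must be a non-negative matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts matrix needs feature and metagenome ids", call. = FALSE)
  if (length(feature_length_bp) != nrow(counts) || any(feature_length_bp <= 0))
    stop("feature_length_bp must be positive, one per feature", call. = FALSE)
  if (length(total_mapped_reads) != ncol(counts) || any(total_mapped_reads <= 0))
    stop("total_mapped_reads must be positive, one per metagenome", call. = FALSE)
  structure(list(counts = counts,
                 feature_length_bp = stats::setNames(as.numeric(feature_length_bp),
                                                     rownames(counts)),
                 total_mapped_reads = stats::setNames(as.numeric(total_mapped_reads),
                                                      colnames(counts))),
            class = "mapping_counts")
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected an ape 'phylo' tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated leaf labels in tree", call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths in tree; defaulting to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths in tree", call. = FALSE)
  tree
}
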