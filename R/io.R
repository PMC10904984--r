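# Readers and writers for the plain-text interchange formats used across
# the pipeline: TSV (tab-separated, header row, "." decimal), Newick trees,
# and JSON metabolic networks / substrate profiles. Writers and readers are
# inverse to each other so intermediate results can be checkpointed.

read_tsv_strict <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_strict <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               rownames_as),
               as.data.frame(x, check.names = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an SGB abundance table and its sample metadata
#'
#' @param path TSV with an `sgb_id` first column and one column per sample,
#'   values in gcpm.
#' @param meta_path TSV with columns `sample_id`, `group`, `total_reads`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, meta_path) {
  tab <- read_tsv_strict(path)
  if (names(tab)[1] != "sgb_id")
    stop("abundance TSV must start with an 'sgb_id' column", call. = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric abundance values", call. = FALSE)
  rownames(values) <- as.character(tab$sgb_id)
  meta <- read_tsv_strict(meta_path)
  abundance_table(values, meta)
}

#' Write an SGB abundance table and its metadata
#'
#' @param table An [abundance_table()].
#' @param path,meta_path Output TSV paths.
#' @export
write_abundance_table <- function(table, path, meta_path) {
  write_tsv_strict(table$values, path, rownames_as = "sgb_id")
  write_tsv_strict(table$meta, meta_path)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Internal node labels are ignored; missing branch lengths are replaced by
#' zero with a warning.
#'
#' @param path Path to a single-tree Newick file.
#' @return An ape `phylo` tree with unique leaf labels and non-negative
#'   branch lengths.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  opens <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  closes <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (opens != closes)
    stop("unbalanced parentheses in Newick file: ", path, call. = FALSE)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  validate_tree(tree)
}

#' Read per-species metabolic networks from JSON
#'
#' Expected layout: a JSON object mapping each species id to a list of
#' reactions, each with `substrates` and `products` arrays.
#'
#' @param path JSON file path.
#' @return Named list of [metabolic_network()] objects.
#' @export
read_metabolic_networks <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(names(raw))) stop("expected a species -> reactions mapping", call. = FALSE)
  nets <- lapply(names(raw), function(sp) {
    rxns <- lapply(raw[[sp]], function(r)
      list(substrates = unlist(r$substrates), products = unlist(r$products)))
    metabolic_network(sp, rxns)
  })
  stats::setNames(nets, names(raw))
}

#' Write metabolic networks to JSON
#'
#' @param networks Named list of [metabolic_network()] objects.
#' @param path Output JSON path.
#' @export
write_metabolic_networks <- function(networks, path) {
  obj <- lapply(networks, function(net) {
    lapply(net$reactions, function(r)
      list(substrates = as.list(r$substrates), products = as.list(r$products)))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read plant substrate profiles from JSON
#'
#' Layout: JSON object mapping plant name to `{"seeds": [...], "targets": [...]}`.
#'
#' @param path JSON file path.
#' @return Named list of [substrate_profile()] objects.
#' @export
read_substrate_profiles <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  profs <- lapply(names(raw), function(pl)
    substrate_profile(pl, unlist(raw[[pl]]$seeds), unlist(raw[[pl]]$targets)))
  stats::setNames(profs, names(raw))
}

#' Write plant substrate profiles to JSON
#'
#' @param profiles Named list of [substrate_profile()] objects.
#' @param path Output JSON path.
#' @export
write_substrate_profiles <- function(profiles, path) {
  obj <- lapply(profiles, function(p)
    list(seeds = as.list(p$seed_metabolites),
         targets = as.list(p$target_metabolites)))
  names(obj) <- vapply(profiles, `[[`, "", "plant_name")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a MAG quality-control table
#'
#' @param path TSV with columns `mag_id`, `completeness`, `contamination`
#'   and optionally `genome_size`, `n_contigs`, `n50`, `source_sample`.
#' @return A [mag_records()] data frame.
#' @export
read_mag_qc <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("mag_id", "completeness", "contamination")
  if (!all(need %in% names(tab)))
    stop("QC table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  grab <- function(col, default) if (col %in% names(tab)) tab[[col]] else default
  mag_records(tab$mag_id, tab$completeness, tab$contamination,
              genome_size = grab("genome_size", NA_real_),
              n_contigs = grab("n_contigs", NA_integer_),
              n50 = grab("n50", NA_real_),
              source_sample = grab("source_sample", NA_character_))
}

#' Read a square pairwise distance matrix from TSV
#'
#' @param path TSV with an `id` first column and one column per id.
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path) {
  tab <- read_tsv_strict(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  distance_matrix(m)
}

#' Write a distance matrix to TSV
#'
#' @param d A [distance_matrix()] (or plain symmetric matrix).
#' @param path Output TSV path.
#' @export
write_distance_matrix <- function(d, path) {
  write_tsv_strict(unclass(d), path, rownames_as = "id")
}

#' Read a gene presence/absence matrix with annotations
#'
#' @param path TSV with columns `gene_id`, `length_bp`, `category` followed
#'   by one 0/1 column per SGB.
#' @return A [gene_presence()] object.
#' @export
read_gene_presence <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("gene_id", "length_bp", "category")
  if (!all(need %in% names(tab)))
    stop("gene presence TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sgb_cols <- setdiff(names(tab), need)
  pm <- as.matrix(tab[, sgb_cols, drop = FALSE])
  rownames(pm) <- as.character(tab$gene_id)
  gene_presence(pm, tab$length_bp, tab$category)
}

#' Write a gene presence/absence matrix
#'
#' @param gpm A [gene_presence()] object.
#' @param path Output TSV path.
#' @export
write_gene_presence <- function(gpm, path) {
  out <- data.frame(gene_id = rownames(gpm$presence),
                    length_bp = unname(gpm$gene_length_bp),
                    category = unname(gpm$annotation_category),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(gpm$presence, check.names = FALSE))
  write_tsv_strict(out, path)
}

#' Read feature read-mapping counts
#'
#' @param path TSV with columns `feature_id`, `length_bp` followed by one
#'   count column per metagenome.
#' @param totals_path TSV with columns `metagenome_id`, `total_mapped_reads`
#'   and optionally `population`.
#' @return A list with elements `counts` (a [mapping_counts()]) and
#'   `populations` (named character vector or `NULL`).
#' @export
read_mapping_counts <- function(path, totals_path) {
  tab <- read_tsv_strict(path)
  if (!all(c("feature_id", "length_bp") %in% names(tab)))
    stop("counts TSV must have 'feature_id' and 'length_bp' columns", call. = FALSE)
  cnt <- as.matrix(tab[, setdiff(names(tab), c("feature_id", "length_bp")),
                       drop = FALSE])
  rownames(cnt) <- as.character(tab$feature_id)
  tot <- read_tsv_strict(totals_path)
  if (!all(c("metagenome_id", "total_mapped_reads") %in% names(tot)))
    stop("totals TSV must have 'metagenome_id' and 'total_mapped_reads'",
         call. = FALSE)
  idx <- match(colnames(cnt), tot$metagenome_id)
  if (anyNA(idx)) stop("metagenomes missing from totals table", call. = FALSE)
  mc <- mapping_counts(cnt, tab$length_bp, tot$total_mapped_reads[idx])
  pops <- if ("population" %in% names(tot))
    stats::setNames(as.character(tot$population[idx]), colnames(cnt)) else NULL
  list(counts = mc, populations = pops)
}
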