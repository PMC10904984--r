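# End-to-end pipeline driver: generates a synthetic cohort (or consumes
# tables on disk), runs every analysis stage, and writes deterministic TSV
# and JSON outputs so two runs with the same configuration and seed are
# byte-identical.

#' Default pipeline configuration
#'
#' The default sizes emulate the field-cohort scale: 628 QC-passing MAGs
#' dereplicating to 161 SGBs, a 44-sample three-group cohort over the
#' 161 SGBs, five plant substrate profiles whose degrader guilds total
#' 26 species, 29 planted module-exclusive genes, and a 34-BGC panel.
#' Pass smaller values for quick runs.
#'
#' @param n_sgbs Cohort SGB count.
#' @param n_per_group Samples per group.
#' @param n_mags_pass,n_mags_fail,n_mag_clusters Synthetic MAG set sizes.
#' @param guild_sizes,redundant_guilds Degrader guild layout over the five
#'   plants (defaults total 26 species including one redundant pair).
#' @param n_genes,n_exclusive Pangenome sizes.
#' @param n_bgcs BGC panel size.
#' @param n_perm Permutations for the pseudo-F test.
#' @param n_clusters Co-abundance clusters to cut.
#' @param tau_min Co-abundance edge threshold on `|tau|`.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(n_sgbs = 161,
                            n_per_group = c(baka_forest = 16,
                                            baka_settled = 10,
                                            nzime_village = 18),
                            n_mags_pass = 628, n_mags_fail = 72,
                            n_mag_clusters = 161,
                            guild_sizes = c(7, 6, 5, 4, 3),
                            redundant_guilds = 1,
                            n_genes = 1000, n_exclusive = 29, n_bgcs = 34,
                            n_perm = 999, n_clusters = 7, tau_min = 0.3) {
  as.list(environment())
}

# Table 2-style BGC product-class inventory (synthetic stand-in for an
# antiSMASH screen): class counts for a 34-BGC panel.
default_bgc_classes <- function(n_bgcs = 34) {
  classes <- rep(c("ranthipeptide", "RRE-containing", "thiopeptide", "NRPS",
                   "NRPS-like", "arylpolyene", "cyclic-lactone-autoinducer",
                   "terpene", "T1PKS", "betalactone", "RiPP-like"),
                 c(6, 8, 1, 2, 1, 7, 1, 4, 1, 1, 2))
  classes <- rep(classes, length.out = n_bgcs)
  stats::setNames(classes, sprintf("BGC_%02d", seq_len(n_bgcs)))
}

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates every input with the given seed, runs MAG dereplication,
#' community statistics, the co-abundance network, metabolic key-species
#' identification, the exclusive-feature screens, and strain-threshold
#' calibration, writing all stage outputs under `out_dir`. All randomness
#' derives from `seed`, so repeated runs are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a list of the in-memory stage results (see the
#'   written files for the on-disk forms).
#' @export
run_pipeline <- function(out_dir, seed = 1, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 8)
  cfg <- config

  ## MAG QC + dereplication on a planted-cluster MAG set
  magset <- gen_mag_set(n_pass = cfg$n_mags_pass, n_fail = cfg$n_mags_fail,
                        n_clusters = cfg$n_mag_clusters, seed = seeds[1])
  retained <- qc_filter(magset$mags)
  sgbs <- dereplicate(retained, magset$dist, threshold = 0.05)
  write_tsv_strict(data.frame(sgb_id = sgbs$sgb_id,
                              representative_mag_id = sgbs$representative_mag_id,
                              n_members = sgbs$n_members,
                              members = vapply(sgbs$members, paste,
                                               "", collapse = ","),
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "sgb_clusters.tsv"))

  ## metabolic networks with planted guilds over the first cohort SGBs
  sgb_ids <- sprintf("SGB_%04d", seq_len(cfg$n_sgbs))
  n_net_species <- min(cfg$n_sgbs,
                       sum(cfg$guild_sizes) + length(cfg$redundant_guilds) + 20)
  netspec <- network_spec(n_species = n_net_species,
                          guild_sizes = cfg$guild_sizes,
                          redundant_guilds = cfg$redundant_guilds,
                          species_ids = sgb_ids[seq_len(n_net_species)],
                          seed = seeds[2])
  nets <- gen_networks(netspec)
  key_results <- lapply(nets$profiles, function(pr)
    minimal_communities(nets$networks, pr))
  module <- wp_module(key_results)
  write_json_det(lapply(key_results, function(r)
    r[c("plant_name", "producible_targets", "essential_species",
        "alternative_species", "minimal_communities")]),
    file.path(out_dir, "key_species.json"))
  write_tsv_strict(data.frame(sgb_id = module, stringsAsFactors = FALSE),
                   file.path(out_dir, "wp_module.tsv"))

  ## cohort with the recovered module planted as the abundance-shifted set
  cspec <- cohort_spec(n_sgbs = cfg$n_sgbs, n_per_group = cfg$n_per_group,
                       gradient_sgbs = utils::head(setdiff(sgb_ids, module), 6),
                       module_sgbs = module, seed = seeds[3])
  cohort <- gen_cohort(cspec)
  write_abundance_table(cohort$table,
                        file.path(out_dir, "abundance.tsv"),
                        file.path(out_dir, "samples.tsv"))
  ape::write.tree(cohort$tree, file.path(out_dir, "sgb_tree.nwk"))

  ## community statistics
  d_uw <- unifrac(cohort$table, cohort$tree, weighted = FALSE)
  d_w <- unifrac(cohort$table, cohort$tree, weighted = TRUE)
  write_distance_matrix(d_uw, file.path(out_dir, "unifrac_unweighted.tsv"))
  write_distance_matrix(d_w, file.path(out_dir, "unifrac_weighted.tsv"))
  ord <- pcoa(d_w, n_axes = 2)
  write_tsv_strict(ord$coordinates, file.path(out_dir, "pcoa_weighted.tsv"),
                   rownames_as = "sample_id")
  perm <- permanova(d_w, cohort$table$meta$group, n_perm = cfg$n_perm,
                    seed = seeds[4])
  kw <- kruskal_wallis_per_sgb(cohort$table)
  write_tsv_strict(kw, file.path(out_dir, "kruskal_wallis.tsv"))

  ## co-abundance network
  filt <- abundance_filter(cohort$table)
  tau <- kendall_tau_matrix(filt)
  clusters <- cluster_sgbs(tau, n_clusters = cfg$n_clusters)
  edges <- build_graph(tau, abs_tau_min = cfg$tau_min)
  cent <- centralities(edges, rownames(tau))
  keys <- keystone_call(cent, filt)
  clab <- cluster_cumulative_abundance(filt, clusters)
  write_tsv_strict(tau, file.path(out_dir, "kendall_tau.tsv"),
                   rownames_as = "sgb_id")
  write_tsv_strict(data.frame(sgb_id = names(clusters),
                              cluster = unname(clusters),
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "clusters.tsv"))
  write_tsv_strict(edges, file.path(out_dir, "edges.tsv"))
  write_tsv_strict(keys, file.path(out_dir, "keystones.tsv"))
  write_tsv_strict(clab$tests, file.path(out_dir, "cluster_group_tests.tsv"))

  ## module cumulative abundance (planted shift)
  mod_test <- module_abundance_test(cohort$table, module)
  write_tsv_strict(mod_test$tests, file.path(out_dir, "module_group_tests.tsv"))

  ## exclusivity screen on a planted pangenome
  pang <- gen_pangenome(sgb_ids, module, n_genes = cfg$n_genes,
                        n_exclusive = cfg$n_exclusive, seed = seeds[5])
  excl <- exclusive_genes(pang$gpm, module)
  write_tsv_strict(excl[, c("feature_id", "category", "length_bp", "n_owners")],
                   file.path(out_dir, "exclusive_genes.tsv"))

  ## prevalence of exclusive genes and of a BGC panel across populations
  mc <- gen_mapping_counts(excl$feature_id, excl$length_bp, seed = seeds[6])
  prev <- prevalence(rpkm(mc$counts), mc$populations)
  write_tsv_strict(prev$prevalence, file.path(out_dir, "gene_prevalence.tsv"),
                   rownames_as = "feature_id")
  bgc_classes <- default_bgc_classes(cfg$n_bgcs)
  bgc_mc <- gen_mapping_counts(names(bgc_classes),
                               rep(20000, cfg$n_bgcs),
                               rural_only = names(bgc_classes)[
                                 bgc_classes %in% c("arylpolyene", "T1PKS",
                                                    "terpene", "betalactone")],
                               seed = seeds[7])
  bgc <- bgc_prevalence(bgc_mc$counts, bgc_mc$populations, bgc_classes)
  write_tsv_strict(bgc$prevalence, file.path(out_dir, "bgc_prevalence.tsv"),
                   rownames_as = "bgc_id")
  write_tsv_strict(bgc$class_prevalence,
                   file.path(out_dir, "bgc_class_prevalence.tsv"),
                   rownames_as = "product_class")

  ## strain-sharing calibration and calls
  spairs <- gen_strain_pairs(strain_spec(seed = seeds[8]))
  related <- spairs$pairs$ngd[spairs$pairs$relation == "same_group_pair"]
  unrelated <- spairs$pairs$ngd[spairs$pairs$relation == "unrelated_pair"]
  thr <- calibrate_threshold(related, unrelated)
  query <- spairs$pairs[spairs$pairs$relation == "unrelated_pair", ]
  query$relation <- "query_pair"
  sharing <- call_sharing(query, stats::setNames(list(thr),
                                                 unique(query$sgb_id)))
  write_json_det(list(threshold = thr,
                      n_events = sum(sharing$counts),
                      events = sharing$events),
                 file.path(out_dir, "strain_sharing.json"))

  ## run summary
  summary <- list(
    n_mags_input = nrow(magset$mags),
    n_mags_retained = nrow(retained),
    n_sgbs = nrow(sgbs),
    permanova_pseudo_F = perm$pseudo_F,
    permanova_p = perm$p_value,
    n_sgbs_q_le_0.05 = sum(kw$q_value <= 0.05),
    n_network_sgbs = nrow(tau),
    n_clusters = length(unique(clusters)),
    n_keystones = sum(keys$is_keystone),
    wp_module_size = length(module),
    module_p_forest_vs_village = mod_test$tests$p_value[
      mod_test$tests$group_a == "baka_forest" &
      mod_test$tests$group_b == "nzime_village"],
    n_exclusive_genes = nrow(excl),
    n_bgcs = cfg$n_bgcs,
    strain_threshold = thr$threshold,
    strain_youden_J = thr$youden_J,
    strain_false_sharing_rate = thr$false_sharing_rate,
    n_sharing_events = sum(sharing$counts))
  write_json_det(summary, file.path(out_dir, "summary.json"))

  invisible(list(sgbs = sgbs, key_results = key_results, module = module,
                 cohort = cohort, permanova = perm, kw = kw, tau = tau,
                 clusters = clusters, centralities = cent, keystones = keys,
                 module_test = mod_test, exclusive = excl, prevalence = prev,
                 bgc = bgc, strain_threshold = thr, sharing = sharing,
                 summary = summary))
}
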