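# Synthetic-data generators reproducing the statistical structure the
# pipeline assumes: a three-group cohort with a compositional gradient and
# a planted wild-plant module, pangenomes with planted module-exclusive
# genes, metabolic networks with planted substrate-degrader guilds, and
# marker trees realizing prescribed related/unrelated nGD distributions.
# Every generator is a pure function of its spec (seed included) and
# returns the ground truth needed to score the downstream stages.

#' Specification of a synthetic three-group cohort
#'
#' Defaults mirror a forager-to-farmer field cohort: 161 SGBs over
#' 16 forest-camp, 10 settled, and 18 farming-village samples, log-normal
#' abundances with multiplicative group effects. Gradient SGBs change
#' monotonically across the ordered groups (half increasing toward the
#' forest end, half decreasing); module SGBs (the planted wild-plant
#' guild) are shifted up toward the forest end.
#'
#' @param n_sgbs Number of SGBs.
#' @param n_per_group Named integer vector of samples for the three groups,
#'   ordered from most forest-associated to most market-associated.
#' @param n_gradient Number of gradient SGBs (used when `gradient_sgbs` is
#'   `NULL`).
#' @param gradient_sgbs Optional explicit gradient SGB ids.
#' @param gradient_effect Log-scale effect per group step for gradient
#'   SGBs (natural log; default `log(3)`).
#' @param module_sgbs Optional explicit module SGB ids (default: the
#'   `n_module` SGBs after the gradient ones).
#' @param n_module Module size when `module_sgbs` is `NULL` (default 26).
#' @param module_effect Log-scale upward shift per group step toward the
#'   first group for module SGBs (default `log(2)`).
#' @param sigma Log-normal noise standard deviation (> 0).
#' @param species_sd Between-species standard deviation of the log-scale
#'   baseline abundance; the default 3 produces the heavy-tailed
#'   rank-abundance structure of real SGB tables, with roughly a tenth of
#'   SGBs too rare to pass the usual 10-gcpm/2-sample network gate.
#' @param total_gcpm Per-sample compositional total after closure.
#' @param detection_limit Abundances below this gcpm value after closure
#'   are recorded as 0, mimicking the detection floor of finite sequencing
#'   depth (gives realistic presence/absence structure).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sgbs = 161,
                        n_per_group = c(baka_forest = 16, baka_settled = 10,
                                        nzime_village = 18),
                        n_gradient = 6, gradient_sgbs = NULL,
                        gradient_effect = log(3),
                        module_sgbs = NULL, n_module = 26,
                        module_effect = log(2),
                        sigma = 1, species_sd = 3, total_gcpm = 1e6,
                        detection_limit = 5, seed = 1) {
  stopifnot(length(n_per_group) == 3, !is.null(names(n_per_group)),
            sigma > 0, n_sgbs >= 2)
  sgb_ids <- sprintf("SGB_%04d", seq_len(n_sgbs))
  if (is.null(gradient_sgbs))
    gradient_sgbs <- sgb_ids[seq_len(min(n_gradient, n_sgbs))]
  if (is.null(module_sgbs)) {
    pool <- setdiff(sgb_ids, gradient_sgbs)
    module_sgbs <- pool[seq_len(min(n_module, length(pool)))]
  }
  stopifnot(all(gradient_sgbs %in% sgb_ids), all(module_sgbs %in% sgb_ids))
  structure(list(n_sgbs = n_sgbs, sgb_ids = sgb_ids,
                 n_per_group = n_per_group,
                 gradient_sgbs = gradient_sgbs,
                 gradient_effect = gradient_effect,
                 module_sgbs = module_sgbs, module_effect = module_effect,
                 sigma = sigma, species_sd = species_sd,
                 total_gcpm = total_gcpm,
                 detection_limit = detection_limit, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Log-normal SGB abundances with multiplicative group effects for the
#' planted gradient and module SGBs, closed to a constant per-sample total
#' (compositional closure mimicking per-million normalization), plus a
#' random coalescent tree over the SGBs.
#'
#' @param spec A [cohort_spec()].
#' @return List with `table` (an [abundance_table()]), `tree` (`phylo`),
#'   and `truth` (planted gradient directions, module membership, spec).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n_samp <- length(groups)
  sample_ids <- sprintf("%s_%02d", groups, stats::ave(seq_len(n_samp),
                                                      groups, FUN = seq_along))
  # group index: first (forest) group = 2 steps, middle = 1, last = 0
  step <- (length(spec$n_per_group) - 1) - (match(groups, names(spec$n_per_group)) - 1)
  base <- stats::rnorm(spec$n_sgbs, mean = 0, sd = spec$species_sd)
  names(base) <- spec$sgb_ids
  # planted SGBs are detectable taxa (the real differential taxa are):
  # draw their baselines from a moderately abundant stratum
  planted <- union(spec$gradient_sgbs, spec$module_sgbs)
  base[planted] <- stats::rnorm(length(planted), mean = 2, sd = 1)
  direction <- stats::setNames(rep(0, spec$n_sgbs), spec$sgb_ids)
  grad <- spec$gradient_sgbs
  if (length(grad))
    direction[grad] <- rep(c(1, -1), length.out = length(grad))
  effect <- stats::setNames(rep(0, spec$n_sgbs), spec$sgb_ids)
  effect[grad] <- direction[grad] * spec$gradient_effect
  effect[spec$module_sgbs] <- effect[spec$module_sgbs] + spec$module_effect
  mu <- outer(base, rep(1, n_samp)) + outer(effect, step)
  vals <- exp(mu + matrix(stats::rnorm(spec$n_sgbs * n_samp, sd = spec$sigma),
                          spec$n_sgbs, n_samp))
  vals <- sweep(vals, 2, colSums(vals), "/") * spec$total_gcpm
  vals[vals < spec$detection_limit] <- 0
  dimnames(vals) <- list(spec$sgb_ids, sample_ids)
  meta <- data.frame(sample_id = sample_ids, group = groups,
                     total_reads = rep(8e6, n_samp),
                     stringsAsFactors = FALSE)
  tree <- ape::rcoal(spec$n_sgbs, tip.label = spec$sgb_ids)
  list(table = abundance_table(vals, meta), tree = tree,
       truth = list(gradient_sgbs = grad,
                    gradient_direction = direction[grad],
                    module_sgbs = spec$module_sgbs,
                    spec = spec))
}

#' Generate a synthetic pangenome with planted module-exclusive genes
#'
#' Plants `n_exclusive` genes carrying screen-relevant annotations that
#' occur only in module SGBs; background genes are scattered freely, but
#' any background gene carrying a screen-relevant annotation is forced to
#' appear in at least one non-module SGB so that the planted set is
#' exactly the exclusivity screen's ground truth.
#'
#' @param sgb_ids All SGB ids (columns).
#' @param module Module SGB ids (subset of `sgb_ids`, non-empty).
#' @param n_genes Total number of genes including the planted ones.
#' @param n_exclusive Number of planted module-exclusive annotated genes
#'   (default 29).
#' @param categories Screen-relevant annotation categories for planted
#'   genes.
#' @param background_p Bernoulli presence probability for background genes.
#' @param seed Integer seed.
#' @return List with `gpm` (a [gene_presence()]) and `truth` (planted
#'   exclusive gene ids).
#' @export
gen_pangenome <- function(sgb_ids, module, n_genes = 1000, n_exclusive = 29,
                          categories = c("CAZy-like", "xenobiotic-like"),
                          background_p = 0.2, seed = 1) {
  stopifnot(length(module) >= 1, all(module %in% sgb_ids),
            n_exclusive <= n_genes)
  set.seed(seed)
  n_sgb <- length(sgb_ids)
  non_module <- setdiff(sgb_ids, module)
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  pm <- matrix(0L, n_genes, n_sgb, dimnames = list(gene_ids, sgb_ids))
  all_cats <- c("CAZy-like", "xenobiotic-like", "other", "none")
  cat_vec <- sample(all_cats, n_genes, replace = TRUE,
                    prob = c(0.1, 0.1, 0.4, 0.4))
  planted <- gene_ids[seq_len(n_exclusive)]
  for (g in planted) {
    owners <- sample(module, size = sample.int(min(3, length(module)), 1))
    pm[g, owners] <- 1L
    cat_vec[match(g, gene_ids)] <- sample(categories, 1)
  }
  background <- setdiff(gene_ids, planted)
  for (g in background) {
    pres <- stats::rbinom(n_sgb, 1, background_p)
    if (sum(pres) == 0) pres[sample.int(n_sgb, 1)] <- 1L
    pm[g, ] <- pres
    # a screen-category background gene must not be module-exclusive
    if (cat_vec[match(g, gene_ids)] %in% categories &&
        length(non_module) && sum(pm[g, non_module]) == 0)
      pm[g, sample(non_module, 1)] <- 1L
  }
  lengths_bp <- sample(300:3000, n_genes, replace = TRUE)
  list(gpm = gene_presence(pm, lengths_bp, cat_vec), truth = planted)
}

#' Specification of synthetic metabolic networks with planted guilds
#'
#' Each guild is a cross-feeding chain: the first member converts the
#' plant's seed compounds into an intermediate, successive members extend
#' the chain, and the last member produces the target. Optionally a guild
#' step is duplicated across two species, making those two alternative
#' (either completes the chain) while unique steps stay essential.
#' Distractor reactions live in a disjoint metabolite namespace whose
#' substrates are never reachable, so they can never complete a chain;
#' generation audits this by running the expansion without each guild.
#'
#' @param n_species Total species count.
#' @param plant_names One plant per guild; defaults to the five western
#'   African rainforest wild plant foods.
#' @param guild_sizes Chain length per guild (unique steps).
#' @param redundant_guilds Indices of guilds whose final step is
#'   duplicated in an extra species (adds one species to that guild).
#' @param distractor_p Probability that a non-guild species carries a
#'   distractor reaction.
#' @param species_ids Optional explicit species ids (e.g. SGB ids).
#' @param seed Integer seed.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(n_species = 20,
                         plant_names = c("Gnetum africanum", "Irvingia spp",
                                         "Baillonella toxisperma",
                                         "Afrostyrax lepidophyllus",
                                         "Panda oleosa"),
                         guild_sizes = c(2, 2, 2, 1, 1),
                         redundant_guilds = integer(0),
                         distractor_p = 0.5, species_ids = NULL, seed = 1) {
  stopifnot(length(guild_sizes) == length(plant_names))
  n_guild <- sum(guild_sizes) + length(redundant_guilds)
  stopifnot(n_guild <= n_species)
  if (is.null(species_ids))
    species_ids <- sprintf("SP_%03d", seq_len(n_species))
  stopifnot(length(species_ids) == n_species)
  structure(list(n_species = n_species, plant_names = plant_names,
                 guild_sizes = guild_sizes,
                 redundant_guilds = redundant_guilds,
                 distractor_p = distractor_p, species_ids = species_ids,
                 seed = seed),
            class = "network_spec")
}

#' Generate synthetic metabolic networks, profiles, and ground truth
#'
#' @param spec A [network_spec()].
#' @return List with `networks` (named list of [metabolic_network()]),
#'   `profiles` (named list of [substrate_profile()]), and `truth` (per
#'   plant: guild members, essential and alternative species).
#' @export
gen_networks <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  ids <- spec$species_ids
  rxns <- stats::setNames(vector("list", length(ids)), ids)
  for (s in ids) rxns[[s]] <- list()
  truth <- list()
  cursor <- 0
  for (gi in seq_along(spec$plant_names)) {
    plant <- spec$plant_names[gi]
    size <- spec$guild_sizes[gi]
    members <- ids[cursor + seq_len(size)]
    cursor <- cursor + size
    tag <- sprintf("P%d", gi)
    seeds <- paste0(tag, "_seed_", 1:2)
    target <- paste0(tag, "_target")
    ints <- if (size > 1) paste0(tag, "_int_", seq_len(size - 1)) else character(0)
    mets <- c(seeds[1], ints, target)
    for (k in seq_len(size)) {
      subs <- if (k == 1) seeds else mets[k]
      rxns[[members[k]]] <- c(rxns[[members[k]]],
                              list(list(substrates = subs,
                                        products = mets[k + 1])))
    }
    alternative <- character(0)
    if (gi %in% spec$redundant_guilds) {
      twin <- ids[cursor + 1]
      cursor <- cursor + 1
      last <- members[size]
      rxns[[twin]] <- c(rxns[[twin]], rxns[[last]][length(rxns[[last]])])
      alternative <- c(last, twin)
      members <- c(members, twin)
    }
    truth[[plant]] <- list(plant_name = plant, members = sort(members),
                           seeds = seeds, target = target,
                           essential = sort(setdiff(members, alternative)),
                           alternative = sort(alternative))
  }
  # distractor reactions: disjoint metabolite namespace, never reachable
  rest <- if (cursor < length(ids)) ids[(cursor + 1):length(ids)] else character(0)
  for (s in rest) {
    if (stats::runif(1) < spec$distractor_p) {
      pair <- sample(1:50, 2)
      rxns[[s]] <- c(rxns[[s]], list(list(substrates = paste0("D_", pair[1]),
                                          products = paste0("D_", pair[2]))))
    }
  }
  keep <- lengths(rxns) > 0
  networks <- lapply(ids[keep], function(s) metabolic_network(s, rxns[[s]]))
  names(networks) <- ids[keep]
  profiles <- lapply(truth, function(tr)
    substrate_profile(tr$plant_name, tr$seeds, tr$target))
  names(profiles) <- spec$plant_names
  # generation-time audit: guild removal breaks its chain, full guild works
  for (tr in truth) {
    with_guild <- producible_targets(networks, NULL, profiles[[tr$plant_name]])
    stopifnot(tr$target %in% with_guild)
    without <- setdiff(names(networks), tr$members)
    if (length(without)) {
      broken <- producible_targets(networks, without, profiles[[tr$plant_name]])
      stopifnot(!(tr$target %in% broken))
    }
  }
  list(networks = networks, profiles = profiles, truth = truth)
}

#' Specification of synthetic related/unrelated strain pairs
#'
#' Related pairs emulate same-strain retention (small nGD); unrelated
#' pairs emulate strains from different individuals with no transmission
#' (large nGD). Distributions are normal, truncated to `[0, 1)`.
#'
#' @param n_related,n_unrelated Pair counts.
#' @param related_mean,related_sd,unrelated_mean,unrelated_sd Distribution
#'   parameters on the nGD scale.
#' @param sgb_id SGB the pairs belong to.
#' @param seed Integer seed.
#' @return A list of class `strain_spec`.
#' @export
strain_spec <- function(n_related = 20, n_unrelated = 50,
                        related_mean = 0.01, related_sd = 0.005,
                        unrelated_mean = 0.5, unrelated_sd = 0.1,
                        sgb_id = "SGB_0001", seed = 1) {
  structure(list(n_related = n_related, n_unrelated = n_unrelated,
                 related_mean = related_mean, related_sd = related_sd,
                 unrelated_mean = unrelated_mean, unrelated_sd = unrelated_sd,
                 sgb_id = sgb_id, seed = seed),
            class = "strain_spec")
}

rtruncnorm01 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= 0 & x < 0.995])
  }
  out[seq_len(n)]
}

#' Generate strain-pair marker trees with prescribed nGD values
#'
#' Each pair gets a three-leaf marker tree built so that the two strain
#' leaves realize the drawn nGD exactly: a cherry `(a:x, b:x)` with
#' `x = g / (2 (1 - g))` next to a unit of outgroup branch length gives
#' `nGD(a, b) = g`. Reported nGDs are recomputed from the trees with
#' [ngd()], so the pair list is internally consistent.
#'
#' @param spec A [strain_spec()].
#' @return List with `trees` (named list of `phylo`), `pairs` (data frame
#'   `pair_id`, `sgb_id`, `sample_a`, `sample_b`, `relation`, `ngd`), and
#'   `truth` (the drawn distributions).
#' @export
gen_strain_pairs <- function(spec) {
  stopifnot(inherits(spec, "strain_spec"))
  set.seed(spec$seed)
  g_rel <- rtruncnorm01(spec$n_related, spec$related_mean, spec$related_sd)
  g_unr <- rtruncnorm01(spec$n_unrelated, spec$unrelated_mean, spec$unrelated_sd)
  g_all <- c(g_rel, g_unr)
  relation <- rep(c("same_group_pair", "unrelated_pair"),
                  c(spec$n_related, spec$n_unrelated))
  n <- length(g_all)
  pair_ids <- sprintf("pair_%03d", seq_len(n))
  trees <- vector("list", n)
  ngd_obs <- numeric(n)
  for (i in seq_len(n)) {
    g <- g_all[i]
    x <- g / (2 * (1 - g))
    a <- sprintf("%s_a", pair_ids[i]); b <- sprintf("%s_b", pair_ids[i])
    txt <- sprintf("((%s:%.12f,%s:%.12f):0.5,outgroup:0.5);", a, x, b, x)
    trees[[i]] <- ape::read.tree(text = txt)
    ngd_obs[i] <- ngd(trees[[i]], a, b)
  }
  names(trees) <- pair_ids
  pairs <- data.frame(pair_id = pair_ids, sgb_id = spec$sgb_id,
                      sample_a = sprintf("%s_a", pair_ids),
                      sample_b = sprintf("%s_b", pair_ids),
                      relation = relation, ngd = ngd_obs,
                      stringsAsFactors = FALSE)
  list(trees = trees, pairs = pairs,
       truth = list(ngd_drawn = g_all, relation = relation, spec = spec))
}

# Synthetic MAG set with planted clusters, for exercising QC filtering and
# dereplication without genome data: cluster co-members sit at distances
# well inside the species threshold, distinct clusters well outside.
gen_mag_set <- function(n_pass = 628, n_fail = 72, n_clusters = 161,
                        within_max = 0.045, between_min = 0.2, seed = 1) {
  stopifnot(n_clusters <= n_pass)
  set.seed(seed)
  n <- n_pass + n_fail
  mag_ids <- sprintf("MAG_%04d", seq_len(n))
  completeness <- c(stats::runif(n_pass, 55, 100), stats::runif(n_fail, 10, 50))
  contamination <- c(stats::runif(n_pass, 0, 4.5), stats::runif(n_fail, 5, 20))
  mags <- mag_records(mag_ids, completeness, contamination,
                     genome_size = round(stats::runif(n, 1.5e6, 6e6)))
  assign <- c(seq_len(n_clusters),
              sample.int(n_clusters, n_pass - n_clusters, replace = TRUE))
  pass_ids <- mag_ids[seq_len(n_pass)]
  same <- outer(assign, assign, "==")
  ut <- upper.tri(same)
  nv <- sum(ut)
  vals <- ifelse(same[ut], stats::runif(nv, 0.001, within_max),
                 stats::runif(nv, between_min, 0.9))
  d <- matrix(0, n_pass, n_pass, dimnames = list(pass_ids, pass_ids))
  d[ut] <- vals
  d <- d + t(d)
  list(mags = mags, dist = distance_matrix(d),
       truth = list(cluster = stats::setNames(assign, pass_ids),
                    n_clusters = n_clusters))
}

# Synthetic mapping counts for a feature panel over rural + industrial
# metagenome panels: rural-only features get reads only in rural samples.
gen_mapping_counts <- function(feature_ids, feature_length_bp,
                               n_rural = 12, n_industrial = 12,
                               rural_only = feature_ids,
                               mean_depth = 50, seed = 1) {
  set.seed(seed)
  mg_ids <- c(sprintf("rural_%02d", seq_len(n_rural)),
              sprintf("industrial_%02d", seq_len(n_industrial)))
  pops <- stats::setNames(rep(c("rural", "industrial"),
                              c(n_rural, n_industrial)), mg_ids)
  cnt <- matrix(0, length(feature_ids), length(mg_ids),
                dimnames = list(feature_ids, mg_ids))
  for (f in feature_ids) {
    cols <- if (f %in% rural_only) which(pops == "rural") else seq_along(mg_ids)
    cnt[f, cols] <- stats::rpois(length(cols), mean_depth)
  }
  list(counts = mapping_counts(cnt, feature_length_bp,
                               rep(2e6, length(mg_ids))),
       populations = pops)
}
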