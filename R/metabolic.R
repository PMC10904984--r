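# Metabolic key-species identification by boolean network expansion
# ("scope") over combined per-species reaction networks: which metabolites
# are reachable from a plant's seed compounds, which species subsets are
# inclusion-minimal communities producing all reachable targets, and which
# species are essential (in every minimal community) versus alternative
# (in some but not all).

#' Network-expansion scope of a species community
#'
#' Iterates to a fixpoint: a reaction of any included species fires when
#' all its substrates are already reachable, adding its products. The
#' expansion is monotone and bounded by the metabolite universe, so it
#' always terminates; the result contains the seeds and cannot be extended
#' by any community reaction.
#'
#' @param networks Named list of [metabolic_network()] objects.
#' @param species_subset Character vector of species ids to include
#'   (default: all).
#' @param seeds Character vector of seed metabolite ids.
#' @return List with `species_set` and the sorted `reachable_metabolites`.
#' @export
scope <- function(networks, species_subset = NULL, seeds) {
  if (is.null(names(networks)))
    stop("networks must be a named list", call. = FALSE)
  if (is.null(species_subset)) species_subset <- names(networks)
  unknown <- setdiff(species_subset, names(networks))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  rxns <- unlist(lapply(networks[species_subset], `[[`, "reactions"),
                 recursive = FALSE, use.names = FALSE)
  reached <- unique(as.character(seeds))
  active <- rep(TRUE, length(rxns))
  repeat {
    fired <- FALSE
    for (i in which(active)) {
      r <- rxns[[i]]
      if (all(r$substrates %in% reached)) {
        active[i] <- FALSE
        new <- setdiff(r$products, reached)
        if (length(new)) {
          reached <- c(reached, new)
          fired <- TRUE
        }
      }
    }
    if (!fired) break
  }
  list(species_set = species_subset,
       reachable_metabolites = sort(reached))
}

#' Producible targets of a substrate profile
#'
#' Targets of the profile reachable by network expansion from the profile's
#' seeds, given the community `species_subset`.
#'
#' @inheritParams scope
#' @param profile A [substrate_profile()].
#' @return Sorted character vector of producible target metabolites.
#' @export
producible_targets <- function(networks, species_subset = NULL, profile) {
  sc <- scope(networks, species_subset, profile$seed_metabolites)
  sort(intersect(profile$target_metabolites, sc$reachable_metabolites))
}

# species with at least one reaction firing during full-community
# expansion from the given seeds; species outside this set can never
# contribute to any subset's scope (expansion is monotone in community)
relevant_species <- function(networks, seeds) {
  full <- scope(networks, NULL, seeds)$reachable_metabolites
  keep <- vapply(networks, function(net)
    any(vapply(net$reactions, function(r)
      all(r$substrates %in% full), logical(1))), logical(1))
  names(networks)[keep]
}

#' Minimal communities and key species for a substrate profile
#'
#' First determines the producible targets under the full community, then
#' enumerates the inclusion-minimal species subsets (of size up to
#' `max_size`) whose scope still covers all of them. Essential species
#' belong to every minimal community; alternative species to some but not
#' all. Candidate species are pre-filtered to those with at least one
#' reaction firing under the full-community expansion (others provably
#' cannot matter). When more than `exhaustive_cutoff` candidates remain,
#' a greedy deletion heuristic seeds the search instead and results carry
#' a non-exhaustiveness warning.
#'
#' @inheritParams producible_targets
#' @param max_size Largest community size enumerated.
#' @param exhaustive_cutoff Candidate-species count above which the greedy
#'   fallback is used.
#' @return An object of class `key_species_result`: list with
#'   `plant_name`, `producible_targets`, `unreachable_targets`,
#'   `essential_species`, `alternative_species`, `minimal_communities`
#'   (list of character vectors), and `exhaustive` flag.
#' @export
minimal_communities <- function(networks, profile, max_size = 8,
                                exhaustive_cutoff = 20) {
  targets <- producible_targets(networks, NULL, profile)
  unreachable <- setdiff(profile$target_metabolites, targets)
  result <- function(mcs, exhaustive) {
    ess <- if (length(mcs)) sort(Reduce(intersect, mcs)) else character(0)
    alt <- if (length(mcs)) sort(setdiff(unique(unlist(mcs)), ess)) else character(0)
    structure(list(plant_name = profile$plant_name,
                   producible_targets = targets,
                   unreachable_targets = sort(unreachable),
                   essential_species = ess,
                   alternative_species = alt,
                   minimal_communities = mcs,
                   exhaustive = exhaustive),
              class = "key_species_result")
  }
  if (!length(targets)) return(result(list(), TRUE))
  cand <- relevant_species(networks, profile$seed_metabolites)
  covers <- function(subset)
    length(setdiff(targets,
                   producible_targets(networks, subset, profile))) == 0
  if (length(cand) <= exhaustive_cutoff) {
    mcs <- list()
    for (k in seq_len(min(max_size, length(cand)))) {
      for (combo in utils::combn(cand, k, simplify = FALSE)) {
        if (any(vapply(mcs, function(m) all(m %in% combo), logical(1))))
          next                          # superset of a known minimal set
        if (covers(combo)) mcs <- c(mcs, list(sort(combo)))
      }
    }
    return(result(mcs, TRUE))
  }
  warning("more than ", exhaustive_cutoff, " candidate species; ",
          "greedy search may miss minimal communities", call. = FALSE)
  # greedy deletion from the full candidate set down to one minimal
  # community, then probe single-species replacements for alternatives
  comm <- cand
  for (sp in cand) {
    trial <- setdiff(comm, sp)
    if (length(trial) && covers(trial)) comm <- trial
  }
  mcs <- list(sort(comm))
  for (sp in comm) {
    without <- setdiff(cand, sp)
    if (!covers(without)) next          # sp irreplaceable
    alt_comm <- without
    for (s2 in without) {
      trial <- setdiff(alt_comm, s2)
      if (length(trial) && covers(trial)) alt_comm <- trial
    }
    alt_comm <- sort(alt_comm)
    if (!any(vapply(mcs, identical, logical(1), alt_comm)))
      mcs <- c(mcs, list(alt_comm))
  }
  result(mcs, FALSE)
}

#' Union of key species over substrate profiles
#'
#' The wild-plant module is the union, over the per-plant results, of the
#' species involved in degrading at least one substrate profile: essential
#' species always, alternative species unless `essential_only = TRUE`.
#'
#' @param results List of `key_species_result` objects (one per plant).
#' @param essential_only Restrict to essential species.
#' @return Sorted character vector of species ids.
#' @export
wp_module <- function(results, essential_only = FALSE) {
  sets <- lapply(results, function(r)
    if (essential_only) r$essential_species
    else union(r$essential_species, r$alternative_species))
  sort(unique(unlist(sets)))
}

#' Cumulative module abundance and pairwise group tests
#'
#' Sums abundance over the module SGBs per sample and compares each group
#' pair with a rank-sum test. Module members missing from the table are
#' skipped with a warning.
#'
#' @param table An [abundance_table()].
#' @param module Character vector of SGB ids (non-empty after intersection
#'   with the table).
#' @return List with `per_sample` (named numeric vector of cumulative
#'   gcpm), `used_sgbs`, and `tests` (data frame `group_a`, `group_b`,
#'   `p_value`).
#' @export
module_abundance_test <- function(table, module) {
  if (!length(module)) stop("module is empty", call. = FALSE)
  present <- intersect(module, rownames(table$values))
  skipped <- setdiff(module, present)
  if (length(skipped))
    warning("module SGBs absent from table, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(present))
    stop("no module SGB present in the abundance table", call. = FALSE)
  sums <- colSums(table$values[present, , drop = FALSE])
  groups <- table$meta$group
  glev <- sort(unique(groups))
  tests <- do.call(rbind, lapply(utils::combn(glev, 2, simplify = FALSE),
                                 function(pr) {
    p <- suppressWarnings(stats::wilcox.test(sums[groups == pr[1]],
                                             sums[groups == pr[2]])$p.value)
    data.frame(group_a = pr[1], group_b = pr[2], p_value = p,
               stringsAsFactors = FALSE)
  }))
  list(per_sample = sums, used_sgbs = sort(present), tests = tests)
}
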