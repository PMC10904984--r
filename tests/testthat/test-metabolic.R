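# Network expansion (scope), producible targets, minimal communities,
# wild-plant module, and the module abundance comparison

test_that("scope expands to the documented fixpoints", {
  nets <- list(sp = metabolic_network("sp", list(
    list(substrates = "A", products = "B"),
    list(substrates = c("B", "C"), products = "D"))))
  # no applicable reactions: reachable = seeds
  expect_equal(scope(nets, NULL, "Z")$reachable_metabolites, "Z")
  # A -> B fires; B + C -> D stays blocked without C
  expect_equal(scope(nets, NULL, "A")$reachable_metabolites,
               sort(c("A", "B")))
  # with C supplied the chain completes
  expect_equal(scope(nets, NULL, c("A", "C"))$reachable_metabolites,
               sort(c("A", "B", "C", "D")))
  expect_error(scope(nets, "ghost", "A"), "unknown species")
})

test_that("scope is monotone and idempotent and matches the naive oracle", {
  set.seed(17)
  for (rep in 1:30) {
    n_sp <- sample(2:6, 1)
    mets <- sprintf("m%02d", 1:30)
    nets <- lapply(seq_len(n_sp), function(i) {
      n_rxn <- sample(1:8, 1)
      metabolic_network(sprintf("sp%d", i), lapply(seq_len(n_rxn), function(r)
        list(substrates = sample(mets, sample(1:3, 1)),
             products = sample(mets, sample(1:2, 1)))))
    })
    names(nets) <- sprintf("sp%d", seq_len(n_sp))
    seeds <- sample(mets, 3)
    full <- scope(nets, NULL, seeds)$reachable_metabolites
    expect_equal(full, oracle_scope(nets, names(nets), seeds))
    # monotone in community
    sub <- sample(names(nets), n_sp - 1)
    part <- scope(nets, sub, seeds)$reachable_metabolites
    expect_true(all(part %in% full))
    # monotone in seeds and idempotent
    expect_true(all(full %in%
      scope(nets, NULL, c(seeds, sample(mets, 1)))$reachable_metabolites))
    expect_equal(scope(nets, NULL, full)$reachable_metabolites, full)
  }
})

test_that("producible targets intersect the scope with the profile", {
  nets <- toy_networks()
  prof <- substrate_profile("plant", "seed", "tgt")
  expect_equal(producible_targets(nets, NULL, prof), "tgt")
  # empty community reaches nothing beyond the seeds
  expect_equal(producible_targets(nets, character(0), prof), character(0))
  # distractor-only community cannot produce the target
  expect_equal(producible_targets(nets, "D", prof), character(0))
})

test_that("minimal communities classify essential vs alternative species", {
  nets <- toy_networks()      # A -> i1; B or C finish; D irrelevant
  prof <- substrate_profile("plant", "seed", "tgt")
  res <- minimal_communities(nets, prof)
  expect_true(res$exhaustive)
  expect_setequal(res$minimal_communities,
                  list(c("A", "B"), c("A", "C")))
  expect_equal(res$essential_species, "A")
  expect_equal(res$alternative_species, c("B", "C"))

  # single self-sufficient degrader
  nets1 <- list(X = metabolic_network("X", list(
                  list(substrates = "seed", products = "tgt"))),
                Y = metabolic_network("Y", list(
                  list(substrates = "u", products = "v"))))
  res1 <- minimal_communities(nets1, prof)
  expect_equal(res1$minimal_communities, list("X"))
  expect_equal(res1$essential_species, "X")
  expect_equal(res1$alternative_species, character(0))

  # obligate cross-feeding pair: both essential
  nets2 <- list(A = metabolic_network("A", list(
                  list(substrates = "seed", products = "mid"))),
                B = metabolic_network("B", list(
                  list(substrates = "mid", products = "tgt"))))
  res2 <- minimal_communities(nets2, prof)
  expect_equal(res2$minimal_communities, list(c("A", "B")))
  expect_setequal(res2$essential_species, c("A", "B"))

  # unreachable target reported, no minimal communities
  prof_un <- substrate_profile("plant", "seed", "unmakeable")
  res3 <- minimal_communities(nets, prof_un)
  expect_equal(res3$minimal_communities, list())
  expect_equal(res3$unreachable_targets, "unmakeable")
})

test_that("minimal communities equal exhaustive powerset enumeration", {
  set.seed(23)
  for (rep in 1:20) {
    n_sp <- sample(3:7, 1)
    mets <- sprintf("m%d", 1:12)
    nets <- lapply(seq_len(n_sp), function(i)
      metabolic_network(sprintf("sp%d", i), lapply(seq_len(sample(1:4, 1)),
        function(r) list(substrates = sample(mets, sample(1:2, 1)),
                         products = sample(mets, 1)))))
    names(nets) <- sprintf("sp%d", seq_len(n_sp))
    seeds <- sample(mets, 2)
    tg <- setdiff(sample(mets, 3), seeds)
    if (!length(tg)) next
    prof <- substrate_profile("p", seeds, tg)
    res <- minimal_communities(nets, prof, max_size = n_sp)
    want <- oracle_minimal_communities(nets, prof)
    expect_setequal(res$minimal_communities, want)
    # minimality audit: dropping any member loses a producible target
    for (mc in res$minimal_communities) {
      expect_true(all(res$producible_targets %in%
                        producible_targets(nets, mc, prof)))
      if (length(mc) > 1) for (sp in mc)
        expect_false(all(res$producible_targets %in%
                           producible_targets(nets, setdiff(mc, sp), prof)))
    }
  }
})

test_that("wp_module unions essential and alternative species", {
  mk <- function(plant, ess, alt) structure(
    list(plant_name = plant, essential_species = ess,
         alternative_species = alt),
    class = "key_species_result")
  empty <- lapply(1:5, function(i) mk(paste0("p", i), character(0), character(0)))
  expect_equal(wp_module(empty), character(0))
  two <- list(mk("p1", "X", character(0)), mk("p2", "Y", character(0)))
  expect_equal(wp_module(two), c("X", "Y"))
  withalt <- list(mk("p1", "X", "Z"), mk("p2", "Y", character(0)))
  expect_equal(wp_module(withalt), c("X", "Y", "Z"))
  expect_equal(wp_module(withalt, essential_only = TRUE), c("X", "Y"))
})

test_that("module abundance test sums members and flags group shifts", {
  set.seed(6)
  vals <- matrix(rexp(80, 0.1), 8, 10,
                 dimnames = list(sprintf("S%d", 1:8), paste0("s", 1:10)))
  groups <- rep(c("g1", "g2"), each = 5)
  meta <- data.frame(sample_id = colnames(vals), group = groups,
                     total_reads = 1e6)
  mod <- rownames(vals)[1:3]
  vals[mod, groups == "g1"] <- vals[mod, groups == "g1"] * 100
  tab <- abundance_table(vals, meta)
  res <- module_abundance_test(tab, mod)
  expect_equal(res$per_sample, colSums(vals[mod, ]))
  expect_lt(res$tests$p_value, 0.05)
  expect_gt(median(res$per_sample[groups == "g1"]),
            median(res$per_sample[groups == "g2"]))

  full <- module_abundance_test(tab, rownames(vals))
  expect_equal(full$per_sample, colSums(vals))
  expect_error(module_abundance_test(tab, character(0)), "empty")
  expect_warning(module_abundance_test(tab, c(mod, "ghost")), "skipped")
})
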