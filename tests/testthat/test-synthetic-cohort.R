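test_that("sim_config validates rates, matrices and founder distributions", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(fission_rate = 1.5), "\\[0, 1\\]")
  bad_tm <- default_transition_matrix()
  bad_tm[1, 1] <- 0.5
  expect_error(sim_config(transition_matrix = bad_tm), "sum to 1")
  expect_error(sim_config(founder_distribution = c(NOT_A_PHENOTYPE = 1)),
               "founder_distribution")
  expect_error(
    simulate_cohort(sim_config(glands_per_patient = 10, biopsy_size = 8,
                               biopsies_per_patient = 2), seed = 1),
    "exceeds"
  )
  expect_error(simulate_cohort(sim_config()), "seed")
})

test_that("without mutations the variant table is empty and all glands are singleton clones", {
  cfg <- sim_config(n_patients = 2, mutation_rate = 0, n_polymorphisms = 0)
  sim <- simulate_cohort(cfg, seed = 5)
  expect_equal(sum(sim$variants$var_class != "none"), 0)
  graph <- call_clones(filter_variants(sim$variants))
  expect_equal(nrow(graph$clones), nrow(graph$nodes))
  expect_true(all(graph$clones$n_samples == 1))
})

test_that("with no transitions and cardiac founders every biopsy is monophenotypic", {
  ident <- diag(5)
  dimnames(ident) <- list(be_phenotypes(), be_phenotypes())
  cfg <- sim_config(n_patients = 3, transition_prob = 0.3,
                    transition_matrix = ident,
                    founder_distribution = c(CARDIAC = 1))
  sim <- simulate_cohort(cfg, seed = 9)
  expect_true(all(sim$glands$phenotype == "CARDIAC"))
  div <- diversity_by_specimen(classify_glands(sim$glands))
  expect_true(all(div$richness == 1))
  expect_true(all(div$shannon == 0))
})

test_that("the classifier recovers the simulated phenotype from marker profiles", {
  cfg <- sim_config(n_patients = 3, transition_prob = 0.25)
  sim <- simulate_cohort(cfg, seed = 21)
  classified <- classify_glands(sim$glands[, setdiff(names(sim$glands),
                                                     "phenotype")])
  expect_equal(classified$phenotype, sim$glands$phenotype)
})

test_that("mutation sets grow monotonically along every lineage", {
  cfg <- sim_config(n_patients = 2, mutation_rate = 2, fission_rate = 0.2)
  sim <- simulate_cohort(cfg, seed = 13)
  muts <- split(sim$mutations$event_id, sim$mutations$gland_id)
  gen <- sim$genealogy
  children <- gen[!is.na(gen$parent_id), ]
  expect_gt(nrow(children), 0)
  for (i in seq_len(nrow(children))) {
    parent_set <- muts[[children$parent_id[i]]]
    child_set <- muts[[children$gland_id[i]]]
    expect_true(all(parent_set %in% child_set))
  }
  # the parent map is acyclic: every parent was born strictly earlier
  born <- stats::setNames(gen$generation, gen$gland_id)
  expect_true(all(born[children$parent_id] < children$generation))
})

test_that("identical config and seed give identical output tables", {
  cfg <- scenario_presets()$predysplasia
  s1 <- simulate_cohort(cfg, seed = 77)
  s2 <- simulate_cohort(cfg, seed = 77)
  expect_identical(s1$glands, s2$glands)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$genealogy, s2$genealogy)
  s3 <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(s1$variants, s3$variants))
})

test_that("mutation accrual is independent of phenotype (neutrality)", {
  cfg <- sim_config(n_patients = 8, transition_prob = 0.25,
                    mutation_rate = 2, fission_rate = 0.2)
  sim <- simulate_cohort(cfg, seed = 31)
  counts <- table(factor(sim$mutations$gland_id,
                         levels = sim$glands$gland_id))
  by_ph <- split(as.integer(counts), sim$glands$phenotype)
  by_ph <- by_ph[lengths(by_ph) >= 5]
  expect_gte(length(by_ph), 2)
  expect_gt(kruskal_wallis(by_ph)$p_value, 0.01)
})

test_that("stroma carries the polymorphisms and nothing else; filtering removes them everywhere", {
  cfg <- sim_config(n_patients = 2, n_polymorphisms = 2)
  sim <- simulate_cohort(cfg, seed = 8)
  stroma <- sim$variants[sim$variants$tissue == "stroma" &
                           sim$variants$var_class != "none", ]
  expect_equal(nrow(stroma), 4)  # 2 polymorphisms x 2 patients
  expect_true(all(variant_key(stroma) %in% sim$polymorphisms))
  kept <- filter_variants(sim$variants)  # stroma subtraction alone
  expect_false(any(kept$key %in% sim$polymorphisms, na.rm = TRUE))
  # polymorphism-list filtering alone removes them too
  kept2 <- filter_variants(sim$variants, polymorphisms = sim$polymorphisms,
                           subtract_stroma = FALSE)
  expect_false(any(kept2$key %in% sim$polymorphisms, na.rm = TRUE))
})

test_that("called clones recover the true genealogy with perfect pairwise precision", {
  total_called <- 0; total_correct <- 0; total_true <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_patients = 1, glands_per_patient = 50,
                      n_generations = 10, mutation_rate = 2,
                      biopsy_size = 10, biopsies_per_patient = 5,
                      n_polymorphisms = 0, transition_prob = 0.05)
    sim <- simulate_cohort(cfg, seed = s)
    graph <- call_clones(filter_variants(sim$variants))
    acc <- clone_accuracy(graph, sim$truth_clones)
    total_called <- total_called + acc$n_called_pairs
    total_correct <- total_correct + acc$n_correct_pairs
    total_true <- total_true + acc$n_true_pairs
  }
  expect_gt(total_called, 0)
  expect_equal(total_correct, total_called)  # precision 1: no false merges
  expect_equal(total_correct, total_true)    # every true pair is marked
})

test_that("scenario presets are valid and hold cohort structure", {
  presets <- scenario_presets()
  expect_setequal(names(presets), c("nondysplastic", "predysplasia",
                                    "adjacent_dysplasia", "neo_be"))
  for (p in presets) expect_silent(validate_sim_config(p))
  expect_equal(presets$nondysplastic$n_patients, 19L)
  expect_equal(presets$predysplasia$n_patients, 12L)
  expect_equal(presets$adjacent_dysplasia$n_patients, 18L)
  expect_equal(presets$neo_be$n_patients, 19L)
  expect_equal(presets$neo_be$transition_prob, 0)
})

test_that("neo-BE cohorts show zero within-biopsy diversity for any seed", {
  for (s in c(2, 19, 101)) {
    sim <- simulate_cohort(scenario_presets()$neo_be, seed = s)
    div <- diversity_by_specimen(classify_glands(sim$glands))
    expect_true(all(div$shannon == 0))
    expect_true(all(div$richness == 1))
  }
})
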