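test_that("variant keys use position+allele for SNVs and region-level keys for tract insertions", {
  v <- tibble::tibble(
    position = c(10492L, 303L, 2283L),
    ref = c("T", "C", "T"), alt = c("C", "Cins", "C"),
    var_class = c("SNV", "insertion", "SNV"),
    region = c("MT-ND4L", "MT-OHR", "MT-RNR2")
  )
  expect_equal(variant_key(v), c("m.10492T>C", "MT-OHR:Cins", "m.2283T>C"))
})

test_that("filtering removes stromal, polymorphic and unconfirmed variants", {
  v <- dplyr::bind_rows(
    tibble::tibble(sample_id = "g1", tissue = "epithelial_gland",
                   patient_id = "p1", position = 100L, ref = "A", alt = "G",
                   var_class = "SNV", zygosity = "homoplasmic",
                   het_level = NA_real_, confirmed = TRUE,
                   region = NA_character_),
    tibble::tibble(sample_id = "g1", tissue = "epithelial_gland",
                   patient_id = "p1", position = 200L, ref = "C", alt = "T",
                   var_class = "SNV", zygosity = "homoplasmic",
                   het_level = NA_real_, confirmed = TRUE,
                   region = NA_character_),
    tibble::tibble(sample_id = "g1", tissue = "epithelial_gland",
                   patient_id = "p1", position = 300L, ref = "G", alt = "A",
                   var_class = "SNV", zygosity = "homoplasmic",
                   het_level = NA_real_, confirmed = FALSE,
                   region = NA_character_),
    tibble::tibble(sample_id = "p1.stroma", tissue = "stroma",
                   patient_id = "p1", position = 100L, ref = "A", alt = "G",
                   var_class = "SNV", zygosity = "homoplasmic",
                   het_level = NA_real_, confirmed = TRUE,
                   region = NA_character_)
  )
  kept <- filter_variants(v, polymorphisms = "m.200C>T")
  real <- kept[kept$var_class != "none", ]
  expect_equal(nrow(real), 0)  # stromal, polymorphic, unconfirmed all removed
  # without strict confirmation the repeat-unconfirmed call survives
  lenient <- filter_variants(v, polymorphisms = "m.200C>T",
                             require_confirmed = FALSE)
  expect_equal(lenient$key[lenient$var_class != "none"], "m.300G>A")
  # a confirmed epithelial-only non-polymorphic variant is retained; the
  # unconfirmed one still falls to strict confirmation
  keep2 <- filter_variants(v)
  expect_equal(keep2$key[keep2$var_class != "none"], "m.200C>T")
})

test_that("filtering is idempotent and demands a stroma control in subtraction mode", {
  case <- example_case("spec_intestinal")
  once <- filter_variants(case$variants)
  twice <- filter_variants(once)
  expect_equal(dplyr::arrange(once, sample_id, position),
               dplyr::arrange(twice, sample_id, position))
  no_stroma <- case$variants[case$variants$tissue != "stroma", ]
  expect_error(filter_variants(no_stroma), "stroma")
  expect_silent(filter_variants(no_stroma, subtract_stroma = FALSE))
})

test_that("cases are informative only when a retained epithelial variant remains", {
  series <- filter_variants(sequenced_case_series())
  per_case <- case_informative(series, by_patient = TRUE)
  expect_equal(nrow(per_case), 10)
  expect_equal(sum(per_case$informative), 3)
  # the case whose only mutation was shared with stroma is uninformative
  expect_false(per_case$informative[per_case$patient_id == "stromal1"])
})

test_that("a five-sample clone spanning oxyntocardiac, specialized and cardiac glands is recovered", {
  case <- example_case("oxy_spec_cardiac")
  glands <- classify_glands(case$glands)
  graph <- call_clones(filter_variants(case$variants), phenotypes = glands)
  expect_equal(nrow(graph$nodes), 6)
  sizes <- sort(graph$clones$n_samples, decreasing = TRUE)
  expect_equal(sizes, c(5L, 1L))
  big <- graph$clones[graph$clones$n_samples == 5, ]
  expect_equal(big$sample_ids, "caseA.g1;caseA.g2;caseA.g3;caseA.g4;caseA.g5")
  anc <- ancestry_statements(graph)
  expect_equal(nrow(anc), 1)
  expect_equal(anc$phenotypes, "CARDIAC;OXYNTOCARDIAC;SPECIALIZED")
  expect_equal(anc$supporting_variants, "MT-OHR:Cins")
})

test_that("a cardiac and a mature intestinal gland sharing m.10492T>C form one clone", {
  case <- example_case("cardiac_intestinal")
  graph <- call_clones(filter_variants(case$variants),
                       phenotypes = classify_glands(case$glands))
  anc <- ancestry_statements(graph)
  expect_equal(nrow(anc), 1)
  expect_equal(anc$phenotypes, "CARDIAC;MATURE_INTESTINAL")
  expect_equal(anc$supporting_variants, "m.10492T>C")
  expect_equal(anc$n_samples, 2L)
})

test_that("two retained MT-RNR2 variants mark a four-gland specialized/intestinal clone", {
  case <- example_case("spec_intestinal")
  kept <- filter_variants(case$variants)
  keys <- unique(kept$key[kept$var_class != "none"])
  expect_setequal(keys, c("m.2217T>C", "m.2283T>C"))
  graph <- call_clones(kept, phenotypes = classify_glands(case$glands))
  expect_equal(sort(graph$clones$n_samples, decreasing = TRUE),
               c(4L, 1L, 1L))
  big <- graph$clones[graph$clones$n_samples == 4, ]
  expect_equal(big$sample_ids, "caseC.g2;caseC.g3;caseC.g4;caseC.g5")
  anc <- ancestry_statements(graph)
  expect_equal(anc$phenotypes, "MATURE_INTESTINAL;SPECIALIZED")
  expect_equal(anc$supporting_variants, "m.2217T>C;m.2283T>C")
})

test_that("heteroplasmic variants are clonal marks only at high heteroplasmy", {
  v <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("g1", "g2"), tissue = "epithelial_gland",
                   patient_id = "p1", position = 500L, ref = "A", alt = "G",
                   var_class = "SNV", zygosity = "heteroplasmic",
                   het_level = c(0.9, 0.45), confirmed = TRUE,
                   region = NA_character_),
    tibble::tibble(sample_id = "p1.stroma", tissue = "stroma",
                   patient_id = "p1", position = NA_integer_,
                   ref = NA_character_, alt = NA_character_,
                   var_class = "none", zygosity = NA_character_,
                   het_level = NA_real_, confirmed = NA,
                   region = NA_character_)
  )
  kept <- filter_variants(v)
  # at the default threshold only g1's call qualifies: no edge
  expect_equal(nrow(call_clones(kept)$edges), 0)
  # lowering the threshold below 0.45 links the glands
  expect_equal(nrow(call_clones(kept, het_threshold = 0.4)$edges), 1)
})

test_that("clone partitions match brute-force transitive closure and are order-invariant", {
  for (seed in 1:6) {
    v <- random_variant_table(n_samples = sample(4:10, 1), n_keys = 6,
                              seed = seed)
    kept <- filter_variants(v)
    graph <- call_clones(kept)
    # oracle: explicit pairwise sharing relation, closed transitively
    real <- kept[kept$var_class != "none", ]
    ids <- sort(unique(kept$sample_id[kept$tissue != "stroma"]))
    pairs <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a < pairs$b, ]
    pairs$share <- mapply(function(a, b) {
      length(intersect(real$key[real$sample_id == a],
                       real$key[real$sample_id == b])) > 0
    }, pairs$a, pairs$b)
    comp <- brute_force_components(ids, pairs[pairs$share, c("a", "b")])
    oracle_partition <- lapply(unname(comp), sort)
    called_partition <- lapply(
      split(graph$nodes$sample_id, graph$nodes$clone_id), sort)
    expect_setequal(unname(called_partition), oracle_partition)
    # permuting input rows does not change the partition
    perm <- kept[sample(nrow(kept)), ]
    graph2 <- call_clones(perm)
    expect_equal(
      dplyr::arrange(graph$nodes, sample_id),
      dplyr::arrange(graph2$nodes, sample_id)
    )
  }
})

test_that("ancestry statements require phenotypes and skip single-phenotype clones", {
  case <- example_case("oxy_spec_cardiac")
  graph <- call_clones(filter_variants(case$variants))
  expect_error(ancestry_statements(graph), "phenotype")
  # all glands same phenotype -> no cross-phenotype statement
  same <- stats::setNames(rep("CARDIAC", 6), paste0("caseA.g", 1:6))
  expect_equal(nrow(ancestry_statements(graph, phenotypes = same)), 0)
})
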