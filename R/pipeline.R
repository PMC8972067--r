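#' Run the full gland-phenotype analysis pipeline
#'
#' Chains the analysis stages on a gland table and (optionally) a variant
#' table: marker-based phenotype classification, per-specimen and
#' per-patient diversity, nonparametric group comparisons, bootstrap
#' sampling sufficiency, somatic variant filtering, clone calling and
#' cross-phenotype ancestry statements. Record counts at every stage are
#' logged and reconcile: no gland or variant is silently dropped.
#'
#' @param glands Gland table (tibble) or path to a gland table TSV.
#' @param variants Optional variant table (tibble) or path; enables the
#'   clonal-inference stages.
#' @param polymorphisms Character vector of polymorphism keys, or path to a
#'   key list file.
#' @param per_patient Compare groups on per-patient mean Shannon diversity
#'   (default `TRUE`); otherwise on per-specimen values.
#' @param het_threshold Heteroplasmy threshold for clonal marks (see
#'   [call_clones()]).
#' @param require_confirmed Strict repeat-confirmation filtering (see
#'   [filter_variants()]).
#' @param bootstrap_sizes Integer vector of bootstrap resample sizes, or
#'   `NULL` to skip the sufficiency analysis.
#' @param n_reps Bootstrap replicates per size.
#' @param seed Integer seed; required when `bootstrap_sizes` is non-`NULL`
#'   (the only stochastic stage).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV together with `run_log.tsv` and a human-readable
#'   `summary.txt`.
#' @param pepsinogen_na Passed to [classify_glands()].
#' @return A list of class `be_pipeline` with elements `glands` (classified),
#'   `specimen_diversity`, `patient_diversity`, `phenotype_summary`,
#'   `phenotype_frequencies`, `group_comparisons` (pairwise Mann-Whitney plus
#'   a Kruskal-Wallis row when >2 groups), `bootstrap`, `filtered_variants`,
#'   `clone_graph`, `ancestry`, `informative_cases` and `log` (a tibble of
#'   stage/record counts).
#' @export
run_pipeline <- function(glands, variants = NULL, polymorphisms = character(),
                         per_patient = TRUE, het_threshold = 0.8,
                         require_confirmed = TRUE, bootstrap_sizes = NULL,
                         n_reps = 1000, seed = NULL, out_dir = NULL,
                         pepsinogen_na = c("UNCLASSIFIED", "OXYNTOCARDIAC")) {
  pepsinogen_na <- match.arg(pepsinogen_na)
  if (is.character(glands) && length(glands) == 1) {
    glands <- read_gland_table(glands)
  }
  if (!is.null(variants) && is.character(variants) && length(variants) == 1) {
    variants <- read_variant_table(variants)
  }
  if (is.character(polymorphisms) && length(polymorphisms) == 1 &&
      file.exists(polymorphisms)) {
    polymorphisms <- read_polymorphisms(polymorphisms)
  }
  if (!is.null(bootstrap_sizes) && is.null(seed)) {
    stop("bootstrap sufficiency is stochastic: a seed is required",
         call. = FALSE)
  }

  log_rows <- list()
  log_add <- function(stage, quantity, n) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      stage = stage, quantity = quantity, n = as.integer(n))
  }

  # --- classification ---
  log_add("classify", "glands_read", nrow(glands))
  glands <- classify_glands(glands, pepsinogen_na = pepsinogen_na)
  n_uncl <- sum(glands$phenotype == "UNCLASSIFIED")
  log_add("classify", "glands_classified", nrow(glands) - n_uncl)
  log_add("classify", "glands_unclassified", n_uncl)

  # --- diversity ---
  spec_div <- diversity_by_specimen(glands)
  log_add("diversity", "specimens_analysed", nrow(spec_div))
  pat_div <- mean_diversity_per_patient(spec_div)
  log_add("diversity", "patients_analysed", nrow(pat_div))
  pheno_summary <- phenotype_count_summary(spec_div$richness)
  pheno_freq <- glands |>
    dplyr::filter(.data$phenotype != "UNCLASSIFIED") |>
    dplyr::count(dplyr::across(dplyr::any_of("group")), .data$phenotype,
                 name = "n_glands") |>
    dplyr::group_by(dplyr::across(dplyr::any_of("group"))) |>
    dplyr::mutate(percentage = round(100 * .data$n_glands /
                                       sum(.data$n_glands), 2)) |>
    dplyr::ungroup()

  # --- group comparisons ---
  comparisons <- NULL
  unit <- if (per_patient) pat_div else spec_div
  value_col <- if (per_patient) "mean_shannon" else "shannon"
  if ("group" %in% names(unit) && dplyr::n_distinct(unit$group) >= 2) {
    groups <- split(unit[[value_col]], unit$group)
    pairs <- utils::combn(names(groups), 2)
    comparisons <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
      compare_groups(groups[[pairs[1, i]]], groups[[pairs[2, i]]],
                     group_a = pairs[1, i], group_b = pairs[2, i])
    }))
    if (length(groups) > 2) {
      kw <- kruskal_wallis(groups)
      comparisons <- dplyr::bind_rows(
        comparisons,
        tibble::tibble(group_a = "all", group_b = "all",
                       n_a = NA_integer_, n_b = NA_integer_,
                       statistic = kw$statistic, p_value = kw$p_value,
                       test_name = kw$test_name)
      )
    }
  }

  # --- bootstrap sufficiency ---
  boot <- NULL
  if (!is.null(bootstrap_sizes)) {
    pool <- glands$phenotype[glands$phenotype != "UNCLASSIFIED"]
    boot <- bootstrap_sufficiency(pool, bootstrap_sizes, n_reps = n_reps,
                                  seed = seed)
  }

  # --- clonal inference ---
  filtered <- NULL; graph <- NULL; ancestry <- NULL; informative <- NULL
  if (!is.null(variants)) {
    epi_ids <- unique(variants$sample_id[variants$tissue != "stroma"])
    unknown <- setdiff(epi_ids, glands$gland_id)
    if (length(unknown) > 0) {
      stop("validation error: epithelial variant sample(s) absent from the ",
           "gland table: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    n_real <- sum(!.is_placeholder(variants) & variants$tissue != "stroma")
    log_add("clones", "epithelial_variants_read", n_real)
    filtered <- filter_variants(variants, polymorphisms = polymorphisms,
                                require_confirmed = require_confirmed)
    n_kept <- sum(!.is_placeholder(filtered) & filtered$tissue != "stroma")
    log_add("clones", "variants_retained", n_kept)
    log_add("clones", "variants_removed", n_real - n_kept)
    informative <- case_informative(filtered, by_patient = TRUE)
    log_add("clones", "informative_cases", sum(informative$informative))
    graph <- call_clones(filtered, het_threshold = het_threshold,
                         phenotypes = glands)
    ancestry <- ancestry_statements(graph)
    log_add("clones", "clones_called", nrow(graph$clones))
    log_add("clones", "ancestry_statements", nrow(ancestry))
  }

  res <- structure(
    list(glands = glands, specimen_diversity = spec_div,
         patient_diversity = pat_div, phenotype_summary = pheno_summary,
         phenotype_frequencies = pheno_freq, group_comparisons = comparisons,
         bootstrap = boot, filtered_variants = filtered, clone_graph = graph,
         ancestry = ancestry, informative_cases = informative,
         log = dplyr::bind_rows(log_rows),
         params = list(per_patient = per_patient,
                       het_threshold = het_threshold,
                       require_confirmed = require_confirmed,
                       seed = seed)),
    class = "be_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write all pipeline result tables to a directory
#'
#' @param result A `be_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "be_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x)) readr::write_tsv(x, file.path(out_dir, name), na = "NA",
                                      progress = FALSE)
  }
  write_gland_table(result$glands, file.path(out_dir, "glands_classified.tsv"))
  w(result$specimen_diversity, "diversity_by_specimen.tsv")
  w(result$patient_diversity, "diversity_by_patient.tsv")
  w(result$phenotype_summary, "phenotypes_per_specimen.tsv")
  w(result$phenotype_frequencies, "phenotype_frequencies.tsv")
  w(result$group_comparisons, "group_comparisons.tsv")
  w(result$bootstrap, "bootstrap_sufficiency.tsv")
  w(result$filtered_variants, "variants_retained.tsv")
  if (!is.null(result$clone_graph)) {
    w(result$clone_graph$nodes, "clone_membership.tsv")
    w(result$clone_graph$clones, "clones.tsv")
  }
  w(result$ancestry, "ancestry_statements.tsv")
  w(result$informative_cases, "informative_cases.tsv")
  w(result$log, "run_log.tsv")
  writeLines(utils::capture.output(print(result)),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.be_pipeline <- function(x, ...) {
  cat("Barrett's gland phenotype analysis\n")
  cat("==================================\n")
  cat("R", as.character(getRversion()), "| begland",
      as.character(utils::packageVersion("begland")),
      "| seed:", if (is.null(x$params$seed)) "none" else x$params$seed, "\n\n")
  lg <- x$log
  for (i in seq_len(nrow(lg))) {
    cat(sprintf("  %-10s %-28s %d\n", lg$stage[i], lg$quantity[i], lg$n[i]))
  }
  cat("\nPhenotypes per specimen:\n")
  print(as.data.frame(x$phenotype_summary), row.names = FALSE)
  if (!is.null(x$group_comparisons)) {
    cat("\nGroup comparisons (",
        if (x$params$per_patient) "per-patient mean Shannon" else
          "per-specimen Shannon", "):\n", sep = "")
    print(as.data.frame(x$group_comparisons), row.names = FALSE)
  }
  if (!is.null(x$ancestry)) {
    cat("\nCross-phenotype ancestry statements:", nrow(x$ancestry), "\n")
    if (nrow(x$ancestry) > 0) {
      print(as.data.frame(x$ancestry), row.names = FALSE)
    }
  }
  invisible(x)
}
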