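#' Phenotype composition of one tissue specimen
#'
#' Tabulates gland phenotype labels into counts, excluding `"UNCLASSIFIED"`
#' glands by default: the five phenotypes define the species set over which
#' diversity is measured, so unclassifiable glands do not enter the
#' frequency denominators.
#'
#' @param phenotypes Character vector of per-gland phenotype labels.
#' @param exclude_unclassified Drop `"UNCLASSIFIED"` labels before counting
#'   (default `TRUE`).
#' @return Named integer vector of counts over the labels present.
#' @export
#' @examples
#' specimen_composition(c("CARDIAC", "CARDIAC", "SPECIALIZED"))
specimen_composition <- function(phenotypes, exclude_unclassified = TRUE) {
  phenotypes <- as.character(phenotypes)
  if (exclude_unclassified) {
    phenotypes <- phenotypes[phenotypes != "UNCLASSIFIED"]
  }
  if (length(phenotypes) == 0) {
    stop("empty composition: no classified glands to tabulate", call. = FALSE)
  }
  counts <- table(phenotypes)
  stats::setNames(as.integer(counts), names(counts))
}

## Accept either a label vector or a named count vector; return counts > 0.
.as_counts <- function(x) {
  if (is.character(x) || is.factor(x)) {
    counts <- specimen_composition(x)
  } else {
    counts <- x
    if (!is.null(names(counts))) counts <- counts[names(counts) != "UNCLASSIFIED"]
    if (any(counts < 0)) stop("negative phenotype counts", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) <= 0) {
    stop("empty composition: diversity requires at least one classified gland",
         call. = FALSE)
  }
  counts
}

#' Shannon diversity index of a phenotype composition
#'
#' Computes `H = -sum_i p_i * ln(p_i)` in nats, where `p_i` is the frequency
#' of phenotype `i` among the classified glands of a specimen, with the
#' convention `0 * ln(0) = 0` (zero-count classes contribute nothing).
#'
#' @param composition Either a character vector of per-gland phenotype labels
#'   or a named non-negative count vector (zero counts allowed;
#'   `"UNCLASSIFIED"` entries are excluded).
#' @return Non-negative numeric scalar; `0` when a single phenotype is
#'   present, at most `ln(richness)`.
#' @seealso [richness()]
#' @export
#' @examples
#' shannon_index(c(CARDIAC = 2, SPECIALIZED = 2))  # ln 2
#' shannon_index(c(CARDIAC = 5))                   # 0
shannon_index <- function(composition) {
  counts <- .as_counts(composition)
  p <- counts / sum(counts)
  -sum(p * log(p)) + 0  # + 0 normalises IEEE negative zero
}

#' Phenotypic richness of a composition
#'
#' The number of distinct gland phenotypes present (count > 0) in a specimen.
#'
#' @inheritParams shannon_index
#' @return Integer scalar in `1..5`.
#' @export
richness <- function(composition) {
  length(.as_counts(composition))
}

#' Per-specimen diversity table
#'
#' Computes richness and Shannon diversity for every specimen (biopsy or
#' resection) in a classified gland table.
#'
#' @param glands Data frame with columns `biopsy_id`, `patient_id`,
#'   `phenotype` and optionally `group`.
#' @param specimen_col Column identifying the specimen (default
#'   `"biopsy_id"`).
#' @return A tibble with one row per specimen: specimen id, `patient_id`,
#'   `group` (if present), `n_glands` (classified glands), `richness`,
#'   `shannon`. Specimens whose glands are all `UNCLASSIFIED` are dropped
#'   with a message.
#' @export
diversity_by_specimen <- function(glands, specimen_col = "biopsy_id") {
  stopifnot(specimen_col %in% names(glands), "phenotype" %in% names(glands))
  keep <- glands$phenotype != "UNCLASSIFIED"
  n_dropped_glands <- sum(!keep)
  classified <- glands[keep, , drop = FALSE]
  all_ids <- unique(glands[[specimen_col]])
  if (nrow(classified) == 0) {
    stop("no classified glands in any specimen", call. = FALSE)
  }
  lost <- setdiff(all_ids, unique(classified[[specimen_col]]))
  if (length(lost) > 0) {
    message(length(lost), " specimen(s) contained only UNCLASSIFIED glands ",
            "and were dropped from diversity analysis")
  }
  group_cols <- intersect(c("patient_id", "group"), names(classified))
  out <- classified |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(specimen_col, group_cols)))) |>
    dplyr::summarise(
      n_glands = dplyr::n(),
      richness = richness(.data$phenotype),
      shannon  = shannon_index(.data$phenotype),
      .groups = "drop"
    )
  attr(out, "n_unclassified_dropped") <- n_dropped_glands
  out
}

#' Distribution of phenotypes-per-specimen across a cohort
#'
#' For each richness value k observed, reports how many specimens show
#' exactly k phenotypes and what percentage of the cohort that is (rounded
#' to 2 decimals).
#'
#' @param richness_values Integer vector of per-specimen richness values
#'   (e.g. the `richness` column of [diversity_by_specimen()]).
#' @return A tibble with columns `n_phenotypes`, `n_specimens`, `percentage`.
#' @export
#' @examples
#' phenotype_count_summary(c(1, 2, 3))
phenotype_count_summary <- function(richness_values) {
  if (length(richness_values) == 0) {
    stop("empty cohort: no specimens to summarise", call. = FALSE)
  }
  tab <- table(factor(richness_values, levels = sort(unique(richness_values))))
  tibble::tibble(
    n_phenotypes = as.integer(names(tab)),
    n_specimens  = as.integer(tab),
    percentage   = round(100 * as.integer(tab) / length(richness_values), 2)
  )
}

#' Mean diversity per patient
#'
#' Aggregates per-specimen diversity to the patient level by arithmetic mean
#' of the Shannon index (and of richness), one row per patient.
#'
#' @param specimen_diversity A tibble from [diversity_by_specimen()]
#'   (requires columns `patient_id` and `shannon`).
#' @return A tibble with one row per patient: `patient_id`, `group` (if
#'   present and unique within patient), `n_specimens`, `mean_richness`,
#'   `mean_shannon`.
#' @export
mean_diversity_per_patient <- function(specimen_diversity) {
  stopifnot(all(c("patient_id", "shannon") %in% names(specimen_diversity)))
  if (anyNA(specimen_diversity$patient_id)) {
    stop("orphan specimen: every specimen must map to exactly one patient",
         call. = FALSE)
  }
  has_group <- "group" %in% names(specimen_diversity)
  if (has_group) {
    n_groups <- specimen_diversity |>
      dplyr::distinct(.data$patient_id, .data$group) |>
      dplyr::count(.data$patient_id)
    if (any(n_groups$n > 1)) {
      stop("patient(s) assigned to more than one group: ",
           paste(n_groups$patient_id[n_groups$n > 1], collapse = ", "),
           call. = FALSE)
    }
  }
  keys <- c("patient_id", if (has_group) "group")
  specimen_diversity |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_specimens   = dplyr::n(),
      mean_richness = mean(.data$richness),
      mean_shannon  = mean(.data$shannon),
      .groups = "drop"
    )
}
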