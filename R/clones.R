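## Somatic mtDNA variant filtering and clone calling.
##
## Microdissected gland samples are genotyped against the 16,569-bp rCRS
## mitochondrial reference. Variants shared between glands at homoplasmy (or
## high heteroplasmy) act as clonal marks: the probability of two glands
## acquiring the same variant independently is vanishingly small, so shared
## retained variants imply a common ancestral gland propagated by fission.

MT_GENOME_SIZE <- 16569L

#' Variant keys for clone matching
#'
#' Builds the identity key under which variants are matched across samples.
#' SNVs and deletions are keyed by position and alternate allele
#' (`m.<pos><ref>><alt>`). Insertions inside homopolymer tracts are keyed at
#' the region level (`<region>:<alt>`), because the exact position of an
#' insertion within e.g. the m.303-311 C-tract of the H-strand replication
#' origin is inherently ambiguous; a position-based key is used only when no
#' region tag is available.
#'
#' @param variants Data frame with columns `position`, `ref`, `alt`,
#'   `var_class` (`"SNV"`, `"insertion"`, `"deletion"`) and `region`.
#' @return Character vector of keys, one per row (`NA` for wild-type
#'   placeholder rows with missing `position`).
#' @export
variant_key <- function(variants) {
  pos_key <- sprintf("m.%d%s>%s", variants$position, variants$ref,
                     variants$alt)
  key <- ifelse(
    variants$var_class == "insertion" & !is.na(variants$region),
    paste0(variants$region, ":", variants$alt),
    pos_key
  )
  key[is.na(variants$position) & is.na(variants$alt)] <- NA_character_
  key
}

.variant_cols <- c("sample_id", "tissue", "patient_id", "position", "ref",
                   "alt", "var_class", "zygosity", "het_level", "confirmed",
                   "region")

## Split a variant table into real variant rows and wild-type placeholder
## rows (position NA), which only establish that a sample was sequenced.
.is_placeholder <- function(variants) {
  is.na(variants$position) & (is.na(variants$alt) | variants$var_class == "none")
}

.check_variant_table <- function(variants) {
  missing_cols <- setdiff(.variant_cols, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  real <- variants[!.is_placeholder(variants), , drop = FALSE]
  if (nrow(real) > 0) {
    bad_pos <- real$position < 1 | real$position > MT_GENOME_SIZE
    if (any(bad_pos, na.rm = TRUE)) {
      stop("variant position(s) outside 1..", MT_GENOME_SIZE, call. = FALSE)
    }
    same <- !is.na(real$ref) & !is.na(real$alt) & real$ref == real$alt
    if (any(same)) stop("ref and alt alleles must differ", call. = FALSE)
    hl <- real$het_level[real$zygosity == "heteroplasmic"]
    if (any(!is.na(hl) & (hl <= 0 | hl >= 1))) {
      stop("heteroplasmy levels must lie in (0, 1)", call. = FALSE)
    }
  }
  invisible(variants)
}

#' Filter somatic mtDNA variant calls
#'
#' Reduces a per-sample variant table to the somatic epithelial variants
#' usable as clonal marks, applying three filters within each case
#' (patient): (a) stroma subtraction - any variant also called in a stroma
#' sample of the same case is removed as germline or non-epithelial; (b)
#' known-polymorphism exclusion against a user-supplied key list; (c) in
#' strict mode (default), removal of calls not confirmed by repeat PCR
#' sequencing from the original DNA sample.
#'
#' Wild-type samples are represented by placeholder rows (`position = NA`,
#' `var_class = "none"`); these are preserved so that downstream clone
#' calling still sees every sequenced sample, and so that filtering is
#' idempotent.
#'
#' @param variants Variant table (see [read_variant_table()] for the
#'   dialect); stroma rows have `tissue == "stroma"`.
#' @param polymorphisms Character vector of variant keys (as from
#'   [variant_key()]) to exclude; may be empty.
#' @param subtract_stroma Apply stroma subtraction (default `TRUE`). Each
#'   case must then contain at least one stroma sample (a wild-type
#'   placeholder row suffices).
#' @param require_confirmed Drop unconfirmed calls (default `TRUE`).
#' @return The variant table restricted to retained epithelial variant rows
#'   plus one placeholder row per sequenced sample, with a `key` column
#'   added.
#' @export
filter_variants <- function(variants, polymorphisms = character(),
                            subtract_stroma = TRUE, require_confirmed = TRUE) {
  .check_variant_table(variants)
  variants$key <- variant_key(variants)
  placeholder <- .is_placeholder(variants)

  # one placeholder per sequenced sample, so sample presence survives
  registry <- variants[, intersect(names(variants),
                                   c(.variant_cols, "key"))]
  registry <- dplyr::distinct(
    dplyr::select(registry, "sample_id", "tissue", "patient_id")
  )
  placeholders <- registry
  placeholders$position <- NA_integer_
  placeholders$ref <- NA_character_
  placeholders$alt <- NA_character_
  placeholders$var_class <- "none"
  placeholders$zygosity <- NA_character_
  placeholders$het_level <- NA_real_
  placeholders$confirmed <- NA
  placeholders$region <- NA_character_
  placeholders$key <- NA_character_

  real <- variants[!placeholder, , drop = FALSE]

  if (subtract_stroma) {
    has_stroma <- tapply(registry$tissue == "stroma", registry$patient_id, any)
    if (!all(has_stroma)) {
      stop("stroma subtraction requires >= 1 stroma sample per case; ",
           "missing for: ",
           paste(names(has_stroma)[!has_stroma], collapse = ", "),
           call. = FALSE)
    }
  }

  retained <- dplyr::bind_rows(lapply(split(real, real$patient_id), function(case) {
    epi <- case[case$tissue != "stroma", , drop = FALSE]
    if (nrow(epi) == 0) return(epi)
    if (subtract_stroma) {
      stroma_keys <- unique(case$key[case$tissue == "stroma"])
      epi <- epi[!epi$key %in% stroma_keys, , drop = FALSE]
    }
    epi <- epi[!epi$key %in% polymorphisms, , drop = FALSE]
    if (require_confirmed) {
      epi <- epi[!is.na(epi$confirmed) & epi$confirmed, , drop = FALSE]
    }
    epi
  }))

  out <- dplyr::bind_rows(retained, placeholders)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Is a case informative for clonal analysis?
#'
#' After filtering, a case is informative when at least one retained somatic
#' variant remains in at least one epithelial sample; cases with no mtDNA
#' mutations, or whose only mutations were shared with stroma (hence
#' removed), carry no clonal marks.
#'
#' @param filtered Variant table returned by [filter_variants()].
#' @param by_patient If `TRUE`, return a tibble with one row per case.
#' @return Logical scalar (any case informative), or a tibble
#'   (`patient_id`, `informative`) when `by_patient = TRUE`.
#' @export
case_informative <- function(filtered, by_patient = FALSE) {
  real <- filtered[!.is_placeholder(filtered) &
                     filtered$tissue != "stroma", , drop = FALSE]
  if (!by_patient) return(nrow(real) > 0)
  patients <- unique(filtered$patient_id)
  tibble::tibble(
    patient_id = patients,
    informative = patients %in% unique(real$patient_id)
  )
}

## Does a variant call meet the clonal-mark zygosity criterion?
.is_clonal_mark <- function(zygosity, het_level, het_threshold) {
  zygosity == "homoplasmic" |
    (zygosity == "heteroplasmic" & !is.na(het_level) &
       het_level >= het_threshold)
}

#' Call clones from shared retained variants
#'
#' Builds a clone graph over the epithelial samples of each case: two
#' samples are connected when they share at least one retained variant with
#' an identical key, each call being homoplasmic or heteroplasmic at or
#' above `het_threshold` ("homoplasmic or highly heteroplasmic"). Clones are
#' the connected components; samples sharing no variant are singleton
#' clones. Samples from different cases are never connected.
#'
#' @param filtered Variant table returned by [filter_variants()].
#' @param het_threshold Minimum heteroplasmy level for a heteroplasmic call
#'   to count as a clonal mark (default 0.8; the choice is a convention, not
#'   a measured quantity).
#' @param phenotypes Optional mapping of epithelial sample id to phenotype
#'   label: either a named character vector or a data frame with columns
#'   matching `sample_id`/`gland_id` and `phenotype`.
#' @return An object of class `clone_graph`: a list with `nodes` (tibble:
#'   `sample_id`, `patient_id`, `phenotype`, `clone_id`), `edges` (tibble:
#'   `sample_a`, `sample_b`, `patient_id`, `shared_keys` semicolon-joined),
#'   `clones` (tibble: `clone_id`, `patient_id`, `n_samples`, `sample_ids`,
#'   `n_phenotypes`), and `het_threshold`.
#' @export
call_clones <- function(filtered, het_threshold = 0.8, phenotypes = NULL) {
  placeholder <- .is_placeholder(filtered)
  if (!"key" %in% names(filtered)) filtered$key <- variant_key(filtered)
  epi_mask <- filtered$tissue != "stroma"
  nodes <- dplyr::distinct(
    tibble::tibble(sample_id = filtered$sample_id[epi_mask],
                   patient_id = filtered$patient_id[epi_mask])
  )
  if (nrow(nodes) == 0) {
    stop("no epithelial samples to call clones on", call. = FALSE)
  }

  marks <- filtered[!placeholder & epi_mask, , drop = FALSE]
  marks <- marks[.is_clonal_mark(marks$zygosity, marks$het_level,
                                 het_threshold), , drop = FALSE]

  # pairwise shared keys within each case
  edges <- tibble::tibble(sample_a = character(), sample_b = character(),
                          patient_id = character(), shared_keys = character())
  if (nrow(marks) > 0) {
    by_key <- dplyr::distinct(marks[, c("patient_id", "key", "sample_id")])
    pair_list <- lapply(split(by_key, list(by_key$patient_id, by_key$key),
                              drop = TRUE), function(grp) {
      ids <- sort(unique(grp$sample_id))
      if (length(ids) < 2) return(NULL)
      pairs <- utils::combn(ids, 2)
      tibble::tibble(sample_a = pairs[1, ], sample_b = pairs[2, ],
                     patient_id = grp$patient_id[1], key = grp$key[1])
    })
    pair_tbl <- dplyr::bind_rows(pair_list)
    if (nrow(pair_tbl) > 0) {
      edges <- pair_tbl |>
        dplyr::group_by(.data$sample_a, .data$sample_b, .data$patient_id) |>
        dplyr::summarise(
          shared_keys = paste(sort(unique(.data$key)), collapse = ";"),
          .groups = "drop"
        )
    }
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("sample_a", "sample_b")],
    directed = FALSE,
    vertices = data.frame(name = sort(nodes$sample_id))
  )
  comp <- igraph::components(g)
  membership <- comp$membership[nodes$sample_id]

  # stable clone ids: per patient, numbered by first sample id in the clone
  nodes$component <- as.integer(membership)
  clone_ids <- nodes |>
    dplyr::group_by(.data$patient_id, .data$component) |>
    dplyr::summarise(first_sample = min(.data$sample_id), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$first_sample) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(clone_id = paste0(.data$patient_id, ".clone",
                                    dplyr::row_number())) |>
    dplyr::ungroup()
  nodes <- dplyr::left_join(nodes,
                            clone_ids[, c("patient_id", "component", "clone_id")],
                            by = c("patient_id", "component"))
  nodes$component <- NULL

  nodes <- .attach_phenotypes(nodes, phenotypes)

  clones <- nodes |>
    dplyr::group_by(.data$clone_id, .data$patient_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      sample_ids = paste(sort(.data$sample_id), collapse = ";"),
      n_phenotypes = dplyr::n_distinct(.data$phenotype[!is.na(.data$phenotype)]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_id, .data$clone_id)

  structure(
    list(nodes = nodes, edges = edges, clones = clones,
         het_threshold = het_threshold),
    class = "clone_graph"
  )
}

.attach_phenotypes <- function(nodes, phenotypes) {
  if (is.null(phenotypes)) {
    nodes$phenotype <- NA_character_
    return(nodes)
  }
  if (is.data.frame(phenotypes)) {
    id_col <- intersect(c("sample_id", "gland_id"), names(phenotypes))[1]
    if (is.na(id_col) || !"phenotype" %in% names(phenotypes)) {
      stop("phenotype mapping needs a sample_id/gland_id and a phenotype column",
           call. = FALSE)
    }
    map <- stats::setNames(as.character(phenotypes$phenotype),
                           phenotypes[[id_col]])
  } else {
    map <- phenotypes
  }
  nodes$phenotype <- unname(map[nodes$sample_id])
  nodes
}

#' @export
print.clone_graph <- function(x, ...) {
  cat("Clone graph over", nrow(x$nodes), "epithelial sample(s):",
      nrow(x$clones), "clone(s),", nrow(x$edges),
      "shared-variant edge(s); het threshold", x$het_threshold, "\n")
  multi <- x$clones[x$clones$n_samples > 1, , drop = FALSE]
  if (nrow(multi) > 0) {
    cat("Multi-sample clones:\n")
    for (i in seq_len(nrow(multi))) {
      cat("  ", multi$clone_id[i], ": ", multi$sample_ids[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Cross-phenotype ancestry statements
#'
#' A clone whose member glands span two or more distinct phenotypes is
#' direct evidence that phenotypically different glands share a common
#' ancestor (the marking mutation arose once in an ancestral gland and was
#' passed to daughters by gland fission). One statement is emitted per such
#' clone, listing the phenotype set and the supporting shared variants.
#'
#' @param graph A `clone_graph` from [call_clones()].
#' @param phenotypes Optional phenotype mapping (as in [call_clones()]);
#'   required unless phenotypes were attached when the graph was built.
#' @return A tibble with one row per multi-phenotype clone: `clone_id`,
#'   `patient_id`, `n_samples`, `phenotypes` (semicolon-joined sorted label
#'   set), `supporting_variants` (semicolon-joined keys).
#' @export
ancestry_statements <- function(graph, phenotypes = NULL) {
  stopifnot(inherits(graph, "clone_graph"))
  nodes <- graph$nodes
  if (!is.null(phenotypes)) {
    nodes <- .attach_phenotypes(nodes[, setdiff(names(nodes), "phenotype")],
                                phenotypes)
  }
  if (anyNA(nodes$phenotype)) {
    stop("every epithelial sample needs a phenotype label for ancestry ",
         "statements; missing for: ",
         paste(nodes$sample_id[is.na(nodes$phenotype)], collapse = ", "),
         call. = FALSE)
  }
  edge_clone <- graph$edges
  if (nrow(edge_clone) > 0) {
    edge_clone$clone_id <- nodes$clone_id[match(edge_clone$sample_a,
                                                nodes$sample_id)]
  }
  out <- nodes |>
    dplyr::group_by(.data$clone_id, .data$patient_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      phenotypes = paste(sort(unique(.data$phenotype)), collapse = ";"),
      n_phenotypes = dplyr::n_distinct(.data$phenotype),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_phenotypes >= 2)
  support <- vapply(out$clone_id, function(cl) {
    keys <- edge_clone$shared_keys[edge_clone$clone_id == cl]
    paste(sort(unique(unlist(strsplit(keys, ";", fixed = TRUE)))),
          collapse = ";")
  }, character(1))
  out$supporting_variants <- unname(support)
  out$n_phenotypes <- NULL
  dplyr::arrange(out, .data$patient_id, .data$clone_id)
}
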