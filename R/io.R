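## Table readers/writers. All tables are UTF-8, tab-separated, "." decimal
## separator and "NA" for missing values; marker columns in gland tables are
## serialized with a "marker:" prefix and states pos/low/neg/na.

#' Read / write a gland table
#'
#' The on-disk gland table dialect has columns `gland_id`, `biopsy_id`,
#' `patient_id`, `group`, then one `marker:<name>` column per lineage
#' marker (states `pos`/`low`/`neg`/`na`), and optionally `phenotype`.
#' In memory the marker columns are unprefixed.
#'
#' @param path File path.
#' @return A tibble with one row per gland.
#' @export
read_gland_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  names(tbl) <- sub("^marker:", "", names(tbl))
  required <- c("gland_id", "biopsy_id", "patient_id", be_markers())
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("malformed gland table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (m in be_markers()) {
    tbl[[m]] <- as.character(tbl[[m]])
    tbl[[m]][is.na(tbl[[m]])] <- "na"
    bad <- which(!tbl[[m]] %in% be_states())
    if (length(bad) > 0) {
      stop("malformed gland table ", path, ": invalid state '",
           tbl[[m]][bad[1]], "' in column marker:", m, ", line ",
           bad[1] + 1L, call. = FALSE)
    }
  }
  dup <- duplicated(tbl[, c("gland_id", "biopsy_id")])
  if (any(dup)) {
    stop("malformed gland table ", path, ": duplicate (gland_id, biopsy_id) ",
         "pair at line ", which(dup)[1] + 1L, call. = FALSE)
  }
  tbl
}

#' @rdname read_gland_table
#' @param glands In-memory gland table.
#' @export
write_gland_table <- function(glands, path) {
  out <- glands
  idx <- match(be_markers(), names(out))
  names(out)[idx[!is.na(idx)]] <- paste0("marker:", be_markers()[!is.na(idx)])
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a variant table
#'
#' Columns: `sample_id`, `tissue` (`epithelial_gland`/`stroma`),
#' `patient_id`, `position` (1-based on the rCRS), `ref`, `alt`,
#' `var_class` (`SNV`/`insertion`/`deletion`, or `none` for a wild-type
#' placeholder row), `zygosity` (`homoplasmic`/`heteroplasmic`),
#' `het_level`, `confirmed`, `region`. A sequenced sample with no variants
#' is recorded as a single `var_class = "none"` placeholder row.
#'
#' @param path File path.
#' @return A tibble with one row per variant call (or placeholder).
#' @export
read_variant_table <- function(path) {
  tbl <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE, na = "NA",
    col_types = readr::cols(
      position = readr::col_integer(),
      het_level = readr::col_double(),
      confirmed = readr::col_logical(),
      .default = readr::col_character()
    )
  )
  missing_cols <- setdiff(.variant_cols, names(tbl))
  if (length(missing_cols) > 0) {
    stop("malformed variant table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .check_variant_table(tbl)
  tbl
}

#' @rdname read_variant_table
#' @param variants In-memory variant table.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a polymorphism key list
#'
#' One variant key (see [variant_key()]) per line; blank lines and lines
#' starting with `#` are ignored. Stands in for a known-polymorphism
#' database lookup.
#'
#' @param path File path.
#' @return Character vector of keys (possibly empty).
#' @export
read_polymorphisms <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Worked example cases from microdissection genotyping
#'
#' Ships three small encoded cases of per-gland marker profiles and mtDNA
#' genotype calls from laser-capture microdissection sequencing, each
#' demonstrating cross-phenotype clonal ancestry:
#'
#' * `"oxy_spec_cardiac"`: six glands plus stroma; five glands spanning
#'   oxyntocardiac, specialized and cardiac phenotypes share a complex
#'   C-insertion in the m.303-311 tract of the H-strand replication origin
#'   (MT-OHR); a sixth cardiac gland and the stroma are wild type.
#' * `"cardiac_intestinal"`: a cardiac-type gland and a neighbouring mature
#'   intestinal gland share a homoplasmic m.10492T>C mutation (MT-ND4L)
#'   absent elsewhere in the biopsy.
#' * `"spec_intestinal"`: six glands plus stroma; two mature intestinal and
#'   two specialized glands share both m.2217T>C and m.2283T>C (MT-RNR2);
#'   one gland of each phenotype and the stroma are wild type.
#'
#' @param case One of `"oxy_spec_cardiac"`, `"cardiac_intestinal"`,
#'   `"spec_intestinal"`.
#' @return A list with elements `glands` (gland table) and `variants`
#'   (variant table).
#' @export
#' @examples
#' case <- example_case("oxy_spec_cardiac")
#' call_clones(filter_variants(case$variants))
example_case <- function(case = c("oxy_spec_cardiac", "cardiac_intestinal",
                                  "spec_intestinal")) {
  case <- match.arg(case)
  dir <- system.file("extdata", package = "begland", mustWork = TRUE)
  list(
    glands = read_gland_table(file.path(dir, paste0(case, "_glands.tsv"))),
    variants = read_variant_table(file.path(dir, paste0(case, "_variants.tsv")))
  )
}

#' The sequenced two-phenotype case series
#'
#' Reconstructs, as a variant table, the series of 10 microdissection-
#' sequenced cases in which at least two gland phenotypes were present:
#' 6 cases without any mtDNA mutation, 1 case whose only mutation was also
#' carried by nonepithelial (stromal) cells, and the 3 informative cases of
#' [example_case()]. Running [filter_variants()] then
#' [case_informative()] on this table recovers the 3 informative cases.
#'
#' @return A variant table covering all 10 cases.
#' @export
sequenced_case_series <- function() {
  quiet <- lapply(sprintf("quiet%02d", 1:6), function(pid) {
    dplyr::bind_rows(
      .wildtype_row(paste0(pid, ".g1"), "epithelial_gland", pid),
      .wildtype_row(paste0(pid, ".g2"), "epithelial_gland", pid),
      .wildtype_row(paste0(pid, ".stroma"), "stroma", pid)
    )
  })
  # one case with a single mutation shared by nonepithelial cells
  shared <- tibble::tibble(
    sample_id = c("stromal1.g1", "stromal1.stroma"),
    tissue = c("epithelial_gland", "stroma"),
    patient_id = "stromal1",
    position = 16189L, ref = "T", alt = "C", var_class = "SNV",
    zygosity = "homoplasmic", het_level = NA_real_, confirmed = TRUE,
    region = NA_character_
  )
  shared <- dplyr::bind_rows(
    shared, .wildtype_row("stromal1.g2", "epithelial_gland", "stromal1")
  )
  informative <- lapply(c("oxy_spec_cardiac", "cardiac_intestinal",
                          "spec_intestinal"),
                        function(cs) example_case(cs)$variants)
  dplyr::bind_rows(c(quiet, list(shared), informative))
}
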