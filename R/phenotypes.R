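#' The five Barrett's esophagus gland phenotypes
#'
#' Gland phenotypes are defined by the differentiated cell lineages a gland
#' contains, read out through six lineage markers: H+/K+-ATPase (parietal
#' cells), pepsinogen (chief cells), MUC5AC (foveolar cells), MUC2 (goblet
#' cells) and the Paneth-cell defensins HD5 (frozen tissue) / HD6 (FFPE).
#' The classifier can additionally emit `"UNCLASSIFIED"` for profiles that
#' match no rule; that label is not a phenotype and is excluded here.
#'
#' @return Character vector of the five phenotype labels, in canonical order:
#'   atrophic corpus, oxyntocardiac, cardiac, specialized, mature intestinal.
#' @seealso [classify_gland()], [count_phenotype_classes()]
#' @export
#' @examples
#' be_phenotypes()
be_phenotypes <- function() {
  c("ATROPHIC_CORPUS", "OXYNTOCARDIAC", "CARDIAC", "SPECIALIZED",
    "MATURE_INTESTINAL")
}

#' Number of distinct gland phenotype classes the classifier can emit
#'
#' Counts the distinct non-`UNCLASSIFIED` labels reachable by
#' [classify_gland()].
#'
#' @return Integer scalar, `5L`.
#' @export
count_phenotype_classes <- function() {
  length(be_phenotypes())
}

## Marker names, in serialization order.
be_markers <- function() {
  c("hk_atpase", "pepsinogen", "muc5ac", "muc2", "hd5", "hd6")
}

## Expression states as serialized in gland tables.
be_states <- function() c("pos", "low", "neg", "na")

#' Construct a per-gland marker expression profile
#'
#' A profile records the expression state of each of the six lineage markers
#' in one gland. States are `"pos"` (positive), `"low"` (weak but detectable),
#' `"neg"` (negative) and `"na"` (not assayed; e.g. HD5 is only assayable on
#' frozen tissue and HD6 only on FFPE).
#'
#' @param hk_atpase,pepsinogen,muc5ac,muc2,hd5,hd6 Expression state of the
#'   marker, one of `"pos"`, `"low"`, `"neg"`, `"na"`.
#' @return Named character vector of length 6 with class `"marker_profile"`.
#' @export
#' @examples
#' marker_profile(muc5ac = "pos", muc2 = "pos")  # specialized-type profile
marker_profile <- function(hk_atpase = "na", pepsinogen = "na", muc5ac = "na",
                           muc2 = "na", hd5 = "na", hd6 = "na") {
  p <- c(hk_atpase = hk_atpase, pepsinogen = pepsinogen, muc5ac = muc5ac,
         muc2 = muc2, hd5 = hd5, hd6 = hd6)
  bad <- !p %in% be_states()
  if (any(bad)) {
    stop("invalid expression state(s) for ",
         paste(names(p)[bad], "=", p[bad], collapse = ", "),
         "; states must be one of ", paste(be_states(), collapse = "/"),
         call. = FALSE)
  }
  structure(p, class = "marker_profile")
}

## A marker is scored expressed when staining is positive or weakly positive.
.is_pos <- function(state) state %in% c("pos", "low")

## Collapse HD5 (frozen) and HD6 (FFPE) into one logical defensin channel:
## either marker expressed => "pos"; both unassayed => "na"; otherwise "neg".
.defensin_state <- function(p) {
  if (.is_pos(p[["hd5"]]) || .is_pos(p[["hd6"]])) return("pos")
  if (p[["hd5"]] == "na" && p[["hd6"]] == "na") return("na")
  "neg"
}

#' Classify one gland from its marker profile
#'
#' Assigns one of the five gland phenotypes from immunohistochemical marker
#' states, or `"UNCLASSIFIED"` when no rule matches. The rules mirror the
#' marker definitions of the phenotypes:
#'
#' * `ATROPHIC_CORPUS`: H+/K+-ATPase+ and pepsinogen+ (parietal and chief
#'   cells).
#' * `OXYNTOCARDIAC`: H+/K+-ATPase+ and pepsinogen- (parietal, no chief).
#' * `CARDIAC`: MUC5AC+ and MUC2- (foveolar/mucous only).
#' * `SPECIALIZED`: MUC5AC+ and MUC2+ (goblet cells with foveolar
#'   epithelium); `"low"` MUC5AC counts as positive.
#' * `MATURE_INTESTINAL`: MUC5AC-, MUC2+, with the defensin channel positive
#'   or unassayed (defensin positivity confirms the call; a gland can be
#'   called on mucins alone when neither defensin was assayable).
#'
#' Parietal-marker rules take precedence: a H+/K+-ATPase-positive gland is
#' never assigned a mucin phenotype. Two profile families are deliberately
#' unclassifiable: H+/K+-ATPase+ together with MUC2+ (a combination never
#' observed; flagged with a warning), and a mucin-positive profile whose
#' discriminating partner marker is unassayed. H+/K+-ATPase-positive glands
#' with pepsinogen unassayed default to `"UNCLASSIFIED"` (set
#' `pepsinogen_na` to `"OXYNTOCARDIAC"` to default the other way).
#'
#' @param profile A [marker_profile()] (or named character vector with the
#'   same six elements).
#' @param pepsinogen_na Label for H+/K+-ATPase-positive glands whose
#'   pepsinogen state is unassayed: `"UNCLASSIFIED"` (default) or
#'   `"OXYNTOCARDIAC"`.
#' @return A single phenotype label (see [be_phenotypes()]) or
#'   `"UNCLASSIFIED"`.
#' @export
#' @examples
#' classify_gland(marker_profile(hk_atpase = "pos", pepsinogen = "pos"))
#' classify_gland(marker_profile(muc5ac = "low", muc2 = "pos", hd5 = "neg"))
classify_gland <- function(profile,
                           pepsinogen_na = c("UNCLASSIFIED", "OXYNTOCARDIAC")) {
  pepsinogen_na <- match.arg(pepsinogen_na)
  p <- marker_profile(profile[["hk_atpase"]], profile[["pepsinogen"]],
                      profile[["muc5ac"]], profile[["muc2"]],
                      profile[["hd5"]], profile[["hd6"]])
  if (all(p == "na")) {
    stop("cannot classify a gland with all six markers unassayed",
         call. = FALSE)
  }

  # Parietal rules take precedence over mucin rules.
  if (.is_pos(p[["hk_atpase"]])) {
    if (.is_pos(p[["muc2"]])) {
      warning("conflicting profile: H+/K+-ATPase-positive and MUC2-positive; ",
              "returning UNCLASSIFIED", call. = FALSE)
      return("UNCLASSIFIED")
    }
    if (.is_pos(p[["pepsinogen"]])) return("ATROPHIC_CORPUS")
    if (p[["pepsinogen"]] == "neg") return("OXYNTOCARDIAC")
    return(pepsinogen_na)
  }

  if (.is_pos(p[["muc5ac"]])) {
    if (.is_pos(p[["muc2"]])) return("SPECIALIZED")
    if (p[["muc2"]] == "neg") return("CARDIAC")
    return("UNCLASSIFIED")  # MUC2 unassayed: cardiac vs specialized ambiguous
  }

  if (p[["muc5ac"]] == "neg" && .is_pos(p[["muc2"]])) {
    if (.defensin_state(p) %in% c("pos", "na")) return("MATURE_INTESTINAL")
    return("UNCLASSIFIED")  # explicitly defensin-negative MUC2+ gland
  }

  "UNCLASSIFIED"
}

#' Classify every gland in a gland table
#'
#' Applies [classify_gland()] row-wise to a gland table (as returned by
#' [read_gland_table()] or [simulate_cohort()]) and appends/overwrites a
#' `phenotype` column.
#'
#' @param glands A data frame with one row per gland and the six marker
#'   columns `hk_atpase`, `pepsinogen`, `muc5ac`, `muc2`, `hd5`, `hd6`.
#' @inheritParams classify_gland
#' @return `glands` with a `phenotype` character column added.
#' @export
classify_glands <- function(glands,
                            pepsinogen_na = c("UNCLASSIFIED", "OXYNTOCARDIAC")) {
  pepsinogen_na <- match.arg(pepsinogen_na)
  missing_cols <- setdiff(be_markers(), names(glands))
  if (length(missing_cols) > 0) {
    stop("gland table is missing marker column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  labs <- vapply(seq_len(nrow(glands)), function(i) {
    prof <- vapply(be_markers(), function(m) as.character(glands[[m]][i]),
                   character(1))
    classify_gland(prof, pepsinogen_na = pepsinogen_na)
  }, character(1))
  glands$phenotype <- labs
  glands
}
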