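## Nonparametric group comparisons and bootstrap sampling sufficiency.

#' Two-group Mann-Whitney U comparison
#'
#' Two-sided Mann-Whitney U test comparing two samples of a continuous
#' summary (typically per-patient mean Shannon diversity, or per-specimen
#' values). Uses the exact null distribution for small samples without ties
#' and the normal approximation with tie correction otherwise (the behaviour
#' of [stats::wilcox.test()]). Fully tied data (every value identical) is
#' reported as no evidence of a difference: `p = 1`.
#'
#' @param values_a,values_b Numeric vectors, both nonempty.
#' @param group_a,group_b Labels carried into the result.
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `statistic`
#'   (the U statistic for the first group), `p_value`, `test_name`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
compare_groups <- function(values_a, values_b, group_a = "a", group_b = "b") {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    # degenerate: every observation identical; U at its null mean, p = 1
    u <- length(values_a) * length(values_b) / 2
    p <- 1.0
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, alternative = "two.sided")
    )
    u <- unname(wt$statistic)
    p <- min(1, wt$p.value)
  }
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    n_a = length(values_a), n_b = length(values_b),
    statistic = u, p_value = p, test_name = "mann_whitney_u"
  )
}

#' Kruskal-Wallis comparison across several groups
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square reference distribution
#' ([stats::kruskal.test()]). With every observation identical across all
#' groups the H statistic degenerates; it is reported as `statistic = 0`,
#' `p = 1`.
#'
#' @param groups A list of two or more nonempty numeric vectors, optionally
#'   named.
#' @return A one-row tibble: `n_groups`, `statistic` (H), `df`, `p_value`,
#'   `test_name`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("kruskal_wallis requires at least 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0)) {
    stop("all groups must be nonempty", call. = FALSE)
  }
  pooled <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(pooled)) == 1) {
    h <- 0
    p <- 1.0
  } else {
    kt <- stats::kruskal.test(
      pooled, factor(rep(seq_along(groups), lengths(groups)))
    )
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  tibble::tibble(
    n_groups = length(groups), statistic = h, df = df,
    p_value = p, test_name = "kruskal_wallis"
  )
}

#' Association between phenotype presence and a continuous covariate
#'
#' Mann-Whitney U test of a covariate (e.g. maximum segment length of the
#' Barrett's lesion, in cm) split by presence/absence of a phenotype across
#' specimens or patients.
#'
#' @param presence Logical vector: does the unit carry the phenotype?
#' @param covariate Numeric vector, same length as `presence`.
#' @return A one-row tibble as from [compare_groups()], with groups
#'   `"present"` and `"absent"`.
#' @export
association_with_covariate <- function(presence, covariate) {
  if (length(presence) != length(covariate)) {
    stop("presence and covariate must have equal length", call. = FALSE)
  }
  presence <- as.logical(presence)
  if (!any(presence) || all(presence)) {
    stop("both presence classes must be represented", call. = FALSE)
  }
  compare_groups(covariate[presence], covariate[!presence],
                 group_a = "present", group_b = "absent")
}

#' Bootstrap sampling-sufficiency curve for the Shannon index
#'
#' Assesses whether the number of glands sampled per specimen is sufficient
#' to estimate phenotypic diversity: for each candidate sample size, glands
#' are resampled with replacement `n_reps` times from the supplied phenotype
#' pool, the Shannon index is computed on each resample, and the mean with a
#' percentile interval is reported. A curve that plateaus below the number
#' of glands actually sampled indicates that sampling more glands would not
#' have changed the diversity estimate.
#'
#' @param phenotypes Character vector of gland phenotype labels (the pool to
#'   resample from). `"UNCLASSIFIED"` labels are dropped first.
#' @param sample_sizes Integer vector of resample sizes (all >= 1).
#' @param n_reps Number of bootstrap replicates per size (default 1000).
#' @param seed Integer seed; required, so the curve is reproducible.
#' @param conf_level Width of the percentile interval (default 0.95).
#' @return A tibble with one row per sample size: `sample_size`,
#'   `mean_shannon`, `se_shannon` (Monte Carlo standard error of the mean),
#'   `ci_lower`, `ci_upper`, `n_reps`.
#' @export
#' @examples
#' pool <- rep(c("CARDIAC", "SPECIALIZED"), each = 50)
#' bootstrap_sufficiency(pool, sample_sizes = c(2, 8, 32), seed = 1)
bootstrap_sufficiency <- function(phenotypes, sample_sizes, n_reps = 1000,
                                  seed, conf_level = 0.95) {
  if (missing(seed) || is.null(seed)) {
    stop("bootstrap_sufficiency is stochastic: a seed is required",
         call. = FALSE)
  }
  phenotypes <- as.character(phenotypes)
  phenotypes <- phenotypes[phenotypes != "UNCLASSIFIED"]
  if (length(phenotypes) == 0) stop("empty gland pool", call. = FALSE)
  if (any(sample_sizes < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  alpha <- (1 - conf_level) / 2

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  rows <- lapply(sample_sizes, function(size) {
    h <- vapply(seq_len(n_reps), function(r) {
      shannon_index(sample(phenotypes, size, replace = TRUE))
    }, numeric(1))
    qs <- stats::quantile(h, c(alpha, 1 - alpha), names = FALSE)
    tibble::tibble(
      sample_size = as.integer(size),
      mean_shannon = mean(h),
      se_shannon = stats::sd(h) / sqrt(n_reps),
      ci_lower = qs[1], ci_upper = qs[2],
      n_reps = as.integer(n_reps)
    )
  })
  dplyr::bind_rows(rows)
}

## Save/restore the global RNG state so seeded helpers do not perturb the
## caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
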