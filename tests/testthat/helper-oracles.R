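# Independent oracles used to cross-check package computations. These are
# deliberately naive implementations (enumeration, direct formulas,
# brute-force closures) kept separate from the code paths they validate.

# Exact two-sided Mann-Whitney p-value by enumeration of all rank
# assignments (no ties assumed).
enumerate_mw_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  assignments <- utils::combn(n + m, n)
  u_null <- apply(assignments, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- n * m / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu))
}

# Kruskal-Wallis H and p by direct formula (tie-corrected).
direct_kw <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  list(statistic = h, p_value = stats::pchisq(h, length(groups) - 1,
                                              lower.tail = FALSE))
}

# Brute-force connected components by transitive closure over an explicit
# "shares a retained clonal-mark key" relation.
brute_force_components <- function(sample_ids, shares) {
  # shares: data.frame with columns a, b (symmetric relation, both samples)
  n <- length(sample_ids)
  adj <- matrix(FALSE, n, n, dimnames = list(sample_ids, sample_ids))
  diag(adj) <- TRUE
  if (nrow(shares) > 0) {
    for (i in seq_len(nrow(shares))) {
      adj[shares$a[i], shares$b[i]] <- TRUE
      adj[shares$b[i], shares$a[i]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  membership <- apply(adj, 1, function(row) min(which(row)))
  split(sample_ids, membership)
}

# Random small variant tables for property tests.
random_variant_table <- function(n_samples, n_keys, seed) {
  set.seed(seed)
  positions <- sample(100:16000, n_keys)
  rows <- list()
  for (s in seq_len(n_samples)) {
    sid <- sprintf("s%02d", s)
    carried <- which(stats::runif(n_keys) < 0.35)
    if (length(carried) == 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, tissue = "epithelial_gland", patient_id = "case1",
        position = NA_integer_, ref = NA_character_, alt = NA_character_,
        var_class = "none", zygosity = NA_character_, het_level = NA_real_,
        confirmed = NA, region = NA_character_)
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, tissue = "epithelial_gland", patient_id = "case1",
        position = positions[carried], ref = "A", alt = "G",
        var_class = "SNV", zygosity = "homoplasmic", het_level = NA_real_,
        confirmed = TRUE, region = NA_character_)
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    sample_id = "case1.stroma", tissue = "stroma", patient_id = "case1",
    position = NA_integer_, ref = NA_character_, alt = NA_character_,
    var_class = "none", zygosity = NA_character_, het_level = NA_real_,
    confirmed = NA, region = NA_character_)
  dplyr::bind_rows(rows)
}

# All 4^6 marker profiles.
all_profiles <- function() {
  states <- c("pos", "low", "neg", "na")
  expand.grid(hk_atpase = states, pepsinogen = states, muc5ac = states,
              muc2 = states, hd5 = states, hd6 = states,
              stringsAsFactors = FALSE)
}
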