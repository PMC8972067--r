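## Forward simulator of Barrett's gland populations.
##
## Each patient starts from a fixed-size population of founder glands.
## Glands clonally expand by gland fission under a Moran-style constant
## population size (each fission is balanced by the death of a random other
## gland, reflecting that the metaplastic segment changes little in size
## over time). Each fission deposits Poisson-distributed new homoplasmic
## mtDNA mutations on the daughter gland; mutations are neutral and never
## influence phenotype, fission or death. Phenotypes change by niche
## succession: per generation each gland switches phenotype with a small
## probability, drawing the destination from a transition matrix. Biopsies
## sample disjoint sets of glands from the final population, and one stroma
## sample per patient carries only designated germline polymorphisms, which
## are also present in every gland, to exercise the filtering path.

#' Default phenotype transition matrix
#'
#' Conditional distribution of the destination phenotype given that a
#' transition (niche succession) event occurs. The moves encode the
#' transitions for which clonal evidence exists, with the cardiac gland as
#' the fulcrum: cardiac glands move mostly toward specialized (and toward
#' oxyntocardiac along the gastric line), oxyntocardiac glands mature to
#' atrophic corpus or revert to cardiac, specialized glands intestinalize to
#' mature intestinal or revert, and the two end states step back toward
#' their neighbours.
#'
#' @return A 5x5 row-stochastic matrix with dimnames [be_phenotypes()].
#' @export
default_transition_matrix <- function() {
  ph <- be_phenotypes()
  m <- matrix(0, 5, 5, dimnames = list(ph, ph))
  m["CARDIAC", c("OXYNTOCARDIAC", "SPECIALIZED")] <- c(0.35, 0.65)
  m["OXYNTOCARDIAC", c("ATROPHIC_CORPUS", "CARDIAC")] <- c(0.5, 0.5)
  m["ATROPHIC_CORPUS", "OXYNTOCARDIAC"] <- 1
  m["SPECIALIZED", c("MATURE_INTESTINAL", "CARDIAC")] <- c(0.7, 0.3)
  m["MATURE_INTESTINAL", "SPECIALIZED"] <- 1
  m
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of one simulated patient group.
#'
#' @param n_patients Number of patients in the group.
#' @param glands_per_patient Constant gland population size per patient.
#' @param n_generations Number of fission/transition generations simulated.
#' @param fission_rate Per-gland, per-generation probability of fission.
#' @param mutation_rate Expected new mtDNA mutations per fission event
#'   (Poisson mean); mutations are homoplasmic at birth.
#' @param genome_size Mitochondrial genome length in bp (default 16,569,
#'   the rCRS); mutation positions are uniform on `1..genome_size`, so
#'   identical keys arising twice independently are possible but rare
#'   (no infinite-sites assumption).
#' @param transition_prob Per-gland, per-generation probability of a
#'   phenotype transition event.
#' @param transition_matrix 5x5 row-stochastic destination matrix given a
#'   transition event (default [default_transition_matrix()]).
#' @param founder_distribution Named probability vector over
#'   [be_phenotypes()] from which founder phenotypes are drawn (default:
#'   all cardiac, the fulcrum phenotype).
#' @param founder_per_patient If `TRUE`, one founder phenotype is drawn per
#'   patient and shared by all its founders (all glands of a patient start
#'   identical); if `FALSE`, each founder gland draws independently.
#' @param biopsy_size Glands sampled per biopsy (without replacement;
#'   biopsies of one patient are disjoint).
#' @param biopsies_per_patient Biopsies taken per patient.
#' @param n_polymorphisms Number of germline polymorphisms per patient,
#'   present in the stroma sample and in every gland.
#' @param heteroplasmic_fraction Fraction of new mutations that are
#'   heteroplasmic rather than homoplasmic (default 0: homoplasmic instant
#'   fixation, matching the clonal marks the analysis relies on). When
#'   positive, heteroplasmy levels are drawn uniformly on (0.05, 0.95).
#' @param group_label Group name written into the gland table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 19, glands_per_patient = 50,
                       n_generations = 10, fission_rate = 0.05,
                       mutation_rate = 2, genome_size = MT_GENOME_SIZE,
                       transition_prob = 0.02,
                       transition_matrix = default_transition_matrix(),
                       founder_distribution = c(CARDIAC = 1),
                       founder_per_patient = TRUE,
                       biopsy_size = 8, biopsies_per_patient = 5,
                       n_polymorphisms = 2, heteroplasmic_fraction = 0,
                       group_label = "nondysplastic") {
  cfg <- list(
    n_patients = as.integer(n_patients),
    glands_per_patient = as.integer(glands_per_patient),
    n_generations = as.integer(n_generations),
    fission_rate = fission_rate,
    mutation_rate = mutation_rate,
    genome_size = as.integer(genome_size),
    transition_prob = transition_prob,
    transition_matrix = transition_matrix,
    founder_distribution = founder_distribution,
    founder_per_patient = isTRUE(founder_per_patient),
    biopsy_size = as.integer(biopsy_size),
    biopsies_per_patient = as.integer(biopsies_per_patient),
    n_polymorphisms = as.integer(n_polymorphisms),
    heteroplasmic_fraction = heteroplasmic_fraction,
    group_label = group_label
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param config A `sim_config` candidate list.
#' @export
validate_sim_config <- function(config) {
  ph <- be_phenotypes()
  with(config, {
    stopifnot(
      n_patients >= 1, glands_per_patient >= 1, n_generations >= 0,
      genome_size >= 1, mutation_rate >= 0,
      biopsy_size >= 1, biopsies_per_patient >= 1, n_polymorphisms >= 0
    )
    probs <- c(fission_rate, transition_prob, heteroplasmic_fraction)
    if (any(probs < 0 | probs > 1)) {
      stop("rates/probabilities must lie in [0, 1]", call. = FALSE)
    }
    tm <- transition_matrix
    if (!is.matrix(tm) || !identical(dim(tm), c(5L, 5L)) ||
        !identical(rownames(tm), ph) || !identical(colnames(tm), ph)) {
      stop("transition_matrix must be 5x5 with phenotype dimnames in ",
           "canonical order", call. = FALSE)
    }
    if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9)) {
      stop("transition_matrix rows must be nonnegative and sum to 1 (1e-9)",
           call. = FALSE)
    }
    fd <- founder_distribution
    if (is.null(names(fd)) || !all(names(fd) %in% ph) || any(fd < 0) ||
        sum(fd) <= 0) {
      stop("founder_distribution must be a nonnegative named vector over ",
           "the phenotype labels", call. = FALSE)
    }
  })
  invisible(config)
}

## Deterministic pseudo-reference base for a position, so that two mutation
## events at the same position always report the same ref allele and key
## matching reduces to (position, alt).
.ref_base <- function(position) {
  c("A", "C", "G", "T")[(position %% 4L) + 1L]
}

## The three possible alternate alleles for each reference base; new_events
## draws an index 1..3, resolved here.
.ALT_TABLE <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

.alt_base <- function(ref, i) {
  .ALT_TABLE[cbind(match(ref, c("A", "C", "G", "T")), i)]
}

#' Simulate a cohort of patients under gland fission
#'
#' Runs the forward model (see the package's methods vignette) for every
#' patient of a group and emits the tables consumed by the analysis modules
#' plus the full ground truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; required (the simulator is stochastic and must
#'   be reproducible).
#' @return A list of class `sim_cohort`:
#' \describe{
#'   \item{glands}{Gland table for all biopsied glands (columns `gland_id`,
#'     `biopsy_id`, `patient_id`, `group`, six marker columns, and the true
#'     `phenotype`). Marker states are the canonical profile of the
#'     phenotype, so [classify_glands()] recovers the truth.}
#'   \item{variants}{Variant table for biopsied glands and one stroma
#'     sample per patient (germline polymorphisms appear in every sample of
#'     a patient; wild-type samples carry a placeholder row).}
#'   \item{genealogy}{One row per gland ever created: `patient_id`,
#'     `gland_id`, `parent_id` (`NA` for founders), `generation`,
#'     `phenotype_at_birth`, `phenotype_final`, `alive`, `sampled`,
#'     `biopsy_id`.}
#'   \item{mutations}{Long table of true somatic mutation carriage:
#'     `patient_id`, `gland_id`, `event_id` (unique per mutation event,
#'     distinguishing true identity from key collisions), `key`,
#'     `position`, `ref`, `alt`.}
#'   \item{truth_clones}{For biopsied glands: `gland_id`, `patient_id`,
#'     `true_clone` - connected components of the "shares >= 1 mutation
#'     event" relation.}
#'   \item{polymorphisms}{Character vector of the germline polymorphism
#'     keys used, suitable for the polymorphism-list filter.}
#' }
#' @export
simulate_cohort <- function(config, seed) {
  validate_sim_config(config)
  if (missing(seed) || is.null(seed)) {
    stop("simulate_cohort is stochastic: a seed is required", call. = FALSE)
  }
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  ph <- be_phenotypes()
  fd <- config$founder_distribution[config$founder_distribution > 0]
  n_sampled <- config$biopsy_size * config$biopsies_per_patient
  if (n_sampled > config$glands_per_patient) {
    stop("biopsy_size * biopsies_per_patient exceeds the gland population ",
         "(", n_sampled, " > ", config$glands_per_patient, ")", call. = FALSE)
  }

  event_counter <- 0L
  glands_out <- list(); variants_out <- list(); genealogy_out <- list()
  mutations_out <- list(); truth_clones_out <- list(); poly_keys <- character()

  for (pi in seq_len(config$n_patients)) {
    pid <- sprintf("%s.p%02d", config$group_label, pi)
    n <- config$glands_per_patient

    # founders
    if (config$founder_per_patient) {
      founder_ph <- rep(sample(names(fd), 1, prob = fd), n)
    } else {
      founder_ph <- sample(names(fd), n, replace = TRUE, prob = fd)
    }
    next_gid <- n + 1L
    pop <- seq_len(n)                       # indices into per-gland records
    gid <- sprintf("%s.g%04d", pid, seq_len(n))
    parent <- rep(NA_character_, n)
    born <- rep(0L, n)
    ph_birth <- founder_ph
    ph_now <- founder_ph
    mut_sets <- rep(list(integer()), n)     # event ids per gland
    alive <- rep(TRUE, n)

    # per-patient event registry, appended per fission, flattened at the end
    ev_id_l <- list(); ev_pos_l <- list(); ev_alt_l <- list()
    ev_het_l <- list(); ev_lev_l <- list()

    new_events <- function(k) {
      if (k == 0) return(integer())
      ids <- event_counter + seq_len(k)
      event_counter <<- event_counter + k
      pos <- sample.int(config$genome_size, k, replace = TRUE)
      alt_i <- sample.int(3L, k, replace = TRUE)  # which of the non-ref bases
      het <- stats::runif(k) < config$heteroplasmic_fraction
      lev <- ifelse(het, stats::runif(k, 0.05, 0.95), NA_real_)
      i <- length(ev_id_l) + 1L
      ev_id_l[[i]] <<- ids; ev_pos_l[[i]] <<- pos; ev_alt_l[[i]] <<- alt_i
      ev_het_l[[i]] <<- het; ev_lev_l[[i]] <<- lev
      ids
    }

    for (gen in seq_len(config$n_generations)) {
      # fission with Moran-style death balancing
      live_idx <- which(alive)
      fissioners <- live_idx[stats::runif(length(live_idx)) < config$fission_rate]
      for (f in fissioners) {
        if (!alive[f]) next  # parent already displaced this generation
        d <- length(gid) + 1L
        gid[d] <- sprintf("%s.g%04d", pid, next_gid); next_gid <- next_gid + 1L
        parent[d] <- gid[f]
        born[d] <- gen
        ph_birth[d] <- ph_now[f]
        ph_now[d] <- ph_now[f]
        mut_sets[[d]] <- c(mut_sets[[f]],
                           new_events(stats::rpois(1, config$mutation_rate)))
        alive[d] <- TRUE
        # one random death among glands other than parent and daughter
        candidates <- setdiff(which(alive), c(f, d))
        if (length(candidates) > 0) {
          victim <- candidates[sample.int(length(candidates), 1)]
          alive[victim] <- FALSE
        }
      }
      # phenotype transitions (niche succession)
      live <- which(alive)
      trans <- live[stats::runif(length(live)) < config$transition_prob]
      if (length(trans) > 0) {
        from <- ph_now[trans]
        for (ph_from in unique(from)) {
          idx <- trans[from == ph_from]
          ph_now[idx] <- sample(ph, length(idx), replace = TRUE,
                                prob = config$transition_matrix[ph_from, ])
        }
      }
    }

    # biopsy sampling: disjoint glands across biopsies of a patient
    live_idx <- which(alive)
    picked <- live_idx[sample.int(length(live_idx), n_sampled)]
    biopsy_of <- rep(sprintf("%s.b%d", pid, seq_len(config$biopsies_per_patient)),
                     each = config$biopsy_size)

    # germline polymorphisms for this patient
    if (config$n_polymorphisms > 0) {
      ppos <- sample.int(config$genome_size, config$n_polymorphisms)
      pref <- .ref_base(ppos)
      palt <- vapply(pref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                     character(1))
      pkey <- sprintf("m.%d%s>%s", ppos, pref, palt)
    } else {
      ppos <- integer(); pref <- character(); palt <- character()
      pkey <- character()
    }
    poly_keys <- c(poly_keys, pkey)

    glands_out[[pid]] <- tibble::tibble(
      gland_id = gid[picked],
      biopsy_id = biopsy_of,
      patient_id = pid,
      group = config$group_label,
      phenotype = ph_now[picked]
    )

    # flatten this patient's event registry
    eid <- as.integer(unlist(ev_id_l))
    epos <- as.integer(unlist(ev_pos_l))
    eref <- .ref_base(epos)
    ealt <- .alt_base(eref, as.integer(unlist(ev_alt_l)))
    ehet <- as.logical(unlist(ev_het_l))
    elev <- as.numeric(unlist(ev_lev_l))
    ekey <- sprintf("m.%d%s>%s", epos, eref, ealt)

    # variant rows: somatic events per sampled gland, plus germline
    # polymorphisms in every sample (incl. stroma); wild-type samples get
    # a placeholder row
    stroma_id <- paste0(pid, ".stroma")
    s_ev <- match(unlist(mut_sets[picked]), eid)
    somatic <- tibble::tibble(
      sample_id = rep(gid[picked], lengths(mut_sets[picked])),
      tissue = "epithelial_gland", patient_id = pid,
      position = epos[s_ev], ref = eref[s_ev], alt = ealt[s_ev],
      var_class = "SNV",
      zygosity = as.character(ifelse(ehet[s_ev], "heteroplasmic",
                                     "homoplasmic")),
      het_level = elev[s_ev], confirmed = TRUE, region = NA_character_
    )
    all_sample_ids <- c(gid[picked], stroma_id)
    all_tissues <- c(rep("epithelial_gland", length(picked)), "stroma")
    if (length(ppos) > 0) {
      poly_tbl <- tibble::tibble(
        sample_id = rep(all_sample_ids, each = length(ppos)),
        tissue = rep(all_tissues, each = length(ppos)),
        patient_id = pid,
        position = rep(as.integer(ppos), length(all_sample_ids)),
        ref = rep(pref, length(all_sample_ids)),
        alt = rep(palt, length(all_sample_ids)),
        var_class = "SNV", zygosity = "homoplasmic", het_level = NA_real_,
        confirmed = TRUE, region = NA_character_
      )
    } else {
      poly_tbl <- NULL
    }
    covered <- unique(c(somatic$sample_id, poly_tbl$sample_id))
    bare <- setdiff(all_sample_ids, covered)
    placeholders <- if (length(bare) > 0) {
      .wildtype_row(bare, all_tissues[match(bare, all_sample_ids)], pid)
    } else {
      NULL
    }
    variants_out[[pid]] <- dplyr::bind_rows(somatic, poly_tbl, placeholders)

    genealogy_out[[pid]] <- tibble::tibble(
      patient_id = pid, gland_id = gid, parent_id = parent,
      generation = born, phenotype_at_birth = ph_birth,
      phenotype_final = ph_now, alive = alive,
      sampled = seq_along(gid) %in% picked,
      biopsy_id = NA_character_
    )
    genealogy_out[[pid]]$biopsy_id[picked] <- biopsy_of

    m_ev <- unlist(mut_sets)
    m_idx <- match(m_ev, eid)
    mutations_out[[pid]] <- tibble::tibble(
      patient_id = pid, gland_id = rep(gid, lengths(mut_sets)),
      event_id = as.integer(m_ev), key = ekey[m_idx],
      position = epos[m_idx], ref = eref[m_idx], alt = ealt[m_idx]
    )

    truth_clones_out[[pid]] <- .true_clones(pid, gid[picked], mut_sets[picked])
  }

  structure(
    list(
      glands = .profiles_from_phenotypes(dplyr::bind_rows(glands_out)),
      variants = dplyr::bind_rows(variants_out),
      genealogy = dplyr::bind_rows(genealogy_out),
      mutations = dplyr::bind_rows(mutations_out),
      truth_clones = dplyr::bind_rows(truth_clones_out),
      polymorphisms = poly_keys,
      config = config,
      seed = as.integer(seed)
    ),
    class = "sim_cohort"
  )
}

.wildtype_row <- function(sample_id, tissue, patient_id) {
  tibble::tibble(
    sample_id = sample_id, tissue = tissue, patient_id = patient_id,
    position = NA_integer_, ref = NA_character_, alt = NA_character_,
    var_class = "none", zygosity = NA_character_, het_level = NA_real_,
    confirmed = NA, region = NA_character_
  )
}

## True co-clonality over shared mutation *events* (not keys): connected
## components of the sharing relation among sampled glands.
.true_clones <- function(pid, gids, mut_sets) {
  n <- length(gids)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (a in seq_len(n)) {
    for (b in seq_len(n)[-seq_len(a)]) {
      if (length(intersect(mut_sets[[a]], mut_sets[[b]])) > 0) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) comp[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tibble::tibble(
    gland_id = gids, patient_id = pid,
    true_clone = paste0(pid, ".true", match(roots, unique(roots)))
  )
}

## Canonical marker profile of each phenotype, so the classifier recovers
## the simulated truth. HD5 is left unassayed (FFPE-style cohort).
.canonical_profiles <- function() {
  tibble::tribble(
    ~phenotype,          ~hk_atpase, ~pepsinogen, ~muc5ac, ~muc2, ~hd5, ~hd6,
    "ATROPHIC_CORPUS",   "pos",      "pos",       "neg",   "neg", "na", "neg",
    "OXYNTOCARDIAC",     "pos",      "neg",       "pos",   "neg", "na", "neg",
    "CARDIAC",           "neg",      "neg",       "pos",   "neg", "na", "neg",
    "SPECIALIZED",       "neg",      "neg",       "pos",   "pos", "na", "neg",
    "MATURE_INTESTINAL", "neg",      "neg",       "neg",   "pos", "na", "pos"
  )
}

.profiles_from_phenotypes <- function(glands) {
  out <- dplyr::left_join(glands, .canonical_profiles(), by = "phenotype")
  cols <- c("gland_id", "biopsy_id", "patient_id", "group", be_markers(),
            "phenotype")
  out[, cols]
}

#' Scenario presets for the four study groups
#'
#' Returns one [sim_config()] per study group, calibrated only to reproduce
#' the qualitative group ordering of phenotypic diversity (no numeric
#' fission or transition rates are available to calibrate against):
#'
#' * `nondysplastic` - Barrett's with no history of dysplasia: 19 patients,
#'   5 biopsies each, low transition probability calibrated so that most
#'   biopsies show one phenotype, two is common and three is rare.
#' * `predysplasia` - biopsies taken before a later dysplasia diagnosis: 12
#'   patients, 4 biopsies each, elevated transition probability.
#' * `adjacent_dysplasia` - nondysplastic epithelium adjacent to dysplasia:
#'   18 patients, 2 specimens each, elevated transition probability.
#' * `neo_be` - post-esophagectomy Barrett's: 19 patients, 2 biopsies each,
#'   no transitions, founder phenotype drawn per patient (cardiac-dominant),
#'   so every biopsy contains exactly one phenotype.
#'
#' @return Named list of `sim_config` objects.
#' @export
scenario_presets <- function() {
  list(
    nondysplastic = sim_config(
      n_patients = 19, biopsies_per_patient = 5, transition_prob = 0.005,
      group_label = "nondysplastic"
    ),
    predysplasia = sim_config(
      n_patients = 12, biopsies_per_patient = 4, transition_prob = 0.08,
      group_label = "predysplasia"
    ),
    adjacent_dysplasia = sim_config(
      n_patients = 18, biopsies_per_patient = 2, transition_prob = 0.08,
      group_label = "adjacent_dysplasia"
    ),
    neo_be = sim_config(
      n_patients = 19, biopsies_per_patient = 2, transition_prob = 0,
      founder_distribution = c(CARDIAC = 0.7, SPECIALIZED = 0.15,
                               ATROPHIC_CORPUS = 0.15),
      founder_per_patient = TRUE,
      group_label = "neo_be"
    )
  )
}

#' Precision and recall of called clones against simulated truth
#'
#' Compares the pairwise co-membership of a called [call_clones()] partition
#' with the true co-clonality of a [simulate_cohort()] run. A called
#' co-clonal pair is a true positive when the two glands genuinely share a
#' mutation event in the genealogy; precision below 1 can only arise from
#' key collisions (two independent mutation events at the same position
#' with the same alternate allele).
#'
#' @param graph A `clone_graph` over simulated gland samples.
#' @param truth_clones The `truth_clones` table of a `sim_cohort`.
#' @return A one-row tibble: `n_called_pairs`, `n_true_pairs`,
#'   `n_correct_pairs`, `precision`, `recall` (each `NA` when its
#'   denominator is empty).
#' @export
clone_accuracy <- function(graph, truth_clones) {
  stopifnot(inherits(graph, "clone_graph"))
  called <- .pair_set(graph$nodes$sample_id, graph$nodes$clone_id)
  truth <- .pair_set(truth_clones$gland_id, truth_clones$true_clone)
  n_called <- length(called); n_true <- length(truth)
  n_correct <- length(intersect(called, truth))
  tibble::tibble(
    n_called_pairs = n_called, n_true_pairs = n_true,
    n_correct_pairs = n_correct,
    precision = if (n_called > 0) n_correct / n_called else NA_real_,
    recall = if (n_true > 0) n_correct / n_true else NA_real_
  )
}

.pair_set <- function(ids, membership) {
  out <- character()
  for (cl in unique(membership)) {
    members <- sort(ids[membership == cl])
    if (length(members) < 2) next
    pairs <- utils::combn(members, 2)
    out <- c(out, paste(pairs[1, ], pairs[2, ], sep = "|"))
  }
  out
}
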