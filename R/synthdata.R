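# Synthetic-data generators. They emulate the study design end to end --
# plate screens with controls, NB counts with planted regulation, ranked
# lists with planted reversal genes -- with explicit seeds and ground-truth
# tables, so every downstream stage is testable without external data.

# Default assay baselines. The screen noise SDs are calibrated so that the
# simulated assays reproduce the reported assay quality: plain Z = 0.83 for
# the cystine HTS, replicate-adjusted (r = 3) Z = 0.55 for the apoptosis HCS
# with 32 + 32 controls per 384-well plate (censoring of near-zero control
# fractions at 0 is accounted for in the calibration).
CYSTINE_DEFAULTS <- list(
  wells_per_plate = 48L, neg_ctrl_per_plate = 8L, pos_ctrl_per_plate = 8L,
  noise_sd = 0.0255, n_replicates = 1L,
  vehicle_level = 12, protein_mg = 0.5, positive_frac = 0.1
)
APOPTOSIS_DEFAULTS <- list(
  wells_per_plate = 384L, neg_ctrl_per_plate = 32L, pos_ctrl_per_plate = 32L,
  noise_sd = 0.119, n_replicates = 3L,
  induced_frac = 0.40, non_induced_frac = 0.05, total_nuclei = 1000L
)

plate_grid <- function(wells_per_plate) {
  known <- list(`48` = c(6L, 8L), `96` = c(8L, 12L), `384` = c(16L, 24L))
  g <- known[[as.character(wells_per_plate)]]
  if (is.null(g)) {
    cols <- ceiling(sqrt(wells_per_plate))
    g <- c(ceiling(wells_per_plate / cols), cols)
  }
  g
}

well_labels <- function(n, wells_per_plate) {
  g <- plate_grid(wells_per_plate)
  idx <- seq_len(n) - 1L
  paste0(LETTERS[idx %/% g[2] + 1L], sprintf("%02d", idx %% g[2] + 1L))
}

#' Configuration for a simulated compound screen
#'
#' Describes one phenotypic screen of the compound library: plate geometry,
#' per-plate control wells, planted true hits, readout noise, and replicate
#' plates. Phenotype-specific defaults: the cystine HTS uses 48-well plates
#' (8 vehicle + 8 cysteamine control wells, single replicate), the apoptosis
#' HCS 384-well plates (32 induced-untreated + 32 non-induced controls,
#' triplicate plates). Noise is gaussian on the readout with
#' `sd = noise_sd * control mean`.
#'
#' @param phenotype `"cystine"` or `"apoptosis"`.
#' @param n_compounds Library size (default 1200).
#' @param planted_hits `NULL` or data frame with `compound_id` and `effect`
#'   (true fractional reduction in \[0, 1\]); planted compounds must exist in
#'   the library.
#' @param wells_per_plate,neg_ctrl_per_plate,pos_ctrl_per_plate Plate
#'   geometry; defaults per phenotype.
#' @param noise_sd Readout noise as a fraction of the negative-control mean;
#'   defaults per phenotype (calibrated to the assay-quality the generator
#'   emulates).
#' @param n_replicates Number of replicate plate sets (replicates live on
#'   different plates).
#' @param n_plates Plates per replicate; derived from the library size when
#'   `NULL`.
#' @param seed Mandatory RNG seed.
#' @return Object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(phenotype = c("cystine", "apoptosis"),
                              n_compounds = 1200,
                              planted_hits = NULL,
                              wells_per_plate = NULL,
                              neg_ctrl_per_plate = NULL,
                              pos_ctrl_per_plate = NULL,
                              noise_sd = NULL,
                              n_replicates = NULL,
                              n_plates = NULL,
                              seed = 1L) {
  phenotype <- match.arg(phenotype)
  defaults <- if (phenotype == "cystine") CYSTINE_DEFAULTS else APOPTOSIS_DEFAULTS
  n_compounds <- assert_count(n_compounds, "n_compounds", lower = 1)
  wells_per_plate <- assert_count(wells_per_plate %||% defaults$wells_per_plate,
                                  "wells_per_plate", lower = 4)
  neg_ctrl_per_plate <- assert_count(neg_ctrl_per_plate %||% defaults$neg_ctrl_per_plate,
                                     "neg_ctrl_per_plate", lower = 2)
  pos_ctrl_per_plate <- assert_count(pos_ctrl_per_plate %||% defaults$pos_ctrl_per_plate,
                                     "pos_ctrl_per_plate", lower = 2)
  noise_sd <- noise_sd %||% defaults$noise_sd
  assert_number(noise_sd, "noise_sd", lower = 0)
  n_replicates <- assert_count(n_replicates %||% defaults$n_replicates,
                               "n_replicates", lower = 1)
  seed <- assert_count(seed, "seed")

  capacity <- wells_per_plate - neg_ctrl_per_plate - pos_ctrl_per_plate
  if (capacity < 1L) {
    stopf("plate geometry error: %d control wells leave no room on a %d-well plate",
          neg_ctrl_per_plate + pos_ctrl_per_plate, wells_per_plate)
  }
  plates_needed <- ceiling(n_compounds / capacity)
  if (is.null(n_plates)) {
    n_plates <- plates_needed
  } else {
    n_plates <- assert_count(n_plates, "n_plates", lower = 1)
    if (n_plates < plates_needed) {
      stopf("plate geometry error: %d compounds need %d plates of capacity %d, got %d",
            n_compounds, plates_needed, capacity, n_plates)
    }
  }

  compound_ids <- sprintf("CPD%04d", seq_len(n_compounds))
  if (!is.null(planted_hits)) {
    if (!is.data.frame(planted_hits) ||
        !all(c("compound_id", "effect") %in% names(planted_hits))) {
      stopf("'planted_hits' must have columns 'compound_id' and 'effect'")
    }
    if (anyDuplicated(planted_hits$compound_id)) stopf("duplicated planted compound ids")
    unknown <- setdiff(planted_hits$compound_id, compound_ids)
    if (length(unknown)) {
      stopf("planted compound(s) not in the library: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
    }
    if (any(planted_hits$effect < 0 | planted_hits$effect > 1)) {
      stopf("planted effects must lie in [0, 1]")
    }
  }

  structure(
    c(list(phenotype = phenotype, n_compounds = n_compounds,
           compound_ids = compound_ids, planted_hits = planted_hits,
           wells_per_plate = wells_per_plate,
           neg_ctrl_per_plate = neg_ctrl_per_plate,
           pos_ctrl_per_plate = pos_ctrl_per_plate,
           capacity = capacity, n_plates = n_plates,
           noise_sd = noise_sd, n_replicates = n_replicates, seed = seed),
      defaults[setdiff(names(defaults),
                       c("wells_per_plate", "neg_ctrl_per_plate",
                         "pos_ctrl_per_plate", "noise_sd", "n_replicates"))]),
    class = "screen_sim_config"
  )
}

#' Simulate a compound screen
#'
#' Generates per-well plate tables with vehicle/positive control wells and
#' library-compound wells. Non-hit compounds have expected normalized
#' activity 100% of vehicle; a planted hit with effect `e` has expected
#' activity `100 * (1 - e)`. Gaussian readout noise with
#' `sd = noise_sd * control mean`; readouts are censored at physical bounds
#' (0, and 1 for fractions). Identical seeds give identical output.
#'
#' For the cystine phenotype, wells carry `cystine_nmol` and `protein_mg`;
#' for apoptosis, `positive_nuclei` and `total_nuclei`, with roles
#' `induced_untreated` (normalization reference), `non_induced` (Z-factor
#' positive control) and `compound` (induced, treated).
#'
#' @param cfg A [screen_sim_config()].
#' @return List of class `screen_sim` with `wells` (data frame: `plate_id`,
#'   `well`, `replicate`, `compound_id`, `role`, readout columns), `truth`
#'   (data frame: `compound_id`, `effect`, `expected_activity`), and
#'   `config`.
#' @export
simulate_screen <- function(cfg) {
  if (!inherits(cfg, "screen_sim_config")) stopf("'cfg' must be a screen_sim_config")
  with_seed(cfg$seed, {
    effects <- stats::setNames(numeric(cfg$n_compounds), cfg$compound_ids)
    if (!is.null(cfg$planted_hits)) {
      effects[cfg$planted_hits$compound_id] <- cfg$planted_hits$effect
    }
    plate_of <- rep(seq_len(cfg$n_plates), each = cfg$capacity)[seq_len(cfg$n_compounds)]

    reps <- lapply(seq_len(cfg$n_replicates), function(r) {
      plates <- lapply(seq_len(cfg$n_plates), function(p) {
        cpds <- cfg$compound_ids[plate_of == p]
        n_cpd <- length(cpds)
        n_wells <- cfg$neg_ctrl_per_plate + cfg$pos_ctrl_per_plate + n_cpd
        roles <- c(rep(if (cfg$phenotype == "cystine") "vehicle" else "induced_untreated",
                       cfg$neg_ctrl_per_plate),
                   rep(if (cfg$phenotype == "cystine") "cysteamine" else "non_induced",
                       cfg$pos_ctrl_per_plate),
                   rep("compound", n_cpd))
        data.frame(
          plate_id = sprintf("R%d-P%02d", r, p),
          well = well_labels(n_wells, cfg$wells_per_plate),
          replicate = r,
          compound_id = c(rep(NA_character_, n_wells - n_cpd), cpds),
          role = roles,
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, plates)
    })
    wells <- do.call(rbind, reps)

    # expected activity per well, as a fraction of the negative-control level
    activity <- ifelse(
      wells$role == "compound", 1 - effects[wells$compound_id],
      ifelse(wells$role %in% c("vehicle", "induced_untreated"), 1,
             if (cfg$phenotype == "cystine") cfg$positive_frac
             else cfg$non_induced_frac / cfg$induced_frac)
    )

    if (cfg$phenotype == "cystine") {
      level <- cfg$vehicle_level * activity +
        stats::rnorm(nrow(wells), 0, cfg$noise_sd * cfg$vehicle_level)
      level <- pmax(level, 0)
      wells$cystine_nmol <- level * cfg$protein_mg
      wells$protein_mg <- cfg$protein_mg
    } else {
      frac <- cfg$induced_frac * activity +
        stats::rnorm(nrow(wells), 0, cfg$noise_sd * cfg$induced_frac)
      frac <- pmin(pmax(frac, 0), 1)
      wells$total_nuclei <- cfg$total_nuclei
      wells$positive_nuclei <- as.integer(round(frac * cfg$total_nuclei))
    }

    truth <- data.frame(
      compound_id = cfg$compound_ids,
      effect = unname(effects),
      expected_activity = 100 * (1 - unname(effects)),
      stringsAsFactors = FALSE
    )
    structure(list(wells = wells, truth = truth, config = cfg),
              class = "screen_sim")
  })
}

#' Configuration for a simulated count matrix
#'
#' Two-group negative-binomial counts with planted up/down regulation in the
#' second (knockout) group. Defaults mirror a triplicate-vs-triplicate
#' design.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (default 3).
#' @param baseline_mean NB mean for unregulated genes (default 100).
#' @param dispersion NB dispersion `alpha` (variance `mu + alpha mu^2`),
#'   > 0; values below 1e-9 fall back to Poisson sampling.
#' @param planted_up Named numeric vector: gene -> log2 effect (>= 1) in the
#'   knockout group.
#' @param planted_down Named numeric vector: gene -> log2 effect (<= -1);
#'   disjoint from `planted_up`.
#' @param seed Mandatory RNG seed.
#' @return Object of class `counts_sim_config`.
#' @export
counts_sim_config <- function(n_genes = 10000, n_per_group = 3,
                              baseline_mean = 100, dispersion = 0.05,
                              planted_up = NULL, planted_down = NULL,
                              seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", lower = 1)
  n_per_group <- assert_count(n_per_group, "n_per_group", lower = 1)
  assert_number(baseline_mean, "baseline_mean", lower = 1e-12)
  assert_number(dispersion, "dispersion", lower = 0)
  if (dispersion <= 0) stopf("'dispersion' must be > 0 (use a tiny value for the Poisson limit)")
  seed <- assert_count(seed, "seed")
  genes <- sprintf("G%05d", seq_len(n_genes))
  check_planted <- function(x, name, sign) {
    if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(x)) || !is.numeric(x)) stopf("'%s' must be a named numeric vector", name)
    unknown <- setdiff(names(x), genes)
    if (length(unknown)) stopf("'%s' contains gene(s) not in the genome: %s",
                               name, paste(utils::head(unknown, 5), collapse = ", "))
    if (sign > 0 && any(x < 1)) stopf("'%s' effects must be >= 1 (log2)", name)
    if (sign < 0 && any(x > -1)) stopf("'%s' effects must be <= -1 (log2)", name)
    x
  }
  planted_up <- check_planted(planted_up, "planted_up", 1)
  planted_down <- check_planted(planted_down, "planted_down", -1)
  if (length(intersect(names(planted_up), names(planted_down)))) {
    stopf("'planted_up' and 'planted_down' must be disjoint")
  }
  structure(
    list(n_genes = n_genes, genes = genes, n_per_group = n_per_group,
         baseline_mean = baseline_mean, dispersion = dispersion,
         planted_up = planted_up, planted_down = planted_down, seed = seed),
    class = "counts_sim_config"
  )
}

#' Simulate a two-group NB count matrix
#'
#' @param cfg A [counts_sim_config()].
#' @return List of class `counts_sim` with `counts` (integer matrix, genes x
#'   samples), `samples` (data frame `sample`, `group` with levels
#'   `wild_type` / `knockout`), `truth` (data frame `gene`, `log2_effect`,
#'   `is_de`), and `config`.
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "counts_sim_config")) stopf("'cfg' must be a counts_sim_config")
  with_seed(cfg$seed, {
    m <- cfg$n_per_group
    effect <- stats::setNames(numeric(cfg$n_genes), cfg$genes)
    effect[names(cfg$planted_up)] <- cfg$planted_up
    effect[names(cfg$planted_down)] <- cfg$planted_down
    mu1 <- rep(cfg$baseline_mean, cfg$n_genes)
    mu2 <- cfg$baseline_mean * 2^effect
    mu <- cbind(matrix(rep(mu1, m), ncol = m),
                matrix(rep(mu2, m), ncol = m))
    n_cells <- length(mu)
    counts <- if (cfg$dispersion < 1e-9) {
      stats::rpois(n_cells, lambda = as.vector(mu))
    } else {
      stats::rnbinom(n_cells, mu = as.vector(mu), size = 1 / cfg$dispersion)
    }
    counts <- matrix(as.integer(counts), nrow = cfg$n_genes,
                     dimnames = list(cfg$genes,
                                     c(sprintf("WT%d", seq_len(m)),
                                       sprintf("KO%d", seq_len(m)))))
    samples <- data.frame(
      sample = colnames(counts),
      group = rep(c("wild_type", "knockout"), each = m),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(gene = cfg$genes, log2_effect = unname(effect),
                        is_de = unname(effect != 0), stringsAsFactors = FALSE)
    structure(list(counts = counts, samples = samples, truth = truth,
                   config = cfg),
              class = "counts_sim")
  })
}

#' Configuration for simulated prototype ranked lists
#'
#' Each compound gets a total order over the genome. A planted reverser of a
#' disease-UP gene is placed in the bottom (compound-downregulated) tail of
#' exactly its configured number of supporting compounds' lists and outside
#' both tails elsewhere; symmetric for disease-DOWN genes. Setting
#' `same_direction = TRUE` for a planted gene places it in the
#' same-direction tail instead (a distractor that the voting stage must
#' never select).
#'
#' @param genome Character vector of gene ids.
#' @param n_compounds Number of ranked lists (default 5).
#' @param planted_reversers `NULL` or data frame with columns `gene`,
#'   `disease_direction` (`"up"`/`"down"`), `support` (0..n_compounds), and
#'   optionally `same_direction` (logical).
#' @param tail_size Tail size used for planting (default 250); must leave a
#'   non-tail middle large enough for the planted genes.
#' @param seed Mandatory RNG seed.
#' @return Object of class `prl_sim_config`.
#' @export
prl_sim_config <- function(genome, n_compounds = 5, planted_reversers = NULL,
                           tail_size = 250, seed = 1L) {
  genome <- as.character(genome)
  if (anyDuplicated(genome)) stopf("'genome' has duplicated gene ids")
  n_compounds <- assert_count(n_compounds, "n_compounds", lower = 1)
  tail_size <- assert_count(tail_size, "tail_size", lower = 1)
  if (2L * tail_size > length(genome)) {
    stopf("tail_size %d too large for a %d-gene genome", tail_size, length(genome))
  }
  seed <- assert_count(seed, "seed")
  if (!is.null(planted_reversers)) {
    need <- c("gene", "disease_direction", "support")
    if (!is.data.frame(planted_reversers) || !all(need %in% names(planted_reversers))) {
      stopf("'planted_reversers' must have columns %s", paste(need, collapse = ", "))
    }
    if (anyDuplicated(planted_reversers$gene)) stopf("duplicated planted genes")
    unknown <- setdiff(planted_reversers$gene, genome)
    if (length(unknown)) stopf("planted gene(s) absent from genome: %s",
                               paste(utils::head(unknown, 5), collapse = ", "))
    if (!all(planted_reversers$disease_direction %in% c("up", "down"))) {
      stopf("disease_direction must be 'up' or 'down'")
    }
    if (any(planted_reversers$support < 0 | planted_reversers$support > n_compounds)) {
      stopf("support counts must lie in 0..n_compounds")
    }
    if (is.null(planted_reversers$same_direction)) {
      planted_reversers$same_direction <- FALSE
    }
    if (nrow(planted_reversers) > length(genome) - 2L * tail_size) {
      stopf("too many planted genes for the non-tail middle region")
    }
  }
  structure(
    list(genome = genome, n_compounds = n_compounds,
         planted_reversers = planted_reversers, tail_size = tail_size,
         seed = seed),
    class = "prl_sim_config"
  )
}

#' Simulate per-compound prototype ranked lists
#'
#' @param cfg A [prl_sim_config()].
#' @return List of class `prl_sim` with `prls` (named list of
#'   [ranked_list()] objects), `truth` (the planted table plus a
#'   `supporting_compounds` column naming the supporters), and `config`.
#' @export
simulate_prls <- function(cfg) {
  if (!inherits(cfg, "prl_sim_config")) stopf("'cfg' must be a prl_sim_config")
  with_seed(cfg$seed, {
    G <- length(cfg$genome)
    ts <- cfg$tail_size
    compounds <- sprintf("DRUG%02d", seq_len(cfg$n_compounds))
    planted <- cfg$planted_reversers
    if (is.null(planted)) {
      planted <- data.frame(gene = character(), disease_direction = character(),
                            support = integer(), same_direction = logical(),
                            stringsAsFactors = FALSE)
    }
    # choose supporting compounds per planted gene
    supporters <- lapply(planted$support, function(s) sort(sample.int(cfg$n_compounds, s)))

    prls <- lapply(seq_len(cfg$n_compounds), function(j) {
      supported_here <- vapply(supporters, function(s) j %in% s, logical(1))
      # a compound downregulates a disease-UP gene it supports (and vice
      # versa), unless the plant is a same-direction distractor
      zone <- rep("middle", nrow(planted))
      opp <- ifelse(planted$disease_direction == "up", "down", "up")
      tail_dir <- ifelse(planted$same_direction, planted$disease_direction, opp)
      zone[supported_here] <- tail_dir[supported_here]

      up_tail_genes <- planted$gene[zone == "up"]
      down_tail_genes <- planted$gene[zone == "down"]
      mid_genes <- planted$gene[zone == "middle"]

      perm <- character(G)
      pos_up <- sample(seq_len(ts), length(up_tail_genes))
      pos_down <- sample(seq.int(G - ts + 1L, G), length(down_tail_genes))
      pos_mid <- sample(seq.int(ts + 1L, G - ts), length(mid_genes))
      perm[pos_up] <- up_tail_genes
      perm[pos_down] <- down_tail_genes
      perm[pos_mid] <- mid_genes
      rest <- setdiff(cfg$genome, planted$gene)
      perm[perm == ""] <- sample(rest)
      ranked_list(compounds[j], perm)
    })
    names(prls) <- compounds
    truth <- planted
    truth$supporting_compounds <- vapply(supporters, function(s) {
      paste(compounds[s], collapse = ",")
    }, character(1))
    structure(list(prls = prls, truth = truth, config = cfg),
              class = "prl_sim")
  })
}

#' Simulate dose-response measurements for lead compounds
#'
#' Responses (percent of vehicle) are drawn from a four-parameter logistic
#' truth per compound plus gaussian noise, at the tested dose grid.
#'
#' @param compound_ids Compounds to simulate.
#' @param doses Dose grid in uM (default the tested 1, 2.5, 5, 10).
#' @param n_replicates Replicates per dose (default 3).
#' @param noise_sd Gaussian noise SD on the percent scale (default 2).
#' @param truth Optional data frame (`compound_id`, `a`, `d`, `c`, `b`);
#'   random realistic parameters are drawn when `NULL`.
#' @param seed Mandatory RNG seed.
#' @return List with `data` (data frame `compound_id`, `dose_uM`,
#'   `response_percent`, `replicate`) and `truth`.
#' @export
simulate_dose_response <- function(compound_ids, doses = c(1, 2.5, 5, 10),
                                   n_replicates = 3, noise_sd = 2,
                                   truth = NULL, seed = 1L) {
  seed <- assert_count(seed, "seed")
  with_seed(seed, {
    if (is.null(truth)) {
      truth <- data.frame(
        compound_id = compound_ids,
        a = 100,
        d = stats::runif(length(compound_ids), 5, 15),
        c = stats::runif(length(compound_ids), 1, 3),
        b = stats::runif(length(compound_ids), 1, 2.5),
        stringsAsFactors = FALSE
      )
    }
    grid <- expand.grid(compound_id = compound_ids, dose_uM = doses,
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tr <- truth[match(grid$compound_id, truth$compound_id), ]
    mu <- tr$d + (tr$a - tr$d) / (1 + (grid$dose_uM / tr$c)^tr$b)
    grid$response_percent <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    list(data = grid[order(grid$compound_id, grid$dose_uM, grid$replicate), ],
         truth = truth)
  })
}

#' Simulate a gene-set collection (GMT-style)
#'
#' Random gene sets drawn from a genome, optionally with planted sets whose
#' membership is supplied verbatim (e.g. a set enriched for reversal genes).
#'
#' @param genome Character vector of gene ids.
#' @param n_sets Number of random sets (default 50).
#' @param size_range Min/max random set size (default 10..100).
#' @param planted Optional named list: set id -> character vector of member
#'   genes.
#' @param seed Mandatory RNG seed.
#' @return List of sets (`id`, `name`, `genes`) ready for
#'   [gene_set_collection()] or [write_gmt()].
#' @export
simulate_gene_sets <- function(genome, n_sets = 50, size_range = c(10, 100),
                               planted = NULL, seed = 1L) {
  seed <- assert_count(seed, "seed")
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sz <- sample(seq(size_range[1], size_range[2]), 1)
      list(id = sprintf("SET%03d", i), name = sprintf("random set %d", i),
           genes = sample(genome, sz))
    })
    names(sets) <- vapply(sets, `[[`, character(1), "id")
    for (id in names(planted %||% list())) {
      sets[[id]] <- list(id = id, name = id, genes = planted[[id]])
    }
    sets
  })
}
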