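#' Default synthetic study
#'
#' Builds the seeded synthetic counterpart of the full study design, with
#' ground truth for every stage:
#'
#' * a 1200-compound cystine HTS with 24 planted depleters (effect 0.8) and
#'   an apoptosis HCS with 27 planted protectors (effect 0.7), 6 compounds
#'   overlapping;
#' * a 10,000-gene triplicate count matrix with 200 planted regulated genes
#'   (the 39 reversal genes at log2 effect +/-3, the rest at magnitudes
#'   drawn from 1..3);
#' * 5 prototype ranked lists planting 23 disease-up genes downregulated by
#'   >= 4 compounds and 16 disease-down genes upregulated by >= 4 compounds,
#'   plus below-threshold (support 3), same-direction, and non-DEG
#'   distractors;
#' * dose-response data for the lead compounds (one crossed compound is
#'   marked toxic and excluded, leaving 5 leads) and a gene-set collection
#'   with one set enriched for reversal genes.
#'
#' All randomness derives from `seed`.
#'
#' @param seed Integer base seed.
#' @return List of class `cysti_study` with elements `cystine`, `apoptosis`
#'   (each a `screen_sim`), `counts` (a `counts_sim`), `prls` (a `prl_sim`),
#'   `dose_response`, `gene_sets`, `exclude` (toxic compound id), and
#'   `truth` (planted hit/DEG/reversal ids).
#' @export
default_study <- function(seed = 1L) {
  seed <- assert_count(seed, "seed")

  # --- compound-level truth -------------------------------------------------
  n_compounds <- 1200L
  ids <- sprintf("CPD%04d", seq_len(n_compounds))
  picks <- with_seed(derive_seed(seed, 11), {
    depleters <- sort(sample(ids, 24))
    overlap <- sort(sample(depleters, 6))
    protectors <- sort(c(overlap, sample(setdiff(ids, depleters), 21)))
    list(depleters = depleters, protectors = protectors, overlap = overlap)
  })

  cystine_cfg <- screen_sim_config(
    phenotype = "cystine", n_compounds = n_compounds,
    planted_hits = data.frame(compound_id = picks$depleters, effect = 0.8,
                              stringsAsFactors = FALSE),
    seed = derive_seed(seed, 21)
  )
  apoptosis_cfg <- screen_sim_config(
    phenotype = "apoptosis", n_compounds = n_compounds,
    planted_hits = data.frame(compound_id = picks$protectors, effect = 0.7,
                              stringsAsFactors = FALSE),
    seed = derive_seed(seed, 22)
  )

  # --- transcriptome truth --------------------------------------------------
  n_genes <- 10000L
  genes <- sprintf("G%05d", seq_len(n_genes))
  plant <- with_seed(derive_seed(seed, 12), {
    special <- sample(genes, 49)        # reversal genes + voting distractors
    rev_up <- special[1:23]             # disease-up, down-voted by >= 4
    rev_down <- special[24:39]          # disease-down, up-voted by >= 4
    sub_k <- special[40:45]             # support 3: below the k = 4 cut
    same_dir <- special[46:49]          # supported in the disease direction
    remaining <- sample(setdiff(genes, special), 151)
    other_up <- remaining[1:76]
    other_down <- remaining[77:151]
    ns_distract <- sample(setdiff(genes, c(special, remaining)), 4)
    list(rev_up = rev_up, rev_down = rev_down, sub_k = sub_k,
         same_dir = same_dir, other_up = other_up, other_down = other_down,
         ns_distract = ns_distract,
         other_up_eff = stats::runif(76, 1, 3),
         other_down_eff = -stats::runif(75, 1, 3))
  })
  planted_up <- c(stats::setNames(rep(3, 23), plant$rev_up),
                  stats::setNames(rep(3, 3), plant$sub_k[1:3]),
                  stats::setNames(rep(3, 2), plant$same_dir[1:2]),
                  stats::setNames(plant$other_up_eff, plant$other_up))
  planted_down <- c(stats::setNames(rep(-3, 16), plant$rev_down),
                    stats::setNames(rep(-3, 3), plant$sub_k[4:6]),
                    stats::setNames(rep(-3, 2), plant$same_dir[3:4]),
                    stats::setNames(plant$other_down_eff, plant$other_down))
  counts_cfg <- counts_sim_config(
    n_genes = n_genes, n_per_group = 3, baseline_mean = 100, dispersion = 0.05,
    planted_up = planted_up, planted_down = planted_down,
    seed = derive_seed(seed, 23)
  )

  # --- ranked-list truth ----------------------------------------------------
  dir_of <- function(g) ifelse(g %in% names(planted_up), "up", "down")
  planted_reversers <- data.frame(
    gene = c(plant$rev_up, plant$rev_down, plant$sub_k, plant$same_dir,
             plant$ns_distract),
    disease_direction = c(rep("up", 23), rep("down", 16), dir_of(plant$sub_k),
                          dir_of(plant$same_dir), rep("up", 4)),
    support = c(rep(5, 12), rep(4, 11),       # 23 disease-up reversers
                rep(5, 8), rep(4, 8),         # 16 disease-down reversers
                rep(3, 6),                    # below-threshold
                rep(5, 4),                    # same-direction
                rep(5, 4)),                   # not DEGs
    same_direction = c(rep(FALSE, 45), rep(TRUE, 4), rep(FALSE, 4)),
    stringsAsFactors = FALSE
  )
  prl_cfg <- prl_sim_config(genome = genes, n_compounds = 5,
                            planted_reversers = planted_reversers,
                            tail_size = 250, seed = derive_seed(seed, 24))

  # --- realize the study ----------------------------------------------------
  cystine <- simulate_screen(cystine_cfg)
  apoptosis <- simulate_screen(apoptosis_cfg)
  counts <- simulate_counts(counts_cfg)
  prls <- simulate_prls(prl_cfg)

  exclude <- picks$overlap[1]  # modelled toxic compound, dropped before DR
  leads <- setdiff(picks$overlap, exclude)
  dr <- simulate_dose_response(leads, seed = derive_seed(seed, 25))

  planted_set <- with_seed(derive_seed(seed, 26), {
    c(sample(c(plant$rev_up, plant$rev_down), 15), sample(genes, 25))
  })
  gene_sets <- simulate_gene_sets(genes, n_sets = 50,
                                  planted = list(SET_REVERSAL = planted_set),
                                  seed = derive_seed(seed, 27))

  structure(
    list(cystine = cystine, apoptosis = apoptosis, counts = counts,
         prls = prls, dose_response = dr, gene_sets = gene_sets,
         exclude = exclude,
         truth = list(depleters = picks$depleters,
                      protectors = picks$protectors,
                      overlap = picks$overlap,
                      leads = leads,
                      deg_up = names(planted_up), deg_down = names(planted_down),
                      reversal_up = sort(plant$rev_up),
                      reversal_down = sort(plant$rev_down)),
         seed = seed),
    class = "cysti_study"
  )
}
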