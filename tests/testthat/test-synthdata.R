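test_that("all three generators are deterministic under a fixed seed", {
  cfg <- screen_sim_config("cystine", n_compounds = 100, seed = 1)
  expect_identical(simulate_screen(cfg), simulate_screen(cfg))

  ccfg <- counts_sim_config(n_genes = 200, n_per_group = 3, seed = 1)
  expect_identical(simulate_counts(ccfg), simulate_counts(ccfg))

  pcfg <- prl_sim_config(genome = sprintf("G%05d", 1:100), n_compounds = 3,
                         tail_size = 10, seed = 1)
  expect_identical(simulate_prls(pcfg), simulate_prls(pcfg))
})

test_that("zero-noise screens give exact expected activities", {
  cfg <- screen_sim_config("cystine", n_compounds = 20, noise_sd = 0,
                           planted_hits = data.frame(compound_id = "CPD0007",
                                                     effect = 0.8),
                           seed = 3)
  sim <- simulate_screen(cfg)
  act <- screen_cystine(sim$wells)
  expect_equal(act$activity[act$compound_id == "CPD0007"], 20)
  expect_true(all(abs(act$activity[act$compound_id != "CPD0007"] - 100) < 1e-9))
})

test_that("screen configuration errors are caught", {
  expect_error(screen_sim_config("cystine", wells_per_plate = 10,
                                 neg_ctrl_per_plate = 5, pos_ctrl_per_plate = 5),
               "geometry")
  expect_error(screen_sim_config("cystine", n_compounds = 10,
                                 planted_hits = data.frame(compound_id = "CPD9999",
                                                           effect = 0.5)),
               "not in the library")
  expect_error(screen_sim_config("cystine", n_compounds = 10,
                                 planted_hits = data.frame(compound_id = "CPD0001",
                                                           effect = 1.5)),
               "\\[0, 1\\]")
  expect_error(screen_sim_config("cystine", n_compounds = 500, n_plates = 2),
               "geometry")
})

test_that("simulated counts follow the configured NB law", {
  cfg <- counts_sim_config(n_genes = 50, n_per_group = 500, baseline_mean = 100,
                           dispersion = 0.05,
                           planted_up = c(G00010 = 2), seed = 7)
  sim <- simulate_counts(cfg)
  expect_identical(dim(sim$counts), c(50L, 1000L))
  expect_true(all(sim$counts >= 0))
  expect_type(sim$counts[1, 1], "integer")
  ko <- sim$samples$group == "knockout"
  # planted gene: knockout mean scaled by 2^2 = 4 (law of large numbers)
  expect_equal(mean(sim$counts["G00010", ko]), 400, tolerance = 0.05)
  expect_equal(mean(sim$counts["G00010", !ko]), 100, tolerance = 0.05)
  # truth table marks exactly the planted gene
  expect_identical(sim$truth$gene[sim$truth$is_de], "G00010")
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- counts_sim_config(n_genes = 400, n_per_group = 100,
                           baseline_mean = 100, dispersion = 1e-10, seed = 11)
  sim <- simulate_counts(cfg)
  ratio <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("counts configuration errors are caught", {
  expect_error(counts_sim_config(n_genes = -5), "integer")
  expect_error(counts_sim_config(planted_up = c(NOPE = 2)), "not in the genome")
  expect_error(counts_sim_config(n_genes = 10, planted_up = c(G00001 = 0.5)),
               ">= 1")
  expect_error(counts_sim_config(n_genes = 10, planted_up = c(G00001 = 2),
                                 planted_down = c(G00001 = -2)),
               "disjoint")
})

test_that("simulated PRLs are permutations with planted tail membership", {
  genome <- sprintf("G%05d", 1:500)
  planted <- data.frame(
    gene = c("G00001", "G00002", "G00003"),
    disease_direction = c("up", "up", "down"),
    support = c(5, 3, 4),
    stringsAsFactors = FALSE
  )
  cfg <- prl_sim_config(genome, n_compounds = 5, planted_reversers = planted,
                        tail_size = 20, seed = 5)
  sim <- simulate_prls(cfg)
  expect_length(sim$prls, 5)
  for (rl in sim$prls) expect_setequal(rl$genes, genome)

  # tail membership equals the configured support, gene outside tails elsewhere
  sigs <- lapply(sim$prls, tails_to_signature, tail_size = 20)
  in_down <- vapply(sigs, function(s) "G00001" %in% s$down_set, logical(1))
  expect_equal(sum(in_down), 5)
  in_down2 <- vapply(sigs, function(s) "G00002" %in% s$down_set, logical(1))
  in_up2 <- vapply(sigs, function(s) "G00002" %in% s$up_set, logical(1))
  expect_equal(sum(in_down2), 3)
  expect_equal(sum(in_up2), 0)
  in_up3 <- vapply(sigs, function(s) "G00003" %in% s$up_set, logical(1))
  expect_equal(sum(in_up3), 4)

  # a 3-of-5 supported gene must not be selected at k = 4
  deg <- make_deg(up = c("G00001", "G00002"), down = "G00003")
  sel <- vote_reversal(deg, unname(sigs), k = 4)
  expect_setequal(sel$gene, c("G00001", "G00003"))

  # no planted reversers -> voting selects nothing
  empty_cfg <- prl_sim_config(genome, n_compounds = 5, tail_size = 20, seed = 6)
  empty_sigs <- lapply(simulate_prls(empty_cfg)$prls, tails_to_signature,
                       tail_size = 20)
  none <- vote_reversal(make_deg(ns = genome[1:10]), unname(empty_sigs), k = 4)
  expect_equal(nrow(none), 0)
})

test_that("PRL configuration errors are caught", {
  genome <- sprintf("G%05d", 1:100)
  expect_error(prl_sim_config(genome, tail_size = 10, planted_reversers = data.frame(
    gene = "NOPE", disease_direction = "up", support = 2)), "absent from genome")
  expect_error(prl_sim_config(genome, n_compounds = 3, tail_size = 10,
    planted_reversers = data.frame(
      gene = "G00001", disease_direction = "up", support = 4)), "0..n_compounds")
  expect_error(prl_sim_config(genome, tail_size = 60), "too large")
})
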