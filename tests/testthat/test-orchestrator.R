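test_that("pipeline_config validates its thresholds", {
  dir <- withr::local_tempdir()
  expect_error(pipeline_config(dir, cystine_threshold = 0), "strictly inside")
  expect_error(pipeline_config(dir, apoptosis_threshold = 100), "strictly inside")
  expect_error(pipeline_config(dir, fdr_cut = 1), "strictly inside")
  expect_error(pipeline_config(dir, k = 0), ">= 1")
})

test_that("synthetic pipeline runs are deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  st <- default_study(5)
  m1 <- run_pipeline(pipeline_config(d1, seed = 5), study = st)
  m2 <- run_pipeline(pipeline_config(d2, seed = 5), study = st)
  expect_identical(m1, m2)
  # and the second run reproduces the first from scratch (fresh study)
  d3 <- withr::local_tempdir()
  m3 <- run_pipeline(pipeline_config(d3, seed = 5))
  expect_identical(m1, m3)
})

test_that("file-based pipeline excludes failed plates and reports them", {
  dir <- withr::local_tempdir()
  # --- cystine plates: plant hits on both plates, then wreck plate 2's
  #     vehicle controls so it fails QC and its compounds drop out
  cys <- simulate_screen(screen_sim_config(
    "cystine", n_compounds = 40, noise_sd = 0.02,
    planted_hits = data.frame(compound_id = c("CPD0003", "CPD0035"),
                              effect = 0.8),
    seed = 41))
  wells <- cys$wells
  bad <- wells$plate_id == "R1-P02" & wells$role == "vehicle"
  wells$cystine_nmol[bad] <- c(60, 0.01)[seq_len(sum(bad)) %% 2 + 1]
  cys_path <- file.path(dir, "cystine.csv")
  write_plate_csv(wells, cys_path)

  apo <- simulate_screen(screen_sim_config(
    "apoptosis", n_compounds = 40, noise_sd = 0.05,
    planted_hits = data.frame(compound_id = c("CPD0003", "CPD0010"),
                              effect = 0.7),
    seed = 42))
  apo_path <- file.path(dir, "apoptosis.csv")
  write_plate_csv(apo$wells, apo_path)

  # --- precomputed DEG table + ranked-list files + gene sets
  genome <- sprintf("G%05d", 1:300)
  deg <- make_deg(up = "G00001", down = "G00002", ns = genome[3:100])
  deg_path <- file.path(dir, "deg.tsv")
  write_deg_tsv(deg, deg_path)

  prl <- simulate_prls(prl_sim_config(
    genome, n_compounds = 5,
    planted_reversers = data.frame(gene = c("G00001", "G00002"),
                                   disease_direction = c("up", "down"),
                                   support = c(5, 4)),
    tail_size = 30, seed = 43))
  prl_paths <- vapply(names(prl$prls), function(id) {
    p <- file.path(dir, paste0(id, ".txt"))
    write_ranked_list(prl$prls[[id]], p)
    p
  }, character(1))

  gmt_path <- file.path(dir, "sets.gmt")
  write_gmt(simulate_gene_sets(genome[1:100], n_sets = 10,
                               size_range = c(5, 30), seed = 44), gmt_path)

  cfg <- pipeline_config(
    file.path(dir, "out"), seed = 1, tail_size = 30,
    cystine_plates = cys_path, apoptosis_plates = apo_path,
    deg_tsv = deg_path, prl_files = prl_paths, gmt = gmt_path)
  m <- suppressMessages(run_pipeline(cfg))

  expect_equal(unlist(m$qc$cystine_failed), "R1-P02")
  # plate 2's planted hit is gone with its plate; plate 1's hit survives
  hits <- read_screen_tsv(file.path(dir, "out", "cystine_hits.tsv"))
  expect_false("CPD0035" %in% hits$compound_id)
  expect_equal(hits$compound_id[hits$hit], "CPD0003")
  expect_equal(m$screens$n_cystine_hits, 1L)
  expect_setequal(unlist(m$cross$crossed), "CPD0003")
  expect_equal(m$reversal$disease_up_reversed, 1L)
  expect_equal(m$reversal$disease_down_reversed, 1L)
  expect_true(file.exists(file.path(dir, "out", "manifest.json")))
})

test_that("an empty compound library aborts cleanly at the cystine stage", {
  dir <- withr::local_tempdir()
  controls_only <- data.frame(
    plate_id = "R1-P01", well = sprintf("W%02d", 1:8), replicate = 1,
    compound_id = NA_character_,
    role = rep(c("vehicle", "cysteamine"), each = 4),
    cystine_nmol = c(3, 3.1, 2.9, 3, 0.3, 0.31, 0.29, 0.3), protein_mg = 0.5)
  p <- file.path(dir, "empty.csv")
  write_plate_csv(controls_only, p)
  apo_controls <- data.frame(
    plate_id = "R1-P01", well = sprintf("W%02d", 1:8), replicate = 1,
    compound_id = NA_character_,
    role = rep(c("induced_untreated", "non_induced"), each = 4),
    positive_nuclei = c(400, 410, 390, 400, 50, 51, 49, 50),
    total_nuclei = 1000L)
  ap <- file.path(dir, "apo.csv")
  write_plate_csv(apo_controls, ap)
  cfg <- pipeline_config(file.path(dir, "out"), cystine_plates = p,
                         apoptosis_plates = ap)
  expect_error(run_pipeline(cfg), "stage 'cystine'")
})
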