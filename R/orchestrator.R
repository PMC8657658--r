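#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis plus optional
#' paths to real inputs. When the plate/count/ranked-list inputs are `NULL`,
#' [run_pipeline()] generates them from the seeded [default_study()].
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed for synthetic inputs.
#' @param cystine_threshold Percent-reduction cut for cystine hits (default
#'   50).
#' @param apoptosis_threshold Percent-reduction cut for apoptosis hits
#'   (default 40).
#' @param fdr_cut,lfc_cut DEG thresholds (defaults 0.05 and 1).
#' @param k Minimum opposing compounds in the voting stage (default 4).
#' @param tail_size Ranked-list tail size (default 250).
#' @param qc_threshold Per-plate Z-factor gate (default 0: plates in the
#'   conventional "marginal or better" band are kept; see the methods
#'   vignette for why the plate gate is not the 0.5 assay-level bound).
#' @param z_mode Replicate-adjustment mode for the HCS Z-factor
#'   (`"spread"` or `"whole"`).
#' @param exclude Compound ids excluded before dose-response (e.g. toxic).
#' @param cystine_plates,apoptosis_plates Optional plate CSV paths.
#' @param counts_tsv,sample_sheet Optional counts + sample-sheet paths.
#' @param deg_tsv Optional precomputed DEG TSV (bypasses the NB test).
#' @param prl_files Optional named character vector of ranked-list files.
#' @param gmt Optional GMT path for the enrichment stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            cystine_threshold = 50, apoptosis_threshold = 40,
                            fdr_cut = 0.05, lfc_cut = 1,
                            k = 4, tail_size = 250,
                            qc_threshold = 0, z_mode = c("spread", "whole"),
                            exclude = NULL,
                            cystine_plates = NULL, apoptosis_plates = NULL,
                            counts_tsv = NULL, sample_sheet = NULL,
                            deg_tsv = NULL, prl_files = NULL, gmt = NULL) {
  z_mode <- match.arg(z_mode)
  assert_number(cystine_threshold, "cystine_threshold", lower = 0, upper = 100)
  assert_number(apoptosis_threshold, "apoptosis_threshold", lower = 0, upper = 100)
  if (cystine_threshold <= 0 || cystine_threshold >= 100 ||
      apoptosis_threshold <= 0 || apoptosis_threshold >= 100) {
    stopf("screen thresholds must lie strictly inside (0, 100)")
  }
  assert_number(fdr_cut, "fdr_cut", lower = 0, upper = 1)
  if (fdr_cut <= 0 || fdr_cut >= 1) stopf("fdr_cut must lie strictly inside (0, 1)")
  assert_number(lfc_cut, "lfc_cut", lower = 0)
  k <- assert_count(k, "k", lower = 1)
  tail_size <- assert_count(tail_size, "tail_size", lower = 1)
  assert_number(qc_threshold, "qc_threshold", upper = 1)
  structure(
    list(out_dir = out_dir, seed = assert_count(seed, "seed"),
         cystine_threshold = cystine_threshold,
         apoptosis_threshold = apoptosis_threshold,
         fdr_cut = fdr_cut, lfc_cut = lfc_cut, k = k, tail_size = tail_size,
         qc_threshold = qc_threshold, z_mode = z_mode,
         exclude = exclude,
         cystine_plates = cystine_plates, apoptosis_plates = apoptosis_plates,
         counts_tsv = counts_tsv, sample_sheet = sample_sheet,
         deg_tsv = deg_tsv, prl_files = prl_files, gmt = gmt),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline aborted at stage '%s': %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes QC, the two screens, hit crossing, dose-response fitting, the
#' differential-expression step (or DEG ingest), opposite-direction voting,
#' and enrichment, writing per-stage tables plus a machine-readable JSON
#' manifest to `cfg$out_dir`. Plates failing the Z-factor gate are excluded
#' from hit calling and reported in the manifest, never silently dropped.
#'
#' @param cfg A [pipeline_config()].
#' @param study Optional [default_study()] object to reuse; generated from
#'   `cfg$seed` when inputs are synthetic and `study` is `NULL`.
#' @return The run manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg, study = NULL) {
  if (!inherits(cfg, "pipeline_config")) stopf("'cfg' must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  synthetic <- is.null(cfg$cystine_plates)
  if (synthetic && is.null(study)) study <- default_study(cfg$seed)

  manifest <- list(seed = cfg$seed, synthetic = synthetic, outputs = list())
  out <- function(name) file.path(cfg$out_dir, name)

  # --- inputs ---------------------------------------------------------------
  cys_wells <- run_stage("load-cystine", {
    if (synthetic) study$cystine$wells else read_plate_csv(cfg$cystine_plates)
  })
  apo_wells <- run_stage("load-apoptosis", {
    if (synthetic) study$apoptosis$wells else read_plate_csv(cfg$apoptosis_plates)
  })

  # --- QC -------------------------------------------------------------------
  qc <- run_stage("qc", {
    cys_qc <- qc_plates(cys_wells, "cystine_nmol",
                        positive_role = "cysteamine", negative_role = "vehicle",
                        threshold = cfg$qc_threshold)
    apo_wells$fraction <- apoptosis_fraction(apo_wells$positive_nuclei,
                                             apo_wells$total_nuclei)
    n_rep <- length(unique(apo_wells$replicate %||% 1L))
    apo_qc <- qc_plates(apo_wells, "fraction",
                        positive_role = "non_induced",
                        negative_role = "induced_untreated",
                        threshold = cfg$qc_threshold,
                        replicates = n_rep, adjusted = TRUE, mode = cfg$z_mode)
    cys_assay <- assay_z(cys_wells, "cystine_nmol",
                         positive_role = "cysteamine", negative_role = "vehicle")
    apo_assay <- assay_z(apo_wells, "fraction",
                         positive_role = "non_induced",
                         negative_role = "induced_untreated",
                         replicates = n_rep, adjusted = TRUE, mode = cfg$z_mode)
    list(cystine = cys_qc, apoptosis = apo_qc,
         cystine_assay_z = cys_assay$z, apoptosis_assay_z = apo_assay$z)
  })
  utils::write.table(qc$cystine, out("qc_cystine.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qc$apoptosis, out("qc_apoptosis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  failed_cys <- qc$cystine$plate_id[!qc$cystine$passed]
  failed_apo <- qc$apoptosis$plate_id[!qc$apoptosis$passed]
  cys_wells <- cys_wells[!cys_wells$plate_id %in% failed_cys, ]
  apo_wells <- apo_wells[!apo_wells$plate_id %in% failed_apo, ]
  manifest$qc <- list(
    cystine_assay_z = qc$cystine_assay_z,
    apoptosis_assay_z = qc$apoptosis_assay_z,
    cystine_plates = nrow(qc$cystine), cystine_failed = as.list(failed_cys),
    apoptosis_plates = nrow(qc$apoptosis), apoptosis_failed = as.list(failed_apo)
  )

  # --- screens --------------------------------------------------------------
  cys_hits <- run_stage("cystine", {
    call_cystine_hits(screen_cystine(cys_wells), cfg$cystine_threshold)
  })
  apo_hits <- run_stage("apoptosis", {
    call_apoptosis_hits(screen_apoptosis(apo_wells), cfg$apoptosis_threshold)
  })
  write_screen_tsv(cys_hits, out("cystine_hits.tsv"))
  write_screen_tsv(apo_hits, out("apoptosis_hits.tsv"))
  manifest$screens <- list(
    n_cystine_hits = sum(cys_hits$hit),
    n_apoptosis_hits = sum(apo_hits$hit)
  )

  # --- crossing + dose-response --------------------------------------------
  crossed <- run_stage("cross", cross_screens(cys_hits, apo_hits))
  exclude <- cfg$exclude %||% (if (synthetic) study$exclude else character())
  leads <- setdiff(crossed, exclude)
  manifest$cross <- list(n_crossed = length(crossed),
                         crossed = as.list(crossed),
                         excluded = as.list(intersect(crossed, exclude)),
                         leads = as.list(leads))

  fits <- run_stage("dose-response", {
    if (synthetic && length(leads)) {
      dr <- study$dose_response$data
      fit_dose_response(dr[dr$compound_id %in% leads, ])
    } else NULL
  })
  if (!is.null(fits)) {
    fit_tab <- do.call(rbind, lapply(names(fits), function(id) {
      f <- fits[[id]]
      data.frame(compound_id = id, top = f$a, bottom = f$d, ec50_uM = f$c,
                 hill = f$b, rss = f$rss, converged = f$converged,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(fit_tab, out("dose_response_fits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$dose_response <- list(
      n_fitted = nrow(fit_tab), n_converged = sum(fit_tab$converged),
      median_ec50_uM = stats::median(fit_tab$ec50_uM[fit_tab$converged])
    )
  }

  # --- differential expression ---------------------------------------------
  deg <- run_stage("dge", {
    if (!is.null(cfg$deg_tsv)) {
      tab <- read_deg_table(cfg$deg_tsv)
      label_degs(tab, cfg$fdr_cut, cfg$lfc_cut)
    } else if (synthetic) {
      run_dge(study$counts$counts, study$counts$samples$group,
              reference = "wild_type", fdr_cut = cfg$fdr_cut,
              lfc_cut = cfg$lfc_cut)
    } else {
      counts <- read_counts_tsv(cfg$counts_tsv)
      sheet <- read_sample_sheet(cfg$sample_sheet)
      grp <- sheet$group[match(colnames(counts), sheet$sample)]
      run_dge(counts, grp, fdr_cut = cfg$fdr_cut, lfc_cut = cfg$lfc_cut)
    }
  })
  write_deg_tsv(deg, out("deg.tsv"))
  manifest$dge <- deg_summary(deg)

  # --- reversal voting ------------------------------------------------------
  reversal <- run_stage("reversal", {
    sigs <- if (synthetic) {
      lapply(study$prls$prls, tails_to_signature, tail_size = cfg$tail_size)
    } else if (!is.null(cfg$prl_files)) {
      rls <- lapply(seq_along(cfg$prl_files), function(i) {
        read_ranked_list(cfg$prl_files[i],
                         compound_id = names(cfg$prl_files)[i] %||% NULL)
      })
      lapply(rls, tails_to_signature, tail_size = cfg$tail_size)
    } else {
      stopf("no ranked-list inputs supplied")
    }
    vote_reversal(deg, unname(sigs), k = cfg$k)
  })
  utils::write.table(reversal, out("reversal_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$reversal <- attr(reversal, "counts")

  # --- enrichment -----------------------------------------------------------
  enr <- run_stage("enrich", {
    sets <- if (synthetic) study$gene_sets
            else if (!is.null(cfg$gmt)) read_gmt(cfg$gmt)
            else NULL
    if (is.null(sets) || !nrow(reversal)) return(NULL)
    collection <- suppressMessages(gene_set_collection(sets, universe = deg$gene))
    res <- suppressMessages(hypergeom_enrich(reversal$gene, collection))
    clusters <- summarize_clusters(res, collection)
    list(results = res, clusters = clusters)
  })
  if (!is.null(enr)) {
    utils::write.table(enr$results, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$enrichment <- list(
      n_sets_tested = nrow(enr$results),
      n_significant = sum(enr$results$fdr < 0.05),
      n_clusters = if (nrow(enr$clusters)) max(enr$clusters$cluster) else 0L,
      top_set = if (nrow(enr$results)) enr$results$set_id[1] else NA_character_
    )
  }

  manifest$outputs <- as.list(list.files(cfg$out_dir, full.names = FALSE))
  write_manifest(manifest, out("manifest.json"))
  invisible(manifest)
}
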