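# Readers and writers for the pipeline's plain-text formats. Every table is
# written with a schema-version comment line so files can evolve without
# breaking old readers; readers skip '#' comment lines.

SCHEMA_PREFIX <- "# cystirep-schema:"

write_schema_table <- function(df, path, schema, sep) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s %s/1", SCHEMA_PREFIX, schema), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_schema_table <- function(path, sep) {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read plate well tables (CSV)
#'
#' @param wells Well-level data frame (see [simulate_screen()]).
#' @param path File path.
#' @return `read_plate_csv()` returns the well table; the writer returns the
#'   path invisibly.
#' @export
write_plate_csv <- function(wells, path) {
  write_schema_table(wells, path, "plate-wells", sep = ",")
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  w <- read_schema_table(path, sep = ",")
  need <- c("plate_id", "well", "compound_id", "role")
  miss <- setdiff(need, names(w))
  if (length(miss)) stopf("plate CSV lacks column(s): %s", paste(miss, collapse = ", "))
  w
}

#' Write / read per-compound screen results (TSV)
#'
#' @param results Hit table from [call_cystine_hits()] or
#'   [call_apoptosis_hits()].
#' @param path File path.
#' @export
write_screen_tsv <- function(results, path) {
  write_schema_table(results, path, "screen-result", sep = "\t")
}

#' @rdname write_screen_tsv
#' @export
read_screen_tsv <- function(path) {
  read_schema_table(path, sep = "\t")
}

#' Write / read a gene x sample count matrix (TSV)
#'
#' Genes are rows; the first column is `gene`, remaining columns are sample
#' ids.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path File path.
#' @return `read_counts_tsv()` returns the integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_schema_table(df, path, "counts", sep = "\t")
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read_schema_table(path, sep = "\t")
  if (names(df)[1] != "gene") stopf("counts TSV must start with a 'gene' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  m
}

#' Write / read a sample sheet (CSV: sample, group)
#' @param samples Data frame with `sample` and `group` columns.
#' @param path File path.
#' @export
write_sample_sheet <- function(samples, path) {
  write_schema_table(samples, path, "sample-sheet", sep = ",")
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  s <- read_schema_table(path, sep = ",")
  if (!all(c("sample", "group") %in% names(s))) {
    stopf("sample sheet needs 'sample' and 'group' columns")
  }
  s
}

#' Write / read a DEG table (TSV)
#'
#' The reader accepts precomputed tables (columns `gene`, `log2fc`, `p`,
#' `fdr`, optional `direction`), so users with an externally derived
#' differential-expression table can feed it to the voting stage directly.
#'
#' @param tab DEG table.
#' @param path File path.
#' @export
write_deg_tsv <- function(tab, path) {
  write_schema_table(tab, path, "deg", sep = "\t")
}

#' @rdname write_deg_tsv
#' @export
read_deg_table <- function(path) {
  tab <- read_schema_table(path, sep = "\t")
  need <- c("gene", "log2fc", "p", "fdr")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("DEG TSV lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene)) stopf("duplicate gene ids in DEG table")
  tab
}

#' Write / read ranked-list files (two columns: rank, gene)
#'
#' Ranked lists are total orders: the reader rejects duplicated genes,
#' duplicated (tied) ranks, and non-contiguous rank values.
#'
#' @param rl A [ranked_list()].
#' @param path File path.
#' @export
write_ranked_list <- function(rl, path) {
  df <- data.frame(rank = seq_along(rl$genes), gene = rl$genes,
                   stringsAsFactors = FALSE)
  write_schema_table(df, path, "ranked-list", sep = "\t")
}

#' @rdname write_ranked_list
#' @param compound_id Compound id for the returned list; defaults to the
#'   file name without extension.
#' @export
read_ranked_list <- function(path, compound_id = NULL) {
  df <- read_schema_table(path, sep = "\t")
  if (!all(c("rank", "gene") %in% names(df))) {
    stopf("ranked-list file needs 'rank' and 'gene' columns")
  }
  if (anyDuplicated(df$rank)) stopf("tied ranks in '%s'; ranked lists must be total orders", path)
  if (!identical(sort(as.integer(df$rank)), seq_len(nrow(df)))) {
    stopf("ranks in '%s' are not contiguous from 1", path)
  }
  id <- compound_id %||% sub("\\.[^.]*$", "", basename(path))
  ranked_list(id, df$gene[order(df$rank)])
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set id, description, then member genes.
#'
#' @param path File path.
#' @return `read_gmt()` returns a list of sets (`id`, `name`, `genes`) ready
#'   for [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("GMT file '%s' is empty", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("GMT line with fewer than 3 fields in '%s'", path)
    list(id = f[1], name = f[2], genes = f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "id")
  sets
}

#' @rdname read_gmt
#' @param sets List of sets (`id`, `name`, `genes`).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$id, s$name %||% s$id, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a machine-readable run manifest (JSON)
#'
#' @param manifest Named list of stage summaries and output paths.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
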