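#' Median-of-ratios size factors
#'
#' Library-size normalization for count matrices: each sample's factor is the
#' median across genes of the ratio between its counts and a pseudo-reference
#' sample (the per-gene geometric mean), computed over genes expressed in all
#' samples. Multiplying one sample's counts by a constant multiplies its
#' factor by the same constant; for symmetric designs the geometric mean of
#' the factors is approximately 1.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  expressed <- rowSums(counts > 0) == ncol(counts)
  if (!any(expressed)) {
    stopf("no gene has non-zero counts in every sample; median-of-ratios undefined (consider a pseudo-reference over positive counts)")
  }
  lc <- log(counts[expressed, , drop = FALSE])
  ref <- rowMeans(lc)  # log geometric mean
  sf <- apply(lc, 2, function(x) exp(stats::median(x - ref)))
  if (any(!is.finite(sf)) || any(sf <= 0)) stopf("size factors are not all positive")
  sf
}

as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stopf("counts must be numeric")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("counts must be non-negative integers")
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids in counts")
  counts
}

#' Two-group negative-binomial Wald test
#'
#' A deliberately simple NB test for a two-group comparison: counts are
#' normalized by [size_factors()], the per-gene dispersion is estimated by
#' pooled method of moments (the NB variance is `mu + alpha * mu^2`) and
#' moderated toward the genome-wide median dispersion with `prior_df`
#' pseudo-degrees of freedom, with a Poisson floor on the modelled variance.
#' The log2 fold change of group means (with a pseudo-count) is tested with
#' a Wald statistic referred to a t distribution on
#' `n1 + n2 - 2 + prior_df` degrees of freedom. Genes with all-zero counts
#' get `p = 1` and `log2fc = 0`. There is no mean-dispersion trend fitting
#' and no independent filtering.
#'
#' The moderation is essential at small replicate numbers: with a purely
#' gene-wise dispersion on 4 residual degrees of freedom, even very large
#' Wald statistics cannot reach the small p values that genome-wide FDR
#' control requires, so strongly regulated genes would be unrecoverable at
#' n = 3 per group. Sharing dispersion information across genes is what
#' every NB differential-expression framework does for the same reason.
#'
#' @param counts Genes x samples count matrix.
#' @param group Character/factor of length `ncol(counts)` with exactly two
#'   levels and >= 2 samples per level.
#' @param reference Group level used as the denominator of the fold change;
#'   default the first level (first unique value for character input). The
#'   reported `log2fc` is the other group over the reference.
#' @param sf Optional size factors; computed from `counts` when `NULL`.
#' @param pseudo Pseudo-count added to each group's normalized mean before
#'   taking the log ratio (default 0.5).
#' @param prior_df Pseudo-degrees of freedom of the dispersion moderation
#'   (default 10): the gene-wise estimate is averaged with the genome-wide
#'   median dispersion, weighted `(n1 + n2 - 2) : prior_df`.
#' @return Data frame with `gene`, `base_mean`, `log2fc`, `p`.
#' @export
nb_wald_test <- function(counts, group, reference = NULL, sf = NULL,
                         pseudo = 0.5, prior_df = 10) {
  counts <- as_count_matrix(counts)
  if (length(group) != ncol(counts)) stopf("'group' length must equal ncol(counts)")
  levels_ <- if (is.factor(group)) levels(droplevels(group)) else unique(as.character(group))
  group <- as.character(group)
  if (length(levels_) != 2L) stopf("exactly two groups required, got %d", length(levels_))
  reference <- reference %||% levels_[1]
  if (!reference %in% levels_) stopf("reference '%s' is not a group level", reference)
  other <- setdiff(levels_, reference)
  i1 <- which(group == reference)
  i2 <- which(group == other)
  if (length(i1) < 2L || length(i2) < 2L) {
    stopf("each group needs >= 2 samples (dispersion not estimable)")
  }
  sf <- sf %||% size_factors(counts)
  assert_number(pseudo, "pseudo", lower = 0)

  y <- sweep(counts, 2, sf, "/")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  v_pool <- (rowSums((y[, i1, drop = FALSE] - m1)^2) +
             rowSums((y[, i2, drop = FALSE] - m2)^2)) / (n1 + n2 - 2)

  # modelled per-observation variance on the normalized scale:
  # Poisson part mu * E[1/s] plus overdispersion alpha * mu^2, with the
  # pooled empirical variance as the method-of-moments source.
  inv1 <- mean(1 / sf[i1]); inv2 <- mean(1 / sf[i2]); inv <- mean(1 / sf)
  mbar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- ifelse(mbar > 0, pmax((v_pool - mbar * inv) / mbar^2, 0), 0)

  # moderate the noisy gene-wise estimate toward the genome-wide median
  assert_number(prior_df, "prior_df", lower = 0)
  resid_df <- n1 + n2 - 2
  eligible <- mbar > 1  # dispersion is uninformative for near-empty genes
  alpha_prior <- if (any(eligible)) stats::median(alpha[eligible]) else 0
  alpha <- (resid_df * alpha + prior_df * alpha_prior) / (resid_df + prior_df)

  var1 <- pmax(m1 * inv1 + alpha * m1^2, m1 * inv1)
  var2 <- pmax(m2 * inv2 + alpha * m2^2, m2 * inv2)
  log2fc <- log2((m2 + pseudo) / (m1 + pseudo))
  se2 <- (var1 / n1 / (m1 + pseudo)^2 + var2 / n2 / (m2 + pseudo)^2) / log(2)^2
  w <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p <- 2 * stats::pt(-abs(w), df = resid_df + prior_df)

  zero <- mbar == 0
  log2fc[zero] <- 0
  p[zero] <- 1

  data.frame(gene = rownames(counts), base_mean = mbar,
             log2fc = log2fc, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector. This is the
#' standard BH procedure (delegated to [stats::p.adjust()]) with input
#' validation.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted values (FDR) in \[0, 1\], same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stopf("'p' must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Label differential-expression directions
#'
#' A gene is `up` when `fdr < fdr_cut` and `log2fc >= lfc_cut`, `down` when
#' `fdr < fdr_cut` and `log2fc <= -lfc_cut`, otherwise `ns`. The FDR cut is
#' strict, the fold-change cut boundary-inclusive.
#'
#' @param tab Data frame with `gene`, `log2fc`, `p`, `fdr`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param lfc_cut Absolute log2-fold-change threshold (default 1).
#' @return `tab` with a `direction` column added.
#' @seealso [deg_summary()] for the partition counts.
#' @export
label_degs <- function(tab, fdr_cut = 0.05, lfc_cut = 1) {
  need <- c("gene", "log2fc", "p", "fdr")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("DEG table lacks column(s): %s", paste(miss, collapse = ", "))
  assert_number(fdr_cut, "fdr_cut", lower = 0, upper = 1)
  assert_number(lfc_cut, "lfc_cut", lower = 0)
  sig <- tab$fdr < fdr_cut
  tab$direction <- "ns"
  tab$direction[sig & tab$log2fc >= lfc_cut] <- "up"
  tab$direction[sig & tab$log2fc <= -lfc_cut] <- "down"
  attr(tab, "thresholds") <- list(fdr_cut = fdr_cut, lfc_cut = lfc_cut)
  tab
}

#' Summary counts of a labelled DEG table
#'
#' @param tab Output of [label_degs()].
#' @return List with `total_significant` (FDR below the cut), `up`, `down`,
#'   and `significant_below_lfc` (significant but under the fold-change cut);
#'   the first equals the sum of the other three.
#' @export
deg_summary <- function(tab) {
  th <- attr(tab, "thresholds") %||% list(fdr_cut = 0.05, lfc_cut = 1)
  sig <- tab$fdr < th$fdr_cut
  up <- sum(tab$direction == "up")
  down <- sum(tab$direction == "down")
  list(total_significant = sum(sig), up = up, down = down,
       significant_below_lfc = sum(sig) - up - down)
}

#' Full differential-expression step
#'
#' Convenience wrapper: size factors, NB Wald test, BH adjustment, direction
#' labels.
#'
#' @inheritParams nb_wald_test
#' @inheritParams label_degs
#' @return Labelled DEG table (`gene`, `base_mean`, `log2fc`, `p`, `fdr`,
#'   `direction`).
#' @export
run_dge <- function(counts, group, reference = NULL, fdr_cut = 0.05,
                    lfc_cut = 1, pseudo = 0.5) {
  tab <- nb_wald_test(counts, group, reference = reference, pseudo = pseudo)
  tab$fdr <- bh_adjust(tab$p)
  label_degs(tab, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
}
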