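# fixtures and independent oracles used across test files

# one plate of wells with given control readouts and compound readouts
make_cystine_plate <- function(compound_values, vehicle = c(6, 6),
                               cysteamine = c(0.6, 0.6), protein = 0.5,
                               plate_id = "P01") {
  n_cpd <- length(compound_values)
  data.frame(
    plate_id = plate_id,
    well = sprintf("W%02d", seq_len(length(vehicle) + length(cysteamine) + n_cpd)),
    compound_id = c(rep(NA, length(vehicle) + length(cysteamine)),
                    names(compound_values) %||% sprintf("C%02d", seq_len(n_cpd))),
    role = c(rep("vehicle", length(vehicle)), rep("cysteamine", length(cysteamine)),
             rep("compound", n_cpd)),
    cystine_nmol = c(vehicle, cysteamine, unname(compound_values)) * protein,
    protein_mg = protein,
    stringsAsFactors = FALSE
  )
}

# a labelled DEG table from direction assignments
make_deg <- function(up = character(), down = character(), ns = character()) {
  data.frame(
    gene = c(up, down, ns),
    log2fc = c(rep(2, length(up)), rep(-2, length(down)), rep(0, length(ns))),
    p = 1e-6, fdr = c(rep(1e-4, length(up) + length(down)), rep(1, length(ns))),
    direction = c(rep("up", length(up)), rep("down", length(down)),
                  rep("ns", length(ns))),
    stringsAsFactors = FALSE
  )
}

make_signature <- function(id, up = character(), down = character()) {
  compound_signature(id, up_set = up, down_set = down)
}

# n values with exactly the requested sample mean and SD
rnorm_fixed <- function(n, mean, sd) {
  v <- seq_len(n)
  (v - mean(v)) / stats::sd(v) * sd + mean
}

# independent brute-force BH step-up (the oracle the package must match)
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# exhaustive reversal voting by explicit enumeration over gene x signature
vote_brute_force <- function(deg, signatures, k) {
  out <- list()
  for (i in seq_len(nrow(deg))) {
    g <- deg$gene[i]; dir <- deg$direction[i]
    if (dir == "ns") next
    side <- if (dir == "up") "down_set" else "up_set"
    supporters <- character()
    for (sg in signatures) {
      if (g %in% sg[[side]]) supporters <- c(supporters, sg$compound_id)
    }
    if (length(supporters) >= k) {
      out[[length(out) + 1]] <- data.frame(
        gene = g, disease_direction = dir,
        supporting_compounds = length(supporters),
        compounds = paste(sort(supporters), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), disease_direction = character(),
                      supporting_compounds = integer(), compounds = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$disease_direction, -res$supporting_compounds, res$gene), ,
      drop = FALSE]
}

# exact upper-tail hypergeometric by combinatorial enumeration
hyper_tail_brute_force <- function(x, K, M, n) {
  i <- seq(x, min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

expect_same_rows <- function(a, b) {
  rownames(a) <- NULL; rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
}
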