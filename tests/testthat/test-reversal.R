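test_that("ranked lists must be permutations and tails must fit", {
  expect_error(ranked_list("D1", c("a", "b", "a")), "permutation")
  rl <- ranked_list("D1", letters[1:10])
  sig <- tails_to_signature(rl, 2)
  expect_equal(sig$up_set, c("a", "b"))
  expect_equal(sig$down_set, c("i", "j"))
  half <- tails_to_signature(rl, 5)
  expect_setequal(c(half$up_set, half$down_set), letters[1:10])
  expect_error(tails_to_signature(rl, 6), "too large")
  expect_error(compound_signature("D1", up_set = c("a", "b"), down_set = c("b")),
               "overlap")
})

test_that("mean-rank aggregation with lexicographic tie-break", {
  l1 <- ranked_list("D1", c("A", "B", "C"))
  l2 <- ranked_list("D2", c("C", "B", "A"))
  agg <- aggregate_ranked_lists(list(l1, l2))
  expect_equal(agg$genes, c("A", "B", "C"))  # all mean ranks 2: tie-break

  same <- aggregate_ranked_lists(list(l1, ranked_list("D3", c("A", "B", "C"))))
  expect_equal(same$genes, l1$genes)
  single <- aggregate_ranked_lists(list(l1))
  expect_equal(single$genes, l1$genes)

  expect_error(aggregate_ranked_lists(list(l1, ranked_list("D4", c("A", "B", "X")))),
               "same genome")
})

test_that("voting selects opposite-direction genes supported by >= k compounds", {
  deg <- make_deg(up = c("u1", "u2", "u3"), down = c("d1"), ns = c("n1"))
  sigs <- list(
    make_signature("c1", up = c("d1", "u3", "n1"), down = c("u1", "u2")),
    make_signature("c2", up = c("d1", "u3"), down = c("u1", "u2")),
    make_signature("c3", up = c("d1", "u3"), down = c("u1", "u2")),
    make_signature("c4", up = c("d1", "u3"), down = c("u1")),
    make_signature("c5", up = c("u3"), down = c("x1"))
  )
  out <- vote_reversal(deg, sigs, k = 4)
  # u1: down-voted by 4/5 -> selected; u2: 3/5 -> not; d1: up-voted by 4 -> selected
  # u3: up-voted by 5 (same direction as disease) -> never selected
  expect_setequal(out$gene, c("u1", "d1"))
  expect_equal(out$supporting_compounds[out$gene == "u1"], 4L)
  expect_equal(out$compounds[out$gene == "u1"], "c1,c2,c3,c4")
  counts <- attr(out, "counts")
  expect_equal(counts$disease_up_reversed, 1L)
  expect_equal(counts$disease_down_reversed, 1L)

  expect_error(vote_reversal(deg, sigs, k = 0), ">= 1")
  expect_error(vote_reversal(deg, sigs, k = 6), "exceeds")
})

test_that("voting equals the exhaustive brute-force oracle on random instances", {
  set.seed(77)
  genome <- sprintf("g%02d", 1:50)
  for (trial in 1:200) {
    dirs <- sample(c("up", "down", "ns"), 50, replace = TRUE)
    deg <- make_deg(up = genome[dirs == "up"], down = genome[dirs == "down"],
                    ns = genome[dirs == "ns"])
    sigs <- lapply(1:5, function(j) {
      picks <- sample(genome, 20)
      make_signature(paste0("c", j), up = picks[1:10], down = picks[11:20])
    })
    k <- sample(1:5, 1)
    got <- vote_reversal(deg, sigs, k = k)
    want <- vote_brute_force(deg, sigs, k = k)
    expect_same_rows(got, as.data.frame(want))
  }
})

test_that("selection is monotone in k and tail_size, and order-invariant", {
  genome <- sprintf("G%05d", 1:300)
  planted <- data.frame(gene = c("G00001", "G00002"),
                        disease_direction = c("up", "down"),
                        support = c(5, 4))
  sim <- simulate_prls(prl_sim_config(genome, n_compounds = 5,
                                      planted_reversers = planted,
                                      tail_size = 30, seed = 15))
  deg <- make_deg(up = "G00001", down = "G00002")
  sigs <- lapply(sim$prls, tails_to_signature, tail_size = 30)

  sel_k4 <- vote_reversal(deg, unname(sigs), k = 4)$gene
  sel_k2 <- vote_reversal(deg, unname(sigs), k = 2)$gene
  expect_true(all(sel_k4 %in% sel_k2))  # lowering k never drops a gene

  big_sigs <- lapply(sim$prls, tails_to_signature, tail_size = 60)
  sel_big <- vote_reversal(deg, unname(big_sigs), k = 4)$gene
  expect_true(all(sel_k4 %in% sel_big))  # widening tails never drops a gene

  shuffled <- unname(sigs)[c(3, 1, 5, 2, 4)]
  expect_equal(vote_reversal(deg, shuffled, k = 4),
               vote_reversal(deg, unname(sigs), k = 4),
               ignore_attr = TRUE)
})
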