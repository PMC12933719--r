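test_that("partition enumeration matches the topology shapes on offer", {
  sp <- mini_space()
  # linear 3-atom query, 2-node chain: one partition per cuttable bond
  parts <- enumerate_partitions("CCO", sp)
  expect_length(parts, 2L)
  expect_true(all(vapply(parts, function(p) length(p$classes), integer(1))
                  == 2L))
  # 1-node graph: the trivial partition, no cuts
  single <- single_node_space(c("CCO", "CCC"))
  p1 <- enumerate_partitions("CCCCO", single)
  expect_length(p1, 1L)
  expect_length(p1[[1]]$cut_bonds, 0L)
  # benzene against a 2-node chain: nothing to cut
  expect_length(enumerate_partitions("c1ccccc1", sp), 0L)
  # aromatic and ring bonds are never cut
  parts2 <- enumerate_partitions("Cc1ccccc1CC", sp)
  cut_orders <- unlist(lapply(parts2, function(p) {
    parse_smiles("Cc1ccccc1CC")$bonds$order[p$cut_bonds]
  }))
  expect_true(all(cut_orders == "single"))
  expect_error(enumerate_partitions("CC[*:1]", sp), "placeholder-free")
})

test_that("matching enforces topology, connectivity and the size filter", {
  # node X fragments 2-4 heavy atoms, node Y 6-8: a (3,7) split fits one way
  sp <- space_from_list(list(name = "sz", graphs = list(list(
    id = "g", nodes = list(
      list(id = "x", fragments = list("CC[*:1]", "CCCC[*:1]")),
      list(id = "y", fragments = list("[*:1]CCCCCC", "[*:1]CCCCCCCC"))),
    edges = list(list(a = "x", b = "y", linker_a = "1", linker_b = "1",
                      kind = "single_bond", order = "single"))))))
  q <- parse_smiles("CCCCCCCCCC") # 10 atoms
  parts <- enumerate_partitions(q, sp)
  sizes <- lapply(parts, function(p) vapply(p$classes, `[[`, integer(1),
                                            "heavy"))
  p37 <- parts[[which(vapply(sizes, function(s) setequal(s, c(3, 7)),
                             logical(1)))[1]]]
  # under slack 5 both bijections pass (|3-6| = |7-4| = 3); hand-checked
  m <- match_partition(p37, sp$graphs[[1]], slack = 5)
  expect_length(m, 2L)
  # slack 2 admits only the size-faithful orientation 3 -> x, 7 -> y
  m2 <- match_partition(p37, sp$graphs[[1]], slack = 2)
  expect_length(m2, 1L)
  cls_sizes <- vapply(p37$classes, `[[`, integer(1), "heavy")
  expect_identical(m2[[1]]$assignment[order(cls_sizes)], c("x", "y"))

  # a class 5 atoms beyond the largest fragment fails the slack-5 filter
  sp2 <- space_from_list(list(name = "sz2", graphs = list(list(
    id = "g", nodes = list(
      list(id = "x", fragments = list("CC[*:1]")),
      list(id = "y", fragments = list("[*:1]CCCCC"))),
    edges = list(list(a = "x", b = "y", linker_a = "1", linker_b = "1",
                      kind = "single_bond", order = "single"))))))
  q2 <- parse_smiles(paste(rep("C", 14), collapse = "")) # 12 + 2 split
  parts2 <- enumerate_partitions(q2, sp2)
  p212 <- parts2[[which(vapply(parts2, function(p) {
    setequal(vapply(p$classes, `[[`, integer(1), "heavy"), c(2, 12))
  }, logical(1)))[1]]]
  expect_length(match_partition(p212, sp2$graphs[[1]], slack = 5), 0L)

  # symmetric 2-node graph with identical nodes doubles the matchings
  sp3 <- space_from_list(list(name = "sym", graphs = list(list(
    id = "g", nodes = list(
      list(id = "u", fragments = list("CCC[*:1]")),
      list(id = "v", fragments = list("CCC[*:1]"))),
    edges = list(list(a = "u", b = "v", linker_a = "1", linker_b = "1",
                      kind = "single_bond", order = "single"))))))
  q3 <- parse_smiles("CCCCCC")
  parts3 <- enumerate_partitions(q3, sp3)
  p33 <- parts3[[which(vapply(parts3, function(p) {
    setequal(vapply(p$classes, `[[`, integer(1), "heavy"), c(3, 3))
  }, logical(1)))[1]]]
  expect_length(match_partition(p33, sp3$graphs[[1]], slack = 5), 2L)
})

test_that("fragment ranking swaps under weighting when the mark decides", {
  # fCSFP2.2 on query CCO (features CC, CO), marked substructure = the C-O
  # bond. Fragment CC shares only CC (unweighted 1/2); fragment OCO shares
  # only CO (unweighted 1/3). With k = 10 on the marked CO feature:
  # CC -> 1/(1 + 10) = 1/11, OCO -> 10/(1 + 10*2) = 10/21, so they swap.
  node <- single_node_space(c("CC", "OCO"))$graphs[[1]]$nodes[[1]]
  q <- parse_smiles("CCO")
  cls <- list(atoms = 1:3, capped = q, map = 1:3, heavy = 3L, n_cuts = 0L)
  unw <- score_node_fragments(cls, node, search_config(descriptor = "csfp2.2"))
  expect_equal(unw$frag, c("n1#1", "n1#2"))
  expect_equal(unw$score, c(1 / 2, 1 / 3))
  wgt <- score_node_fragments(cls, node,
                              search_config(descriptor = "csfp2.2", k = 10),
                              marked_atoms = c(2L, 3L))
  expect_equal(wgt$frag, c("n1#2", "n1#1"))
  expect_equal(wgt$score, c(10 / 21, 1 / 11))
  # no marked atoms in the class: weighted equals unweighted
  same <- score_node_fragments(cls, node,
                               search_config(descriptor = "csfp2.2", k = 10),
                               marked_atoms = integer(0))
  expect_equal(same$score, unw$score)
})

test_that("adjusted atom counts follow k / c with the unweighted floor", {
  expect_equal(adjusted_atom_count(TRUE, search_config(k = 6, correction = 3)),
               2)
  expect_equal(adjusted_atom_count(FALSE, search_config(k = 6)), 1)
  expect_equal(adjusted_atom_count(TRUE, search_config(k = 1)), 1)
  expect_equal(adjusted_atom_count(TRUE, search_config(k = 15,
                                                       correction = 3)), 5)
  expect_equal(adjusted_atom_count(c(TRUE, FALSE),
                                   search_config(k = 9, correction = 3)),
               c(3, 1))
})

stub_matching <- function(graph, ranked_scores, shares,
                          node_ids = paste0("n", seq_along(ranked_scores))) {
  ranked <- lapply(seq_along(ranked_scores), function(i) {
    s <- ranked_scores[[i]]
    data.frame(frag = sprintf("%s#%d", node_ids[i], seq_along(s)),
               score = s, stringsAsFactors = FALSE)
  })
  list(graph = graph, assignment = node_ids, partition = NULL,
       ranked = ranked, shares = shares)
}

test_that("combine_top returns the exact best combinations lazily", {
  sm <- stub_matching("g", list(c(0.9, 0.8), c(0.7, 0.1)), c(0.5, 0.5))
  pool <- combine_top(list(sm), search_config(), pool_size = 2)
  expect_equal(vapply(pool, `[[`, numeric(1), "score"), c(0.80, 0.75))
  # degenerate single-node matching: pool = top fragments by partial score
  sm1 <- stub_matching("g", list(c(0.9, 0.5, 0.4)), 1)
  pool1 <- combine_top(list(sm1), search_config(), pool_size = 2)
  expect_equal(vapply(pool1, `[[`, numeric(1), "score"), c(0.9, 0.5))
  # brute-force equality on random instances, including across matchings
  set.seed(7)
  for (i in 1:50) {
    n_m <- sample(1:3, 1)
    sms <- lapply(seq_len(n_m), function(mi) {
      m <- sample(1:3, 1)
      shares <- stats::runif(m)
      shares <- shares / sum(shares)
      stub_matching(sample(c("g1", "g2"), 1),
                    lapply(seq_len(m), function(i) {
                      sort(round(stats::runif(sample(1:5, 1)), 2),
                           decreasing = TRUE)
                    }),
                    shares)
    })
    P <- sample(1:12, 1)
    lazy <- combine_top(sms, search_config(), pool_size = P)
    brute <- brute_force_pool(sms, P)
    expect_identical(vapply(lazy, combo_id, character(1)),
                     vapply(brute, combo_id, character(1)))
  }
})

test_that("the adjusted combination score rescues small marked classes", {
  # partition A: classes of 6 (unmarked, partial 0) and 4 (all marked,
  # partial 1.0); partition B: classes of 2 (unmarked, partial 0.5) and 8
  # (4 marked, partial 0.409). Unweighted shares favour B; with k = 6, c = 3
  # each marked atom counts as 2 and A wins. All numbers checked by hand.
  cfg_u <- search_config(k = 1)
  cfg_w <- search_config(k = 6, correction = 3)
  share_of <- function(sizes, marked_per_class, cfg) {
    counts <- mapply(function(sz, mk) {
      sum(adjusted_atom_count(c(rep(TRUE, mk), rep(FALSE, sz - mk)), cfg))
    }, sizes, marked_per_class)
    counts / sum(counts)
  }
  mA <- function(cfg) stub_matching("gA", list(0, 1.0),
                                    share_of(c(6, 4), c(0, 4), cfg),
                                    node_ids = c("a1", "a2"))
  mB <- function(cfg) stub_matching("gB", list(0.5, 0.409),
                                    share_of(c(2, 8), c(0, 4), cfg),
                                    node_ids = c("b1", "b2"))
  top_u <- combine_top(list(mA(cfg_u), mB(cfg_u)), cfg_u, pool_size = 2)
  expect_equal(top_u[[1]]$graph, "gB")
  expect_equal(top_u[[1]]$score, 0.2 * 0.5 + 0.8 * 0.409)
  expect_equal(top_u[[2]]$score, 0.4)
  top_w <- combine_top(list(mA(cfg_w), mB(cfg_w)), cfg_w, pool_size = 2)
  expect_equal(top_w[[1]]$graph, "gA")
  expect_equal(top_w[[1]]$score, (8 / 14) * 1.0)
  expect_equal(top_w[[2]]$score, (2 / 14) * 0.5 + (12 / 14) * 0.409)
})

test_that("share normalization holds for every matching", {
  sp <- precompute_fingerprints(mini_space(), "csfp1.4")
  q <- parse_smiles("CCCC(=O)O")
  cfg <- search_config(k = 8)
  sc <- scored_matchings_for(sp, q, cfg, marked_atoms = c(4L, 5L, 6L))
  for (sm in sc$scored) expect_equal(sum(sm$shares), 1)
})

test_that("global re-rank prefers products completing a cross-border mark", {
  # marked area spans the cut: products that reassemble the full marked
  # O-C-C-N chain must outrank products holding only one half
  sp <- space_from_list(list(name = "border", graphs = list(list(
    id = "g", nodes = list(
      list(id = "L", fragments = list("OCC[*:1]", "OC(C)C[*:1]")),
      list(id = "R", fragments = list("[*:1]NC", "[*:1]CC")))    ,
    edges = list(list(a = "L", b = "R", linker_a = "1", linker_b = "1",
                      kind = "single_bond", order = "single"))))))
  q <- "OCCNC"
  marked <- smarts_marked_atoms(parse_smiles(q), "OCCN")
  expect_length(marked, 4L)
  res <- search_space(sp, q, marking = marked,
                      config = search_config(n_results = 4, k = 20))
  complete <- vapply(res$hits$smiles, function(s) {
    smarts_match(parse_smiles(s), "OCCN")
  }, logical(1))
  # direct weighted-similarity evaluation of two assembled products
  qm <- parse_smiles(q)
  qfp <- compute_fingerprint(qm, "csfp1.4", marked = marked)
  w <- feature_weighting(qfp$marked, k = 20)
  s_complete <- weighted_tanimoto(
    qfp, compute_fingerprint(parse_smiles("OCCNC"), "csfp1.4"), w)
  s_split <- weighted_tanimoto(
    qfp, compute_fingerprint(parse_smiles("OCCCC"), "csfp1.4"), w)
  expect_gt(s_complete, s_split)
  expect_true(complete[1])
  expect_equal(res$hits$score[1], 1) # the query itself is a product
})

test_that("search returns the identity product first, weighted or not", {
  sp <- mini_space()
  res <- search_space(sp, "CCCC(=O)O", config = search_config(n_results = 1))
  expect_equal(res$hits$score, 1)
  expect_identical(canonical_code(parse_smiles(res$hits$smiles)),
                   canonical_code(parse_smiles("CCCC(=O)O")))
  res_w <- search_space(sp, "CCCC(=O)O", smarts = "C(=O)[OH]",
                        config = search_config(n_results = 1, k = 20))
  expect_identical(res_w$hits$smiles, res$hits$smiles)
  expect_equal(res_w$hits$score, 1)
})

test_that("search errors and warnings follow the contracts", {
  sp <- mini_space()
  expect_error(search_space(sp, "CCCC(=O)O", smarts = "[Br]"),
               "zero query atoms")
  expect_warning(r <- search_space(sp, "c1ccccc1"), "no topology graph")
  expect_equal(nrow(r$hits), 0L)
  expect_error(search_config(k = 0.5))
  expect_error(search_config(n_results = 0))
})

test_that("weighted path with k = 1 or empty mark reduces exactly", {
  sp <- precompute_fingerprints(mini_space(), "csfp1.4")
  q <- "CCCC(=O)O"
  base <- search_space(sp, q, config = search_config(n_results = 8))
  k1 <- search_space(sp, q, smarts = "C(=O)[OH]",
                     config = search_config(n_results = 8, k = 1))
  expect_same_hits(base, k1)
  expect_equal(base$hits$combination_score, k1$hits$combination_score)
  # intermediate stages agree too
  cfg <- search_config(n_results = 8)
  marked <- smarts_marked_atoms(parse_smiles(q), "C(=O)[OH]")
  sc_b <- scored_matchings_for(sp, q, cfg)$scored
  sc_m <- scored_matchings_for(sp, q, cfg, marked_atoms = marked)$scored
  for (i in seq_along(sc_b)) {
    expect_equal(sc_b[[i]]$shares, sc_m[[i]]$shares)
    for (j in seq_along(sc_b[[i]]$ranked)) {
      expect_equal(sc_b[[i]]$ranked[[j]], sc_m[[i]]$ranked[[j]])
    }
  }
})

test_that("repeated searches are byte-identical on disk", {
  sp <- small_random_space(5)
  src <- attr(sp, "sources")
  out1 <- tempfile(); out2 <- tempfile()
  cfg <- search_config(n_results = 5, k = 10)
  r1 <- search_space(sp, src$smiles[1], smarts = "[c;R]", config = cfg)
  r2 <- search_space(sp, src$smiles[1], smarts = "[c;R]", config = cfg)
  write_result_tsv(r1, out1)
  write_result_tsv(r2, out2)
  expect_identical(readLines(out1), readLines(out2))
  write_result_json(r1, out1)
  write_result_json(r2, out2)
  expect_identical(readLines(out1), readLines(out2))
})
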