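test_that("the generator builds chain spaces that recover their sources", {
  mols <- bundled_molecules()[1:10]
  spec <- synthetic_space_spec(mols, cuts_per_molecule = 2, seed = 7)
  sp <- generate_space(spec)
  src <- attr(sp, "sources")
  expect_equal(nrow(src), 10L)
  # one 3-node chain (all ten molecules have >= 2 cuttable bonds)
  expect_length(sp$graphs, 1L)
  expect_equal(length(sp$graphs[[1]]$nodes), 3L)
  pool_sizes <- vapply(sp$graphs[[1]]$nodes,
                       function(nd) length(nd$fragments), integer(1))
  expect_equal(space_size(sp), prod(pool_sizes))
  # every source molecule is a product (exact canonical-code lookup)
  prods <- enumerate_products(sp, limit = 5000)
  codes <- vapply(prods, `[[`, character(1), "code")
  expect_true(all(src$code %in% codes))
  # provenances pairwise distinct and the count equals space_size
  expect_length(prods, space_size(sp))
})

test_that("generation is deterministic under the seed", {
  mols <- bundled_molecules()[1:6]
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_space(generate_space(synthetic_space_spec(mols, seed = 3)), f1)
  write_space(generate_space(synthetic_space_spec(mols, seed = 3)), f2)
  write_space(generate_space(synthetic_space_spec(mols, seed = 4)), f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("molecules without cuttable bonds are skipped with a warning", {
  expect_warning(sp <- generate_space(
    synthetic_space_spec(c("c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"), seed = 1)),
    "no cuttable bond")
  expect_equal(nrow(attr(sp, "sources")), 1L)
})

test_that("query cases are stratified and satisfy the pattern constraints", {
  sp <- generate_space(synthetic_space_spec(seed = 11))
  cases <- sample_query_cases(sp, 25, seed = 3)
  expect_equal(nrow(cases), 25L)
  expect_equal(as.integer(table(cases$size)), rep(5L, 5))
  for (i in seq_len(nrow(cases))) {
    q <- parse_smiles(cases$query[i])
    pat <- parse_smarts(cases$smarts[i])
    expect_length(pat$atoms, cases$size[i])
    hits <- smarts_matches(q, pat, first_only = TRUE)
    expect_length(hits, 1L)
    atoms <- hits[[1]]
    # at least one non-carbon atom in the matched substructure
    expect_true(any(q$symbol[atoms] != "C"), label = cases$smarts[i])
    # ring systems are included whole
    for (rs in fragsim:::ring_systems(q)) {
      inter <- intersect(rs, atoms)
      expect_true(length(inter) == 0 || length(inter) == length(rs),
                  label = paste("partial ring in", cases$smarts[i]))
    }
  }
  # determinism of sampling
  cases2 <- sample_query_cases(sp, 25, seed = 3)
  expect_identical(cases, cases2)
})

test_that("preservation score counts SMARTS-matching results", {
  hits <- c(rep("CCOC(=O)C", 7), rep("CCCCC", 3))
  expect_equal(preservation_score(hits, "C(=O)O"), 0.7)
  expect_equal(preservation_score(rep("CCO", 4), "OCC"), 1)
  expect_equal(preservation_score(rep("CCO", 4), "N"), 0)
  expect_warning(v <- preservation_score(character(0), "N"))
  expect_true(is.na(v))
})

test_that("scaffold counting reduces to ring systems plus linkers", {
  expect_identical(bm_scaffold("Cc1ccccc1"), bm_scaffold("c1ccccc1"))
  expect_identical(bm_scaffold("CCCCC"), "")
  expect_equal(scaffold_count(c("c1ccccc1", "Cc1ccccc1")), 1L)
  expect_equal(scaffold_count(c("CCC", "CCCC")), 1L)
  expect_equal(scaffold_count(c("c1ccccc1", "C1CCCCC1", "c1ccncc1")), 3L)
  # linker between rings is retained
  expect_identical(bm_scaffold("c1ccccc1CCc1ccccc1C"),
                   bm_scaffold("c1ccccc1CCc1ccccc1"))
  expect_false(bm_scaffold("c1ccccc1CCc1ccccc1") == bm_scaffold("c1ccccc1"))
})

test_that("pairwise similarity distributions have fixed bins", {
  d <- pairwise_similarity_distribution(c("CCO", "CCO"))
  expect_equal(d$values, 1)
  expect_equal(sum(d$histogram$count), 1L)
  expect_equal(d$histogram$count[20], 1L)
  d2 <- pairwise_similarity_distribution(c("CCCC", "OO"), "csfp2.2")
  expect_equal(d2$values, 0)
  d3 <- pairwise_similarity_distribution(c("CCO", "CCN", "CCC", "CO"))
  expect_length(d3$values, 6L) # k(k-1)/2
  expect_equal(nrow(d3$histogram), 20L)
  expect_error(pairwise_similarity_distribution("CCO"), "at least 2")
})

test_that("run_benchmark applies the two discard rules and aggregates", {
  sp <- generate_space(synthetic_space_spec(bundled_molecules()[1:12],
                                            seed = 5))
  cases <- sample_query_cases(sp, 10, seed = 2)
  rep1 <- run_benchmark(sp, cases, k_values = c(5, 10),
                        config = search_config(n_results = 5))
  expect_s3_class(rep1, "benchmark_report")
  expect_true(all(rep1$results$preservation >= 0 &
                    rep1$results$preservation <= 1))
  expect_true(all(rep1$discarded$reason %in%
                    c("no_match_anywhere", "unweighted_already_perfect",
                      "failed")))
  # kept cases: unweighted not perfect, some search matched
  kept <- unique(rep1$results$case)
  base <- rep1$results[rep1$results$k == 1, ]
  expect_true(all(base$preservation < 1))
  per_case_max <- tapply(rep1$results$preservation, rep1$results$case, max)
  expect_true(all(per_case_max > 0))
  expect_setequal(names(rep1$summary), c("k", "mean_preservation"))
  # scaffold diversity is reported per case and k
  expect_true(all(rep1$results$scaffolds >= 1 & rep1$results$scaffolds <= 5))
  # optional pairwise similarity summaries
  repp <- run_benchmark(sp, cases[seq_len(min(2, nrow(cases))), ],
                        k_values = 5, config = search_config(n_results = 5),
                        pairwise = TRUE)
  if (!is.null(repp$pairwise)) {
    expect_true(all(repp$pairwise$mean >= 0 & repp$pairwise$mean <= 1))
    expect_setequal(names(repp$pairwise), c("case", "k", "mean", "median"))
  }
  # determinism: identical rerun
  rep2 <- run_benchmark(sp, cases, k_values = c(5, 10),
                        config = search_config(n_results = 5))
  expect_identical(rep1$results, rep2$results)
  # empty case list -> empty report
  rep0 <- run_benchmark(sp, cases[0, ], k_values = 5)
  expect_equal(nrow(rep0$results), 0L)
  # report files round-trip deterministically
  c1 <- tempfile(fileext = ".csv"); j1 <- tempfile(fileext = ".json")
  c2 <- tempfile(fileext = ".csv"); j2 <- tempfile(fileext = ".json")
  write_benchmark_report(rep1, c1, j1)
  write_benchmark_report(rep2, c2, j2)
  expect_identical(readLines(c1), readLines(c2))
  expect_identical(readLines(j1), readLines(j2))
})

test_that("weighted search with k = 1 equals the unweighted column", {
  sp <- generate_space(synthetic_space_spec(bundled_molecules()[1:8],
                                            seed = 9))
  cases <- sample_query_cases(sp, 4, seed = 1)
  cfg <- search_config(n_results = 5)
  for (i in seq_len(nrow(cases))) {
    unw <- search_space(sp, cases$query[i], config = cfg)
    k1 <- cfg; k1$k <- 1
    wgt <- search_space(sp, cases$query[i], smarts = cases$smarts[i],
                        config = k1)
    expect_same_hits(unw, wgt)
  }
})

test_that("lipinski check counts the computable criteria", {
  expect_equal(lipinski_violations("CCO"), 0L)
  # a large, donor-rich molecule violates MW and donors
  big <- paste0(paste(rep("NC(O)C(O)", 8), collapse = ""), "N")
  expect_gte(lipinski_violations(big), 2L)
})
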