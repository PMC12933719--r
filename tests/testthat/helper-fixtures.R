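# Shared fixtures and independent oracles.

# a small hand-built 2-node space (16 products)
mini_space <- function() {
  space_from_list(list(name = "mini", graphs = list(
    list(id = "g1",
         nodes = list(
           list(id = "n1", fragments = list("CC[*:1]", "CCC[*:1]",
                                            "CCO[*:1]", "c1ccccc1C[*:1]")),
           list(id = "n2", fragments = list("[*:1]CO", "[*:1]C(=O)O",
                                            "[*:1]CN", "[*:1]C(C)=O"))),
         edges = list(list(a = "n1", b = "n2", linker_a = "1",
                           linker_b = "1", kind = "single_bond",
                           order = "single"))))))
}

# single-node space: products are the fragments themselves
single_node_space <- function(frag_smiles) {
  space_from_list(list(name = "single", graphs = list(
    list(id = "g1",
         nodes = list(list(id = "n1", fragments = as.list(frag_smiles))),
         edges = list()))))
}

# random sparse count fingerprint over a shared feature universe
rand_fp <- function(n_features = 8, universe = sprintf("f%02d", 1:20),
                    max_count = 4, tag = "csfp1.4") {
  feats <- sample(universe, n_features)
  counts <- stats::setNames(sample.int(max_count, n_features, replace = TRUE),
                            feats)
  heavy <- stats::setNames(sample.int(4, n_features, replace = TRUE), feats)
  fragsim:::new_molfp(counts, heavy, tag)
}

# oracle: Tanimoto with marked features replicated k-fold
replicated_tanimoto <- function(a, b, marked, k) {
  rep_fp <- function(fp) {
    counts <- fp$counts
    hit <- names(counts) %in% marked
    counts[hit] <- counts[hit] * k
    fragsim:::new_molfp(counts, fp$heavy, fp$tag)
  }
  tanimoto(rep_fp(a), rep_fp(b))
}

# brute-force oracle for the combination pool: enumerate every index
# combination of every matching, score, and sort with the search tie rule
brute_force_pool <- function(scored_matchings, pool_size) {
  entries <- list()
  for (mi in seq_along(scored_matchings)) {
    sm <- scored_matchings[[mi]]
    sizes <- vapply(sm$ranked, nrow, integer(1))
    grid <- do.call(expand.grid, lapply(sizes, seq_len))
    for (r in seq_len(nrow(grid))) {
      ix <- as.integer(grid[r, ])
      entries[[length(entries) + 1L]] <- fragsim:::combo_entry(sm, mi, ix)
    }
  }
  ord <- order(
    -vapply(entries, `[[`, numeric(1), "score"),
    vapply(entries, `[[`, character(1), "graph"),
    vapply(entries, `[[`, character(1), "fragkey"),
    vapply(entries, `[[`, numeric(1), "matching"))
  utils::head(entries[ord], pool_size)
}

combo_id <- function(e) {
  paste(e$matching, paste(e$ix, collapse = ","), signif(e$score, 12))
}

# full internal pipeline up to scored matchings, mirroring search_space
scored_matchings_for <- function(space, query, cfg, marked_atoms = integer(0)) {
  if (is.character(query)) query <- parse_smiles(query)
  if (is.null(space$fp_cache[[cfg$descriptor]])) {
    space <- precompute_fingerprints(space, cfg$descriptor)
  }
  parts <- enumerate_partitions(query, space)
  matchings <- list()
  for (part in parts) {
    for (g in space$graphs) {
      matchings <- c(matchings, match_partition(part, g,
                                                slack = cfg$size_slack))
    }
  }
  list(space = space, query = query,
       scored = fragsim:::score_matchings(matchings, space, cfg,
                                          marked_atoms, query))
}

# random small synthetic space from a seeded subset of bundled molecules
small_random_space <- function(seed, n_sources = 4) {
  set.seed(seed)
  mols <- bundled_molecules()
  pick <- sample(mols, n_sources)
  generate_space(synthetic_space_spec(pick, cuts_per_molecule = 2,
                                      seed = seed))
}

expect_same_hits <- function(a, b) {
  expect_equal(a$hits$smiles, b$hits$smiles)
  expect_equal(a$hits$score, b$hits$score)
  expect_equal(a$hits$fragments, b$hits$fragments)
}
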