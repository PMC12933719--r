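test_that("minimal space parses and sizes multiply per node", {
  tf <- tempfile(fileext = ".json")
  writeLines('{
    "name": "smallest",
    "graphs": [{
      "id": "g1",
      "nodes": [{"id": "n1", "fragments": ["CC[*:1]"]},
                {"id": "n2", "fragments": ["[*:1]O"]}],
      "edges": [{"a": "n1", "b": "n2", "linker_a": "1", "linker_b": "1",
                 "kind": "single_bond", "order": "single"}]
    }]
  }', tf)
  sp <- parse_space(tf)
  expect_equal(space_size(sp), 1)
  expect_s3_class(sp, "fragspace")
})

test_that("space_size is the sum over graphs of node-size products", {
  mk_chain <- function(id, sizes) {
    nodes <- lapply(seq_along(sizes), function(p) {
      linkers <- c(if (p > 1) sprintf("[*:%d]", p - 1),
                   if (p < length(sizes)) sprintf("[*:%d]", p))
      frs <- vapply(seq_len(sizes[p]), function(i) {
        paste0(paste(rep("C", i), collapse = ""),
               paste(linkers, collapse = ""))
      }, character(1))
      list(id = paste0("n", p), fragments = as.list(frs))
    })
    edges <- lapply(seq_len(length(sizes) - 1), function(e) {
      list(a = paste0("n", e), b = paste0("n", e + 1),
           linker_a = as.character(e), linker_b = as.character(e),
           kind = "single_bond", order = "single")
    })
    list(id = id, nodes = nodes, edges = edges)
  }
  sp1 <- space_from_list(list(name = "a",
                              graphs = list(mk_chain("g", c(3, 4, 5)))))
  expect_equal(space_size(sp1), 60)
  sp2 <- space_from_list(list(name = "b",
                              graphs = list(mk_chain("g1", c(2, 2)),
                                            mk_chain("g2", 3))))
  expect_equal(space_size(sp2), 7)
  expect_equal(space_size(single_node_space("CCO")), 1)
})

test_that("validation names the offending key or fragment", {
  expect_error(space_from_list(list(graphs = list())), "missing key 'name'")
  expect_error(space_from_list(list(name = "x", graphs = list(
    list(id = "g", nodes = list(
      list(id = "n1", fragments = list("CC[*:2]")),
      list(id = "n2", fragments = list("[*:1]O"))),
      edges = list(list(a = "n1", b = "n2", linker_a = "1",
                        linker_b = "1")))))),
    "fragment 'n1#1'.*demand \\{1\\}")
  expect_error(space_from_list(list(name = "x", graphs = list(
    list(id = "g", nodes = list(
      list(id = "n1", fragments = list("CC[*:1]")),
      list(id = "n2", fragments = list("[*:1]O")),
      list(id = "n3", fragments = list("[*:9]O"))),
      edges = list(list(a = "n1", b = "n2", linker_a = "1",
                        linker_b = "1")))))),
    "not connected")
  tf <- tempfile(fileext = ".json")
  writeLines("{not json", tf)
  expect_error(parse_space(tf), "malformed JSON")
  expect_error(parse_space(tempfile()), "not found")
})

test_that("a three-node graph with ring-formation edges parses", {
  # shape of the worked example: two single-bond-ish nodes plus an aromatic
  # ring completed across two fragments by a pair of ring-formation edges
  sp <- space_from_list(list(name = "fig", graphs = list(list(
    id = "g1",
    nodes = list(
      list(id = "n1", fragments = list("CC[*:1]")),
      list(id = "n2", fragments = list("[*:1]CCc1cc[*:2][*][*:3]1")),
      list(id = "n3", fragments = list("Oc1cc[*:2][*][*:3]1"))),
    edges = list(
      list(a = "n1", b = "n2", linker_a = "1", linker_b = "1",
           kind = "single_bond", order = "single"),
      list(a = "n2", b = "n3", linker_a = "2", linker_b = "3",
           kind = "ring_formation", order = "aromatic"),
      list(a = "n2", b = "n3", linker_a = "3", linker_b = "2",
           kind = "ring_formation", order = "aromatic"))))))
  expect_length(sp$graphs[[1]]$nodes, 3L)
  expect_length(sp$graphs[[1]]$edges, 3L)
  prods <- enumerate_products(sp)
  expect_length(prods, 1L)
  # the split aromatic ring reassembles at its true size (benzene core)
  expect_true(smarts_match(prods[[1]]$mol, "c1ccccc1"))
  expect_equal(heavy_atom_count(prods[[1]]$mol),
               2 + 5 + 4) # real atoms of the three fragments
})

test_that("assembly joins anchors, drops placeholders, conserves atoms", {
  sp <- mini_space()
  g <- sp$graphs[[1]]
  p <- assemble_product(g, c(n1 = "n1#1", n2 = "n2#1"))
  expect_identical(canonical_code(p), canonical_code(parse_smiles("CCCO")))
  expect_error(assemble_product(g, c(n1 = "n1#1")), "exactly one fragment")
  expect_error(assemble_product(g, c(n1 = "n1#9", n2 = "n2#1")),
               "no fragment")
  # 3-fragment chain: heavy atoms add up (placeholders excluded)
  sp3 <- space_from_list(list(name = "chain3", graphs = list(list(
    id = "g", nodes = list(
      list(id = "a", fragments = list("CCN[*:1]")),
      list(id = "b", fragments = list("[*:1]c1ccc([*:2])cc1")),
      list(id = "c", fragments = list("[*:2]C(=O)O"))),
    edges = list(
      list(a = "a", b = "b", linker_a = "1", linker_b = "1",
           kind = "single_bond", order = "single"),
      list(a = "b", b = "c", linker_a = "2", linker_b = "2",
           kind = "single_bond", order = "single"))))))
  pr <- assemble_product(sp3$graphs[[1]],
                         c(a = "a#1", b = "b#1", c = "c#1"))
  expect_equal(heavy_atom_count(pr), 3 + 6 + 3)
  expect_identical(canonical_code(pr),
                   canonical_code(parse_smiles("CCNc1ccc(C(=O)O)cc1")))
})

test_that("enumeration yields every product once with provenance", {
  sp <- mini_space()
  prods <- enumerate_products(sp, limit = 100)
  expect_length(prods, 16L)
  prov <- vapply(prods, function(p) paste(p$graph,
                                          paste(p$fragments, collapse = ",")),
                 character(1))
  expect_false(anyDuplicated(prov) > 0)
  expect_error(enumerate_products(sp, limit = 10), "over the enumeration")
  expect_length(enumerate_products(single_node_space("CCO")), 1L)
})

test_that("write_space / parse_space round-trips structure", {
  sp <- mini_space()
  tf <- tempfile(fileext = ".json")
  write_space(sp, tf)
  sp2 <- parse_space(tf)
  expect_equal(space_size(sp2), space_size(sp))
  expect_equal(length(sp2$graphs), length(sp$graphs))
  codes <- function(s) sort(unlist(lapply(s$graphs, function(g) {
    lapply(g$nodes, function(nd) {
      vapply(nd$fragments, function(fr) canonical_code(fr$mol), character(1))
    })
  })))
  expect_identical(codes(sp2), codes(sp))
  # byte-identical rewrite
  tf2 <- tempfile(fileext = ".json")
  write_space(sp2, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("fingerprint caches are keyed by descriptor", {
  sp <- precompute_fingerprints(mini_space(), "csfp1.4")
  fp <- fragsim:::space_frag_fp(sp, "csfp1.4", "g1", "n1", "n1#1")
  expect_s3_class(fp, "molfp")
  expect_identical(
    fp$counts,
    compute_fingerprint(parse_smiles("CC[*:1]"), "csfp1.4")$counts)
})
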