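# Synthetic spaces and validation benchmark ------------------------------------------
#
# A desk-scale replica of the validation protocol: build a fragment space by
# fragmenting drug-like molecules at random acyclic single bonds (so every
# source molecule is a product of the space, and cross-combinations of pieces
# from different sources provide near-analogs), sample query/SMARTS cases
# with size-stratified substructure patterns, and measure how the share of
# search results preserving the pattern responds to the weighting factor.

#' Bundled drug-like source molecules
#'
#' Fifty hand-curated drug-like SMILES (no stereochemistry) shipped with the
#' package, used as default input for the synthetic space generator.
#' @return character vector of SMILES, named by compound
#' @export
bundled_molecules <- function() {
  path <- system.file("extdata", "druglike50.smi", package = "fragsim")
  if (path == "") path <- file.path("inst", "extdata", "druglike50.smi")
  parts <- strsplit(readLines(path), " ")
  stats::setNames(vapply(parts, `[[`, character(1), 1),
                  vapply(parts, `[[`, character(1), 2))
}

#' Count Lipinski rule-of-five violations (computable subset)
#'
#' Checks molecular weight <= 500, H-bond donors (N/O with >= 1 H) <= 5 and
#' H-bond acceptors (N + O atoms) <= 10. logP is not computable without
#' fragment contribution tables and is treated as satisfied, so the count is
#' a lower bound.
#' @param mol a molgraph or SMILES string
#' @return integer number of violations (0-3)
#' @export
lipinski_violations <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  no <- mol$symbol %in% c("N", "O") & mol$ptype == "none"
  donors <- sum(no & mol$hcount >= 1)
  acceptors <- sum(no)
  sum(molecular_weight(mol) > 500, donors > 5, acceptors > 10)
}

#' Specification for a synthetic fragment space
#'
#' @param source_smiles character vector of source molecule SMILES (defaults
#'   to the bundled drug-like set with at most one Lipinski violation)
#' @param cuts_per_molecule 1 or 2 acyclic single-bond cuts per molecule
#'   (molecules with too few cuttable bonds fall back to fewer cuts)
#' @param seed random seed driving the cut choices
#' @param name space name
#' @return a synthetic_space_spec
#' @export
synthetic_space_spec <- function(source_smiles = NULL, cuts_per_molecule = 2,
                                 seed = 1, name = "synthetic") {
  if (is.null(source_smiles)) {
    source_smiles <- bundled_molecules()
    source_smiles <- source_smiles[
      vapply(source_smiles, lipinski_violations, integer(1)) <= 1]
  }
  stopifnot(cuts_per_molecule %in% 1:2, length(source_smiles) > 0)
  structure(list(source_smiles = source_smiles,
                 cuts_per_molecule = as.integer(cuts_per_molecule),
                 seed = as.integer(seed), name = name),
            class = "synthetic_space_spec")
}

# cut a molecule at the given bond indices and return pieces ordered as a
# chain, each capped with linker placeholders named by chain edge position
chain_pieces <- function(mol, cut) {
  comp <- mol_components(mol, drop_bonds = cut)
  m <- max(comp)
  b <- mol$bonds
  # component adjacency via cut bonds is a tree; order components as a path
  inc <- lapply(seq_len(m), function(ci) {
    cut[comp[b$a[cut]] == ci | comp[b$b[cut]] == ci]
  })
  deg <- lengths(inc)
  if (m == 1) {
    path <- 1L
  } else {
    ends <- which(deg == 1L)
    if (length(ends) != 2) return(NULL) # not a chain (cannot happen: tree
                                        # with <= 3 nodes and 2 edges)
    first_atom <- vapply(ends, function(ci) min(which(comp == ci)), integer(1))
    start <- ends[which.min(first_atom)]
    path <- start
    while (length(path) < m) {
      nxt_bonds <- setdiff(inc[[path[length(path)]]],
                           unlist(inc[path[-length(path)]]))
      cand <- unique(c(comp[b$a[nxt_bonds]], comp[b$b[nxt_bonds]]))
      nxt <- setdiff(cand, path)
      if (length(nxt) != 1) return(NULL)
      path <- c(path, nxt)
    }
  }
  # piece at chain position p; edge p joins positions p and p+1 via linker p
  lapply(seq_len(m), function(p) {
    ci <- path[p]
    atoms <- which(comp == ci)
    caps <- NULL
    if (length(cut) > 0) {
      rows <- lapply(cut, function(k) {
        ea <- comp[b$a[k]]; eb <- comp[b$b[k]]
        if (ci != ea && ci != eb) return(NULL)
        pa <- match(ea, path); pb <- match(eb, path)
        edge_pos <- min(pa, pb) # edge between positions edge_pos, edge_pos+1
        at <- if (ea == ci) b$a[k] else b$b[k]
        data.frame(at = at, order = b$order[k],
                   name = as.character(edge_pos), stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows) > 0) caps <- do.call(rbind, rows)
    }
    sub <- induced_subgraph(mol, atoms, caps)
    sub$mol
  })
}

#' Generate a synthetic fragment space from source molecules
#'
#' Each source molecule is fragmented at randomly chosen acyclic single bonds
#' into 2-3 pieces; pieces are pooled by chain position into the nodes of a
#' 2-node and/or 3-node chain topology graph (single-bond edges). Every
#' source molecule is reconstructible as a product of its graph; pooling
#' across sources yields the combinatorial bulk. Deterministic under the
#' spec's seed. Fragments are deduplicated per node by canonical code.
#'
#' @param spec a \code{\link{synthetic_space_spec}} (or character vector of
#'   SMILES, taken as \code{source_smiles} with the other defaults)
#' @return a fragspace; attribute \code{"sources"} records each molecule's
#'   SMILES and canonical code
#' @export
generate_space <- function(spec) {
  if (is.character(spec)) spec <- synthetic_space_spec(spec)
  stopifnot(inherits(spec, "synthetic_space_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  pools <- list() # [[n_pieces]][[position]] = character vector of SMILES
  pool_codes <- list()
  sources <- list()
  for (si in seq_along(spec$source_smiles)) {
    smi <- spec$source_smiles[[si]]
    mol <- tryCatch(parse_smiles(smi), error = function(e) NULL)
    if (is.null(mol)) {
      warning("skipping unparseable source molecule: ", smi, call. = FALSE)
      next
    }
    cb <- cuttable_bonds(mol)
    ncut <- min(spec$cuts_per_molecule, length(cb))
    if (ncut == 0) {
      warning("skipping source molecule with no cuttable bond: ", smi,
              call. = FALSE)
      next
    }
    cut <- sort(sample(cb, ncut))
    pieces <- chain_pieces(mol, cut)
    if (is.null(pieces)) next
    m <- length(pieces)
    key <- as.character(m)
    if (is.null(pools[[key]])) {
      pools[[key]] <- rep(list(character(0)), m)
      pool_codes[[key]] <- rep(list(character(0)), m)
    }
    for (p in seq_len(m)) {
      code <- canonical_code(pieces[[p]])
      if (!code %in% pool_codes[[key]][[p]]) {
        pools[[key]][[p]] <- c(pools[[key]][[p]], write_smiles(pieces[[p]]))
        pool_codes[[key]][[p]] <- c(pool_codes[[key]][[p]], code)
      }
    }
    sources[[length(sources) + 1L]] <- data.frame(
      smiles = smi, code = canonical_code(mol), graph = paste0("chain", m),
      stringsAsFactors = FALSE)
  }
  if (length(pools) == 0) stop("no source molecule could be fragmented")
  graphs <- lapply(sort(names(pools)), function(key) {
    m <- as.integer(key)
    nodes <- lapply(seq_len(m), function(p) {
      list(id = paste0("p", p), fragments = as.list(pools[[key]][[p]]))
    })
    edges <- lapply(seq_len(m - 1L), function(e) {
      list(a = paste0("p", e), b = paste0("p", e + 1L),
           linker_a = as.character(e), linker_b = as.character(e),
           kind = "single_bond", order = "single")
    })
    list(id = paste0("chain", m), nodes = nodes, edges = edges)
  })
  space <- space_from_list(list(name = spec$name, graphs = graphs),
                           source = "synthetic generator")
  attr(space, "sources") <- do.call(rbind, sources)
  space
}

# SMARTS extraction -------------------------------------------------------------------

# write the induced subgraph on `atoms` as a SMARTS pattern: element (aromatic
# case) + ring membership per atom, explicit bond orders
subgraph_smarts <- function(mol, atoms) {
  sub <- induced_subgraph(mol, sort(atoms))$mol
  inring <- ring_atom_flags(mol)[sort(atoms)]
  n <- n_atoms(sub)
  adj <- adjacency_list(sub)
  bmap <- bond_index_map(sub)
  visited <- logical(n)
  tree_children <- vector("list", n)
  ring_pairs <- list()
  done <- new.env(parent = emptyenv())
  dfs <- function(v) {
    visited[v] <<- TRUE
    for (u in adj[[v]]) {
      key <- if (v < u) paste(v, u) else paste(u, v)
      if (!is.null(done[[key]])) next
      assign(key, TRUE, envir = done)
      if (visited[u]) {
        ring_pairs[[length(ring_pairs) + 1L]] <<- c(u, v)
      } else {
        tree_children[[v]] <<- c(tree_children[[v]], u)
        dfs(u)
      }
    }
  }
  dfs(1L)
  ring_at <- vector("list", n)
  for (di in seq_along(ring_pairs)) {
    rp <- ring_pairs[[di]]
    ring_at[[rp[1]]] <- c(ring_at[[rp[1]]], list(list(other = rp[2], d = di)))
    ring_at[[rp[2]]] <- c(ring_at[[rp[2]]], list(list(other = rp[1], d = di)))
  }
  atom_token <- function(v) {
    sym <- if (sub$aromatic[v]) tolower(sub$symbol[v]) else sub$symbol[v]
    paste0("[", sym, ";", if (inring[v]) "R" else "!R", "]")
  }
  bond_token <- function(i, j) {
    unname(BOND_CHAR[sub$bonds$order[bond_between(bmap, i, j)]])
  }
  emit <- function(v, from) {
    out <- if (from > 0L) bond_token(from, v) else ""
    out <- paste0(out, atom_token(v))
    for (rc in ring_at[[v]]) {
      out <- paste0(out, bond_token(v, rc$other), rc$d)
    }
    kids <- tree_children[[v]]
    nk <- length(kids)
    for (ki in seq_along(kids)) {
      s <- emit(kids[ki], v)
      if (ki < nk) out <- paste0(out, "(", s, ")") else out <- paste0(out, s)
    }
    out
  }
  emit(1L, 0L)
}

# grow a random connected atom set of exactly `size` atoms; whole ring
# systems only; NULL when the attempt overshoots
grow_substructure <- function(mol, size, rsys) {
  ring_of <- integer(n_atoms(mol))
  for (ri in seq_along(rsys)) ring_of[rsys[[ri]]] <- ri
  close_rings <- function(set) {
    repeat {
      need <- unique(ring_of[set])
      need <- need[need > 0]
      add <- setdiff(unlist(rsys[need]), set)
      if (length(add) == 0) return(set)
      set <- c(set, add)
    }
  }
  adj <- adjacency_list(mol)
  set <- close_rings(sample(n_atoms(mol), 1))
  if (length(set) > size) return(NULL)
  while (length(set) < size) {
    frontier <- setdiff(unique(unlist(adj[set])), set)
    if (length(frontier) == 0) return(NULL)
    cand <- frontier[sample.int(length(frontier), 1)]
    set <- close_rings(c(set, cand))
    if (length(set) > size) return(NULL)
  }
  sort(set)
}

#' Sample query/SMARTS benchmark cases
#'
#' Random (query molecule, SMARTS pattern) pairs, stratified over pattern
#' sizes: each pattern matches exactly its size in connected heavy atoms of
#' its query, includes ring systems only as a whole, and contains at least
#' one non-carbon atom. Patterns are extracted as element + ring-membership
#' SMARTS with explicit bond orders.
#'
#' @param space a synthetic fragspace carrying a \code{"sources"} attribute,
#'   or a character vector of query SMILES
#' @param n_cases number of cases (split evenly over \code{sizes})
#' @param seed random seed
#' @param sizes pattern sizes in heavy atoms
#' @param max_tries sampling attempts per case before reporting a shortfall
#' @return data.frame(case, query, smarts, size); fewer rows (with a warning)
#'   when sampling cannot satisfy the constraints
#' @export
sample_query_cases <- function(space, n_cases, seed = 1, sizes = 3:7,
                               max_tries = 200) {
  queries <- if (is.character(space)) space else {
    src <- attr(space, "sources")
    if (is.null(src)) stop("space has no 'sources' attribute; pass queries")
    src$smiles
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  per_size <- rep(ceiling(n_cases / length(sizes)), length(sizes))
  mols <- lapply(queries, function(q) {
    tryCatch(parse_smiles(q), error = function(e) NULL)
  })
  keep <- !vapply(mols, is.null, logical(1))
  queries <- queries[keep]; mols <- mols[keep]
  rsys_all <- lapply(mols, ring_systems)
  rows <- list()
  seen <- character(0)
  for (szi in seq_along(sizes)) {
    sz <- sizes[szi]
    found <- 0L
    tries <- 0L
    while (found < per_size[szi] && tries < max_tries) {
      tries <- tries + 1L
      qi <- sample.int(length(queries), 1)
      set <- grow_substructure(mols[[qi]], sz, rsys_all[[qi]])
      if (is.null(set)) next
      if (all(mols[[qi]]$symbol[set] == "C")) next
      pat <- subgraph_smarts(mols[[qi]], set)
      key <- paste(qi, pat)
      if (key %in% seen) next
      if (!smarts_match(mols[[qi]], pat)) next # defensive; never expected
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        case = length(rows) + 1L, query = queries[qi], smarts = pat,
        size = sz, stringsAsFactors = FALSE)
      found <- found + 1L
    }
    if (found < per_size[szi]) {
      warning(sprintf("pattern size %d: only %d of %d cases sampled", sz,
                      found, per_size[szi]), call. = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(case = integer(0), query = character(0),
               smarts = character(0), size = integer(0))
  utils::head(out, n_cases)
}

# Metrics -----------------------------------------------------------------------------

#' Share of search results preserving a substructure
#' @param result a fragsearch_result (or character vector of SMILES)
#' @param pattern SMARTS pattern (string or smarts_pattern)
#' @return fraction in [0, 1]; NA (with a warning) for empty results
#' @export
preservation_score <- function(result, pattern) {
  smiles <- if (inherits(result, "fragsearch_result")) result$hits$smiles
            else result
  if (length(smiles) == 0) {
    warning("empty result list: preservation score undefined")
    return(NA_real_)
  }
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  mean(vapply(smiles, function(s) smarts_match(parse_smiles(s), pattern),
              logical(1)))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Atom-based framework: iteratively prune terminal atoms until only ring
#' systems and the linkers between them remain. Acyclic molecules reduce to
#' the empty scaffold.
#' @param mol a molgraph or SMILES string
#' @return canonical SMILES of the scaffold, or "" for acyclic molecules
#' @export
bm_scaffold <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  order_sums <- function(m) {
    s <- numeric(n_atoms(m))
    for (k in seq_len(nrow(m$bonds))) {
      v <- BOND_VALENCE[[m$bonds$order[k]]]
      s[m$bonds$a[k]] <- s[m$bonds$a[k]] + v
      s[m$bonds$b[k]] <- s[m$bonds$b[k]] + v
    }
    s
  }
  repeat {
    deg <- atom_degrees(mol)
    terminal <- which(deg <= 1L)
    if (length(terminal) == 0 || length(terminal) == n_atoms(mol)) {
      if (length(terminal) == n_atoms(mol)) return("")
      break
    }
    keep <- setdiff(seq_len(n_atoms(mol)), terminal)
    before <- order_sums(mol)[keep]
    mol <- induced_subgraph(mol, keep)$mol
    # pruned substituents are replaced by hydrogens
    delta <- ceiling(before) - ceiling(order_sums(mol))
    mol$hcount <- mol$hcount + as.integer(delta)
  }
  write_smiles(mol, canonical = TRUE)
}

#' Number of distinct Bemis-Murcko scaffolds in a hit list
#' @param result a fragsearch_result or character vector of SMILES
#' @return integer count (all-acyclic results count as one empty-scaffold
#'   class)
#' @export
scaffold_count <- function(result) {
  smiles <- if (inherits(result, "fragsearch_result")) result$hits$smiles
            else result
  length(unique(vapply(smiles, bm_scaffold, character(1))))
}

#' Pairwise similarity distribution of a hit list
#'
#' All-pairs unweighted Tanimoto over the result fingerprints, with a fixed
#' 20-bin histogram on [0, 1].
#' @param result a fragsearch_result or character vector of SMILES
#' @param descriptor descriptor name
#' @return list: values, histogram (data.frame lo/hi/count), mean, median
#' @export
pairwise_similarity_distribution <- function(result, descriptor = "csfp1.4") {
  smiles <- if (inherits(result, "fragsearch_result")) result$hits$smiles
            else result
  if (length(smiles) < 2) stop("need at least 2 results")
  fps <- lapply(smiles, function(s) {
    compute_fingerprint(parse_smiles(s), descriptor)
  })
  np <- length(fps)
  vals <- numeric(0)
  for (i in seq_len(np - 1)) {
    for (j in seq(i + 1, np)) {
      vals <- c(vals, tanimoto(fps[[i]], fps[[j]]))
    }
  }
  breaks <- seq(0, 1, by = 0.05)
  bins <- cut(vals, breaks = breaks, include.lowest = TRUE, right = FALSE)
  # values exactly 1 fall in the last bin
  bins[vals == 1] <- levels(bins)[length(levels(bins))]
  hist_df <- data.frame(lo = utils::head(breaks, -1),
                        hi = utils::tail(breaks, -1),
                        count = as.integer(table(bins)))
  list(values = vals, histogram = hist_df, mean = mean(vals),
       median = stats::median(vals))
}

# Benchmark driver --------------------------------------------------------------------

#' Run the substructure-preservation benchmark
#'
#' For every case one unweighted search plus one weighted search per
#' weighting factor is executed, and preservation scores are tabulated.
#' Cases are then discarded by the two protocol rules: (a) no search
#' (weighted or unweighted) produced any molecule matching the pattern — the
#' space evidently holds no similar molecule with the substructure; (b) the
#' unweighted search already preserves the pattern in 100% of its results —
#' weighting cannot show a benefit.
#'
#' @param space a fragspace
#' @param cases data.frame from \code{\link{sample_query_cases}}
#' @param k_values weighting factors for the weighted searches
#' @param config base \code{\link{search_config}} (its k is ignored)
#' @param pairwise also compute the pairwise similarity distribution of every
#'   hit list? (all-pairs; off by default)
#' @return a benchmark_report: \code{results} (per case and k: preservation
#'   score and Bemis-Murcko scaffold count; k = 1 is the unweighted search),
#'   \code{summary} (mean per k), \code{by_size} (mean per k and pattern
#'   size), \code{discarded}, \code{pairwise} (per case and k summary when
#'   enabled), \code{config}
#' @export
run_benchmark <- function(space, cases, k_values = c(5, 10, 15, 20),
                          config = search_config(), pairwise = FALSE) {
  stopifnot(nrow(cases) >= 0, all(k_values >= 1))
  k_values <- sort(unique(k_values[k_values > 1]))
  if (is.null(space$fp_cache[[config$descriptor]])) {
    space <- precompute_fingerprints(space, config$descriptor)
  }
  prod_cache <- new.env(parent = emptyenv())
  scaffold_cache <- new.env(parent = emptyenv())
  scaffolds_of <- function(smiles) {
    length(unique(vapply(smiles, function(s) {
      hit <- scaffold_cache[[s]]
      if (is.null(hit)) {
        hit <- bm_scaffold(s)
        assign(s, hit, envir = scaffold_cache)
      }
      hit
    }, character(1))))
  }
  rows <- list()
  discarded <- list()
  pairwise_rows <- list()
  for (ci in seq_len(nrow(cases))) {
    cs <- cases[ci, ]
    base_cfg <- config
    base_cfg$k <- 1
    scores <- tryCatch({
      run_one <- function(res, kn) {
        if (pairwise && nrow(res$hits) >= 2) {
          d <- pairwise_similarity_distribution(res, config$descriptor)
          pairwise_rows[[length(pairwise_rows) + 1L]] <<- data.frame(
            case = cs$case, k = as.numeric(kn), mean = d$mean,
            median = d$median, stringsAsFactors = FALSE)
        }
        c(preservation = preservation_score(res, cs$smarts),
          scaffolds = scaffolds_of(res$hits$smiles))
      }
      unw <- search_space(space, cs$query, config = base_cfg,
                          product_fp_cache = prod_cache)
      p <- list("1" = run_one(unw, 1))
      for (k in k_values) {
        cfgk <- config
        cfgk$k <- k
        wres <- search_space(space, cs$query, smarts = cs$smarts,
                             config = cfgk, product_fp_cache = prod_cache)
        p[[as.character(k)]] <- run_one(wres, k)
      }
      p
    }, error = function(e) {
      warning("case ", cs$case, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(scores)) {
      discarded[[length(discarded) + 1L]] <-
        data.frame(case = cs$case, reason = "failed",
                   stringsAsFactors = FALSE)
      next
    }
    pres <- vapply(scores, `[[`, numeric(1), "preservation")
    if (all(is.na(pres)) || all(pres[!is.na(pres)] == 0)) {
      discarded[[length(discarded) + 1L]] <-
        data.frame(case = cs$case, reason = "no_match_anywhere",
                   stringsAsFactors = FALSE)
      next
    }
    if (!is.na(pres[["1"]]) && pres[["1"]] == 1) {
      discarded[[length(discarded) + 1L]] <-
        data.frame(case = cs$case, reason = "unweighted_already_perfect",
                   stringsAsFactors = FALSE)
      next
    }
    for (kn in names(scores)) {
      rows[[length(rows) + 1L]] <- data.frame(
        case = cs$case, size = cs$size, k = as.numeric(kn),
        preservation = unname(scores[[kn]][["preservation"]]),
        scaffolds = as.integer(scores[[kn]][["scaffolds"]]),
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(case = integer(0), size = integer(0), k = numeric(0),
               preservation = numeric(0), scaffolds = integer(0))
  summarize <- function(df, by) {
    if (nrow(df) == 0) return(df)
    agg <- stats::aggregate(df$preservation, by = df[by], FUN = mean,
                            na.rm = TRUE)
    names(agg)[ncol(agg)] <- "mean_preservation"
    agg[do.call(order, agg[by]), , drop = FALSE]
  }
  structure(list(
    results = results,
    summary = summarize(results, "k"),
    by_size = summarize(results, c("k", "size")),
    discarded = if (length(discarded) > 0) do.call(rbind, discarded) else
      data.frame(case = integer(0), reason = character(0)),
    pairwise = if (length(pairwise_rows) > 0) do.call(rbind, pairwise_rows)
      else NULL,
    config = config,
    k_values = c(1, k_values)
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  ncase <- length(unique(x$results$case))
  cat(sprintf("<benchmark_report> %d case(s) kept, %d discarded\n", ncase,
              nrow(x$discarded)))
  if (nrow(x$summary) > 0) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report as tidy CSV (+ JSON summary)
#' @param report a benchmark_report
#' @param csv_path path for the per-case CSV
#' @param json_path optional path for the JSON summary
#' @return invisibly csv_path
#' @export
write_benchmark_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$results, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(summary = report$summary,
                              by_size = report$by_size,
                              discarded = report$discarded),
                         json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}
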