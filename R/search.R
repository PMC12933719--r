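# Similarity search core -----------------------------------------------------------
#
# Four stages, operating on building blocks rather than enumerated products:
#   1. partitioning  — cut acyclic single bonds of the query into connected
#                      partition classes shaped like some topology graph;
#   2. matching      — bijections class <-> node with equal topology
#                      (including bond types) and a per-class size filter;
#   3. comparison    — rank each node's fragments against its class by
#                      (weighted) fingerprint Tanimoto similarity;
#   4. combination   — lazy best-first enumeration of the top fragment
#                      combinations by the atom-share-weighted sum of partial
#                      scores, followed by assembly of the candidate pool and
#                      a global (weighted) re-ranking against the full query.
#
# Weighting: features made entirely of marked query atoms get weight k in the
# Tanimoto computation; in the combination score marked atoms count as k/c
# atoms (correction factor c, default 3) so that small classes holding the
# marked area are not drowned out.

#' Search configuration
#'
#' Defaults reproduce the reference configuration: csfp1.4 descriptor,
#' unweighted (k = 1), correction factor 3, minimum marked-feature size 1,
#' size-filter slack 5 heavy atoms, candidate pool = 10 x N.
#'
#' @param n_results N, the number of hits to return
#' @param descriptor fingerprint descriptor name
#' @param k weighting factor for marked features (>= 1; 1 = unweighted)
#' @param correction correction factor c dividing k in the combination-score
#'   atom counts
#' @param min_feature_size smallest feature (heavy atoms) eligible for
#'   up-weighting
#' @param weight_by_size multiply marked feature weights by feature size?
#' @param size_slack maximum heavy-atom difference between a partition class
#'   and the closest fragment of its node
#' @param pool_multiplier candidate pool size = pool_multiplier x n_results
#' @return a search_config object
#' @export
search_config <- function(n_results = 10, descriptor = "csfp1.4", k = 1,
                          correction = 3, min_feature_size = 1,
                          weight_by_size = FALSE, size_slack = 5,
                          pool_multiplier = 10) {
  stopifnot(n_results >= 1, k >= 1, correction > 0, min_feature_size >= 1,
            size_slack >= 0, pool_multiplier >= 1)
  structure(list(
    n_results = as.integer(n_results),
    descriptor = parse_descriptor(descriptor)$tag,
    k = as.numeric(k), correction = as.numeric(correction),
    min_feature_size = as.integer(min_feature_size),
    weight_by_size = isTRUE(weight_by_size),
    size_slack = as.integer(size_slack),
    pool_multiplier = as.integer(pool_multiplier)
  ), class = "search_config")
}

#' Adjusted atom count used in the weighted combination score
#'
#' An unmarked atom counts as 1 atom; a marked atom counts as k / c atoms
#' (never less than 1, so k = 1 reduces exactly to the unweighted count).
#' With k = 6 and c = 3 every marked atom counts as 2.
#'
#' @param marked logical vector (is the atom marked?)
#' @param cfg a search_config supplying k and the correction factor
#' @return numeric vector of per-atom counts
#' @export
adjusted_atom_count <- function(marked, cfg) {
  ifelse(marked, pmax(1, cfg$k / cfg$correction), 1)
}

# Partitioning -----------------------------------------------------------------------

cuttable_bonds <- function(mol) {
  br <- mol_bridges(mol)
  which(br & mol$bonds$order == "single")
}

build_partition <- function(query, cut) {
  comp <- mol_components(query, drop_bonds = cut)
  m <- max(comp)
  b <- query$bonds
  adjacency <- data.frame(
    ci = comp[b$a[cut]], cj = comp[b$b[cut]], order = b$order[cut],
    stringsAsFactors = FALSE
  )
  classes <- lapply(seq_len(m), function(ci) {
    atoms <- which(comp == ci)
    caps <- NULL
    if (length(cut) > 0) {
      inc_a <- cut[comp[b$a[cut]] == ci]
      inc_b <- cut[comp[b$b[cut]] == ci]
      caps <- data.frame(
        at = c(b$a[inc_a], b$b[inc_b]),
        order = c(b$order[inc_a], b$order[inc_b]),
        stringsAsFactors = FALSE
      )
    }
    sub <- induced_subgraph(query, atoms, caps)
    list(atoms = atoms, capped = sub$mol, map = sub$map,
         heavy = length(atoms),
         n_cuts = if (is.null(caps)) 0L else nrow(caps))
  })
  list(cut_bonds = cut, classes = classes, adjacency = adjacency)
}

partition_edge_key <- function(ids_i, ids_j, orders) {
  lo <- pmin(ids_i, ids_j)
  hi <- pmax(ids_i, ids_j)
  sort(paste(lo, hi, orders, sep = "|"))
}

all_permutations <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (r in rest) rec(c(prefix, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(m))
  out
}

# topology-only compatibility: is the class adjacency isomorphic (with bond
# types) to graph g under some bijection?
topology_bijections <- function(part, g) {
  m <- length(part$classes)
  ids <- node_ids(g)
  if (m != length(ids) || graph_has_ring_formation(g)) return(list())
  gkey <- sort(vapply(g$edges, function(e) {
    ab <- sort(c(e$a, e$b))
    paste(ab[1], ab[2], e$order, sep = "|")
  }, character(1)))
  if (nrow(part$adjacency) != length(gkey)) return(list())
  keep <- list()
  for (perm in all_permutations(m)) {
    nid <- ids[perm] # class i -> node nid[i]
    pkey <- partition_edge_key(nid[part$adjacency$ci],
                               nid[part$adjacency$cj],
                               part$adjacency$order)
    if (identical(pkey, gkey)) keep[[length(keep) + 1L]] <- nid
  }
  keep
}

#' Enumerate query partitions compatible with a fragment space
#'
#' All ways of cutting acyclic single bonds of the query such that the
#' resulting connected partition classes form a graph isomorphic (with bond
#' types) to at least one of the space's topology graphs. Topology graphs
#' containing ring-formation edges are not matched.
#'
#' @param query a molgraph (connected, placeholder-free) or SMILES string
#' @param space a fragspace
#' @return list of partition objects
#' @export
enumerate_partitions <- function(query, space) {
  if (is.character(query)) query <- parse_smiles(query)
  if (any(is_placeholder(query))) stop("query must be placeholder-free")
  if (!is_connected_mol(query)) stop("query must be connected")
  eligible <- space$graphs[!vapply(space$graphs, graph_has_ring_formation,
                                   logical(1))]
  counts <- sort(unique(vapply(eligible, function(g) length(g$nodes),
                               integer(1))))
  counts <- counts[counts <= n_atoms(query)]
  if (length(counts) == 0) return(list())
  cb <- cuttable_bonds(query)
  out <- list()
  for (m in counts) {
    ncut <- m - 1L
    if (ncut > length(cb)) next
    cut_sets <- if (ncut == 0) list(integer(0)) else
      utils::combn(cb, ncut, simplify = FALSE)
    for (cut in cut_sets) {
      part <- build_partition(query, cut)
      ok <- any(vapply(eligible, function(g) {
        length(topology_bijections(part, g)) > 0
      }, logical(1)))
      if (ok) out[[length(out) + 1L]] <- part
    }
  }
  out
}

#' Match a partition onto a topology graph
#'
#' Returns every bijection of partition classes onto the graph's nodes under
#' which the class adjacency equals the node adjacency including bond types,
#' and every class is within \code{slack} heavy atoms of at least one
#' fragment of its node. Graphs with ring-formation edges yield no matchings.
#'
#' @param part a partition from \code{\link{enumerate_partitions}}
#' @param g a topology_graph
#' @param slack heavy-atom size slack
#' @return list of matchings: \code{graph} id and \code{assignment}
#'   (node id per class index)
#' @export
match_partition <- function(part, g, slack = 5) {
  bijections <- topology_bijections(part, g)
  out <- list()
  for (nid in bijections) {
    ok <- TRUE
    for (i in seq_along(part$classes)) {
      nd <- graph_node(g, nid[i])
      sizes <- vapply(nd$fragments, `[[`, numeric(1), "heavy")
      if (!any(abs(part$classes[[i]]$heavy - sizes) <= slack)) {
        ok <- FALSE
        break
      }
      # same connectivity: cut-bond count of the class equals the node degree
      degree <- sum(vapply(g$edges, function(e) {
        (e$a == nid[i]) + (e$b == nid[i])
      }, numeric(1)))
      if (part$classes[[i]]$n_cuts != degree) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      out[[length(out) + 1L]] <- list(graph = g$id, assignment = nid,
                                      partition = part)
    }
  }
  out
}

# Comparison ------------------------------------------------------------------------

#' Rank a node's fragments against a partition class
#'
#' Each fragment is scored by the weighted Tanimoto similarity between its
#' fingerprint and the fingerprint of the wildcard-capped class subgraph. The
#' marked feature set is computed on the class subgraph only, so marked
#' features absent from this class never penalize fragments through the
#' denominator. Ties are broken by fragment id.
#'
#' @param cls a partition class
#' @param node a topology_node
#' @param cfg a search_config
#' @param marked_atoms integer vector of marked query atom indices
#' @param frag_fps optional precomputed list of fragment fingerprints (named
#'   by fragment id)
#' @return data.frame(frag, score) sorted by descending score
#' @export
score_node_fragments <- function(cls, node, cfg, marked_atoms = integer(0),
                                 frag_fps = NULL) {
  marked_local <- cls$map[intersect(marked_atoms, cls$atoms)]
  class_fp <- compute_fingerprint(cls$capped, cfg$descriptor,
                                  marked = marked_local)
  w <- if (cfg$k > 1 && length(class_fp$marked) > 0) {
    feature_weighting(class_fp$marked, cfg$k, cfg$min_feature_size,
                      cfg$weight_by_size)
  } else {
    feature_weighting()
  }
  ids <- vapply(node$fragments, `[[`, character(1), "id")
  scores <- vapply(seq_along(node$fragments), function(i) {
    fp <- if (!is.null(frag_fps)) frag_fps[[ids[i]]] else
      compute_fingerprint(node$fragments[[i]]$mol, cfg$descriptor)
    weighted_tanimoto(class_fp, fp, w)
  }, numeric(1))
  ord <- order(-scores, ids)
  data.frame(frag = ids[ord], score = scores[ord], stringsAsFactors = FALSE)
}

# Combination ------------------------------------------------------------------------

# scored matching: graph, assignment, ranked (list of data.frames per class),
# shares (numeric per class)
score_matchings <- function(matchings, space, cfg, marked_atoms, query) {
  adjusted <- adjusted_atom_count(seq_len(n_atoms(query)) %in% marked_atoms,
                                  cfg)
  total <- sum(adjusted)
  g_by_id <- stats::setNames(space$graphs,
                             vapply(space$graphs, `[[`, character(1), "id"))
  rank_cache <- new.env(parent = emptyenv())
  lapply(matchings, function(mt) {
    g <- g_by_id[[mt$graph]]
    part <- mt$partition
    ranked <- lapply(seq_along(part$classes), function(i) {
      key <- paste(paste(part$cut_bonds, collapse = ","), i, mt$graph,
                   mt$assignment[i], sep = "/")
      hit <- rank_cache[[key]]
      if (!is.null(hit)) return(hit)
      nd <- graph_node(g, mt$assignment[i])
      fps <- space$fp_cache[[cfg$descriptor]][[mt$graph]][[mt$assignment[i]]]
      r <- score_node_fragments(part$classes[[i]], nd, cfg, marked_atoms,
                                frag_fps = fps)
      assign(key, r, envir = rank_cache)
      r
    })
    shares <- vapply(part$classes, function(cl) {
      sum(adjusted[cl$atoms]) / total
    }, numeric(1))
    list(graph = mt$graph, assignment = mt$assignment, partition = part,
         ranked = ranked, shares = shares)
  })
}

combo_entry <- function(sm, mi, ix) {
  frags <- vapply(seq_along(ix), function(i) sm$ranked[[i]]$frag[ix[i]],
                  character(1))
  partials <- vapply(seq_along(ix), function(i) sm$ranked[[i]]$score[ix[i]],
                     numeric(1))
  list(score = sum(sm$shares * partials), graph = sm$graph,
       fragkey = paste(frags, collapse = ""), matching = mi, ix = ix,
       fragments = frags, partials = partials,
       assignment = sm$assignment)
}

combo_before <- function(x, y) {
  if (x$score != y$score) return(x$score > y$score)
  if (x$graph != y$graph) return(x$graph < y$graph)
  if (x$fragkey != y$fragkey) return(x$fragkey < y$fragkey)
  x$matching < y$matching
}

#' Top fragment combinations across all matchings (lazy k-best)
#'
#' Best-first enumeration over the ranked per-node fragment lists: the pool
#' returned is exactly the global top-\code{pool_size} combinations by the
#' adjusted combination score (share-weighted sum of partial scores), without
#' full enumeration. Ties break by (score desc, graph id, fragment ids,
#' matching index).
#'
#' @param scored_matchings output of the internal matching scorer: one entry
#'   per matching with ranked lists and class shares
#' @param cfg a search_config
#' @param pool_size number of combinations to return
#' @return list of combinations (fragments, partial scores, combination
#'   score, matching provenance)
#' @export
combine_top <- function(scored_matchings, cfg,
                        pool_size = cfg$n_results * cfg$pool_multiplier) {
  heap <- list()
  seen <- new.env(parent = emptyenv())
  push <- function(entry) {
    key <- paste(entry$matching, paste(entry$ix, collapse = ","))
    if (!is.null(seen[[key]])) return(invisible())
    assign(key, TRUE, envir = seen)
    heap[[length(heap) + 1L]] <<- entry
  }
  for (mi in seq_along(scored_matchings)) {
    sm <- scored_matchings[[mi]]
    push(combo_entry(sm, mi, rep(1L, length(sm$ranked))))
  }
  pool <- list()
  while (length(pool) < pool_size && length(heap) > 0) {
    best <- 1L
    for (i in seq_along(heap)) {
      if (combo_before(heap[[i]], heap[[best]])) best <- i
    }
    top <- heap[[best]]
    heap[[best]] <- NULL
    pool[[length(pool) + 1L]] <- top
    sm <- scored_matchings[[top$matching]]
    for (i in seq_along(top$ix)) {
      if (top$ix[i] < nrow(sm$ranked[[i]])) {
        nix <- top$ix
        nix[i] <- nix[i] + 1L
        push(combo_entry(sm, top$matching, nix))
      }
    }
  }
  pool
}

# Global re-ranking ------------------------------------------------------------------

#' Assemble and globally re-rank a candidate pool
#'
#' Each pooled fragment combination is assembled into a full product and
#' scored by the weighted Tanimoto similarity between the whole-query
#' fingerprint and the product fingerprint. The marked feature set is now
#' computed on the whole query, so marked features spanning several fragments
#' reward products that assemble the complete marked area.
#'
#' @param pool list of combinations from \code{\link{combine_top}}
#' @param query query molgraph
#' @param marked_atoms marked query atom indices
#' @param cfg a search_config
#' @param space the fragspace (for assembly)
#' @param fp_cache optional environment caching product fingerprints across
#'   searches, keyed by graph and fragment ids
#' @return a fragsearch_result
#' @export
global_rerank <- function(pool, query, marked_atoms, cfg, space,
                          fp_cache = NULL) {
  qfp <- compute_fingerprint(query, cfg$descriptor, marked = marked_atoms)
  w <- if (cfg$k > 1 && length(qfp$marked) > 0) {
    feature_weighting(qfp$marked, cfg$k, cfg$min_feature_size,
                      cfg$weight_by_size)
  } else {
    feature_weighting()
  }
  g_by_id <- stats::setNames(space$graphs,
                             vapply(space$graphs, `[[`, character(1), "id"))
  rows <- list()
  for (cb in pool) {
    sel_order <- order(cb$assignment)
    key <- paste(cb$graph, paste(cb$assignment[sel_order],
                                 cb$fragments[sel_order],
                                 sep = "=", collapse = ";"))
    cached <- if (!is.null(fp_cache)) fp_cache[[key]] else NULL
    if (is.null(cached)) {
      g <- g_by_id[[cb$graph]]
      sel <- stats::setNames(cb$fragments, cb$assignment)
      prod_mol <- tryCatch(assemble_product(g, sel), error = function(e) {
        warning("dropping combination (", cb$graph, ": ",
                paste(cb$fragments, collapse = ","), "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(prod_mol)) next
      cached <- list(fp = compute_fingerprint(prod_mol, cfg$descriptor),
                     smiles = write_smiles(prod_mol))
      if (!is.null(fp_cache)) assign(key, cached, envir = fp_cache)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      smiles = cached$smiles,
      score = weighted_tanimoto(qfp, cached$fp, w),
      combination_score = cb$score,
      graph = cb$graph,
      fragments = paste(cb$fragments, collapse = ","),
      matching = cb$matching,
      fragkey = cb$fragkey,
      selkey = key,
      stringsAsFactors = FALSE
    )
  }
  hits <- if (length(rows) == 0) {
    data.frame(smiles = character(0), score = numeric(0),
               combination_score = numeric(0), graph = character(0),
               fragments = character(0), matching = integer(0),
               fragkey = character(0), selkey = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  ord <- order(-hits$score, hits$graph, hits$fragkey, hits$matching)
  hits <- hits[ord, , drop = FALSE]
  # the same node -> fragment selection reached through different matchings
  # is one fragment combination: keep its best-sorted instance only
  hits <- hits[!duplicated(hits$selkey), , drop = FALSE]
  hits <- utils::head(hits, cfg$n_results)
  hits$fragkey <- NULL
  hits$selkey <- NULL
  if (nrow(hits) > 0) hits <- cbind(rank = seq_len(nrow(hits)), hits)
  rownames(hits) <- NULL
  structure(list(
    hits = hits,
    query = write_smiles(query),
    marked_atoms = marked_atoms,
    config = cfg
  ), class = "fragsearch_result")
}

#' @export
print.fragsearch_result <- function(x, ...) {
  cat(sprintf("<fragsearch_result> query %s, %d hit(s), descriptor %s, k=%g\n",
              x$query, nrow(x$hits), x$config$descriptor, x$config$k))
  if (nrow(x$hits) > 0) print(utils::head(x$hits, 10))
  invisible(x)
}

# Pipeline ---------------------------------------------------------------------------

resolve_marking <- function(query, smarts, marking) {
  if (!is.null(smarts)) {
    atoms <- smarts_marked_atoms(query, smarts)
    if (length(atoms) == 0) {
      stop("the marking SMARTS matches zero query atoms; nothing to weight")
    }
    return(atoms)
  }
  if (is.null(marking)) return(integer(0))
  marking <- sort(unique(as.integer(marking)))
  if (length(marking) > 0 &&
      (min(marking) < 1 || max(marking) > n_atoms(query))) {
    stop("marking contains invalid atom indices")
  }
  marking
}

#' Similarity search in a fragment space
#'
#' The full pipeline: partition enumeration, topology matching, per-node
#' fragment ranking, lazy top-combination enumeration and global re-ranking.
#' With no marking (or k = 1) this is the plain unweighted search; with a
#' marked substructure (SMARTS or atom indices) and k > 1, marked fingerprint
#' features and marked atoms are up-weighted at every stage.
#'
#' @param space a fragspace
#' @param query query molecule (SMILES string or molgraph)
#' @param smarts optional SMARTS string selecting the atoms to mark
#' @param marking optional explicit integer vector of marked query atom
#'   indices (ignored when \code{smarts} is given)
#' @param config a \code{\link{search_config}}
#' @param product_fp_cache optional environment reused across searches to
#'   cache assembled product fingerprints
#' @return a fragsearch_result; zero hits (with a warning) when no topology
#'   graph is compatible with the query
#' @export
search_space <- function(space, query, smarts = NULL, marking = NULL,
                         config = search_config(),
                         product_fp_cache = NULL) {
  if (is.character(query)) query <- parse_smiles(query)
  marked_atoms <- resolve_marking(query, smarts, marking)
  if (is.null(space$fp_cache[[config$descriptor]])) {
    space <- precompute_fingerprints(space, config$descriptor)
  }
  parts <- enumerate_partitions(query, space)
  matchings <- list()
  for (part in parts) {
    for (g in space$graphs) {
      matchings <- c(matchings,
                     match_partition(part, g, slack = config$size_slack))
    }
  }
  if (length(matchings) == 0) {
    warning("no topology graph of the space is compatible with the query")
    res <- global_rerank(list(), query, marked_atoms, config, space)
    res$stats <- list(n_partitions = length(parts), n_matchings = 0L,
                      pool_size = 0L)
    return(res)
  }
  scored <- score_matchings(matchings, space, config, marked_atoms, query)
  pool <- combine_top(scored, config)
  res <- global_rerank(pool, query, marked_atoms, config, space,
                       fp_cache = product_fp_cache)
  res$stats <- list(n_partitions = length(parts),
                    n_matchings = length(matchings),
                    pool_size = length(pool))
  res
}

# Output -----------------------------------------------------------------------------

#' Write search hits as a tab-separated SMILES file
#' @param result a fragsearch_result
#' @param path output path
#' @return invisibly the path
#' @export
write_result_tsv <- function(result, path) {
  utils::write.table(result$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a search result (hits, query, config) as JSON
#' @param result a fragsearch_result
#' @param path output path
#' @return invisibly the path
#' @export
write_result_json <- function(result, path) {
  x <- list(query = result$query, marked_atoms = result$marked_atoms,
            config = unclass(result$config), hits = result$hits)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
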