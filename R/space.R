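# Topological fragment spaces ----------------------------------------------------
#
# A fragment space encodes a combinatorial compound library: each topology
# graph has nodes holding interchangeable building-block fragments and edges
# stating how fragments of adjacent nodes bond (via named linker placeholder
# atoms) and with which bond order. A product is built by picking one fragment
# per node and wiring the picks along the edges; placeholder atoms vanish on
# assembly. The encoded library size is the product of node sizes, summed
# over graphs — products are never enumerated during search.
#
# On-disk format: a versioned JSON dialect (the vendor formats are
# proprietary). Fragments are SMILES with linker placeholders written as
# atom-mapped dummy atoms ([*:1] is linker "1") and ring placeholders as
# unmapped dummies ([*]).

EDGE_KINDS <- c("single_bond", "ring_formation")

#' Build a fragment from SMILES
#'
#' Fragments in multi-node graphs carry one atom-mapped dummy atom per
#' incident topology edge; fragments of single-node graphs carry none (they
#' are complete molecules). Linker/edge consistency is enforced by
#' \code{\link{validate_space}}.
#' @param smiles fragment SMILES, linker placeholders as atom-mapped dummies
#' @param id fragment identifier
#' @return a fragment object
#' @export
fragment_from_smiles <- function(smiles, id) {
  mol <- parse_smiles(smiles)
  linkers <- mol$pname[mol$ptype == "linker"]
  if (anyDuplicated(linkers)) {
    stop("fragment '", id, "' has duplicate linker names")
  }
  structure(list(id = id, smiles = smiles, mol = mol,
                 heavy = heavy_atom_count(mol),
                 linkers = sort(linkers)),
            class = "fragment")
}

new_topology_node <- function(id, fragments) {
  if (length(fragments) == 0) stop("topology node '", id, "' has no fragments")
  structure(list(id = id, fragments = fragments), class = "topology_node")
}

new_topology_edge <- function(a, b, linker_a, linker_b,
                              kind = "single_bond", order = "single") {
  if (identical(a, b)) stop("topology edge connects node '", a, "' to itself")
  if (!kind %in% EDGE_KINDS) stop("unknown edge kind '", kind, "'")
  if (!order %in% BOND_ORDERS) stop("unknown edge bond order '", order, "'")
  structure(list(a = a, b = b, linker_a = as.character(linker_a),
                 linker_b = as.character(linker_b), kind = kind,
                 order = order),
            class = "topology_edge")
}

new_topology_graph <- function(id, nodes, edges) {
  structure(list(id = id, nodes = nodes, edges = edges),
            class = "topology_graph")
}

new_fragspace <- function(name, graphs) {
  structure(list(name = name, graphs = graphs, version = 1L,
                 fp_cache = list()),
            class = "fragspace")
}

node_ids <- function(graph) vapply(graph$nodes, `[[`, character(1), "id")

graph_has_ring_formation <- function(graph) {
  any(vapply(graph$edges, function(e) e$kind == "ring_formation", logical(1)))
}

# linker names demanded from a node by its incident edges
node_required_linkers <- function(graph, node_id) {
  req <- character(0)
  for (e in graph$edges) {
    if (e$a == node_id) req <- c(req, e$linker_a)
    if (e$b == node_id) req <- c(req, e$linker_b)
  }
  sort(req)
}

#' Validate a fragment space
#'
#' Checks all structural invariants: unique graph/node ids, edges referencing
#' existing nodes, connected topology graphs, and every fragment carrying
#' exactly the linker set demanded by its node's incident edges.
#' @param space a fragspace
#' @return invisibly TRUE; informative error otherwise
#' @export
validate_space <- function(space) {
  if (length(space$graphs) == 0) stop("space has no topology graphs")
  gids <- vapply(space$graphs, `[[`, character(1), "id")
  if (anyDuplicated(gids)) stop("duplicate topology graph ids")
  for (g in space$graphs) {
    ids <- node_ids(g)
    if (anyDuplicated(ids)) stop("duplicate node ids in graph '", g$id, "'")
    for (e in g$edges) {
      if (!e$a %in% ids || !e$b %in% ids) {
        stop("edge in graph '", g$id, "' references unknown node '",
             if (!e$a %in% ids) e$a else e$b, "'")
      }
    }
    # connectivity of the node/edge graph
    if (length(ids) > 1) {
      seen <- ids[1]
      repeat {
        grow <- FALSE
        for (e in g$edges) {
          if (e$a %in% seen && !e$b %in% seen) { seen <- c(seen, e$b); grow <- TRUE }
          if (e$b %in% seen && !e$a %in% seen) { seen <- c(seen, e$a); grow <- TRUE }
        }
        if (!grow) break
      }
      if (length(seen) < length(ids)) {
        stop("topology graph '", g$id, "' is not connected")
      }
    }
    for (nd in g$nodes) {
      req <- node_required_linkers(g, nd$id)
      if (length(req) == 0 && length(ids) > 1) {
        stop("node '", nd$id, "' in graph '", g$id, "' has no incident edges")
      }
      for (fr in nd$fragments) {
        # linker names are unique per fragment, so the incident edges must
        # demand pairwise distinct linker names matching the fragment's set
        if (anyDuplicated(req) > 0 ||
            !identical(sort(fr$linkers), sort(unique(req)))) {
          stop("fragment '", fr$id, "' in node '", nd$id, "' of graph '",
               g$id, "' carries linkers {", paste(fr$linkers, collapse = ","),
               "} but the node's edges demand {",
               paste(req, collapse = ","), "}")
        }
        validate_mol(fr$mol)
      }
    }
  }
  invisible(TRUE)
}

#' Total number of products encoded by a fragment space
#'
#' The sum over topology graphs of the product of fragment counts per node.
#' @param space a fragspace
#' @return a number (double; spaces can exceed integer range)
#' @export
space_size <- function(space) {
  sizes <- vapply(space$graphs, function(g) {
    prod(vapply(g$nodes, function(nd) length(nd$fragments), numeric(1)))
  }, numeric(1))
  sum(sizes)
}

#' @export
print.fragspace <- function(x, ...) {
  cat(sprintf("<fragspace '%s'> %d topology graph(s), %s products\n",
              x$name, length(x$graphs),
              format(space_size(x), big.mark = ",")))
  for (g in x$graphs) {
    cat(sprintf("  graph %s: %d nodes (%s), %d edges\n", g$id,
                length(g$nodes),
                paste(vapply(g$nodes, function(nd) length(nd$fragments),
                             integer(1)), collapse = "x"),
                length(g$edges)))
  }
  invisible(x)
}

# JSON I/O ----------------------------------------------------------------------

space_from_list <- function(x, source = "space list") {
  for (key in c("name", "graphs")) {
    if (is.null(x[[key]])) {
      stop("malformed space (", source, "): missing key '", key, "'")
    }
  }
  graphs <- lapply(seq_along(x$graphs), function(gi) {
    g <- x$graphs[[gi]]
    for (key in c("id", "nodes")) {
      if (is.null(g[[key]])) {
        stop("malformed space (", source, "): graph ", gi,
             " missing key '", key, "'")
      }
    }
    nodes <- lapply(g$nodes, function(nd) {
      if (is.null(nd$id) || is.null(nd$fragments)) {
        stop("malformed space (", source, "): node in graph '", g$id,
             "' missing key 'id' or 'fragments'")
      }
      frs <- lapply(seq_along(nd$fragments), function(fi) {
        sm <- nd$fragments[[fi]]
        if (!is.character(sm) || length(sm) != 1) {
          stop("malformed space (", source, "): fragment ", fi, " of node '",
               nd$id, "' is not a SMILES string")
        }
        fragment_from_smiles(sm, id = sprintf("%s#%d", nd$id, fi))
      })
      new_topology_node(nd$id, frs)
    })
    edges <- lapply(if (is.null(g$edges)) list() else g$edges, function(e) {
      for (key in c("a", "b", "linker_a", "linker_b")) {
        if (is.null(e[[key]])) {
          stop("malformed space (", source, "): edge in graph '", g$id,
               "' missing key '", key, "'")
        }
      }
      new_topology_edge(e$a, e$b, e$linker_a, e$linker_b,
                        kind = if (is.null(e$kind)) "single_bond" else e$kind,
                        order = if (is.null(e$order)) "single" else e$order)
    })
    new_topology_graph(g$id, nodes, edges)
  })
  sp <- new_fragspace(x$name, graphs)
  validate_space(sp)
  sp
}

space_to_list <- function(space) {
  list(
    format = "fragsim-space",
    version = 1L,
    name = space$name,
    graphs = lapply(space$graphs, function(g) {
      list(
        id = g$id,
        nodes = lapply(g$nodes, function(nd) {
          list(id = nd$id,
               fragments = vapply(nd$fragments, `[[`, character(1), "smiles"))
        }),
        edges = lapply(g$edges, function(e) {
          list(a = e$a, b = e$b, linker_a = e$linker_a,
               linker_b = e$linker_b, kind = e$kind, order = e$order)
        })
      )
    })
  )
}

#' Read a fragment space from its JSON file
#' @param path path to a space JSON file
#' @return a validated fragspace
#' @export
parse_space <- function(path) {
  if (!file.exists(path)) stop("space file not found: ", path)
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) {
                  stop("malformed JSON in '", path, "': ",
                       conditionMessage(e))
                })
  space_from_list(x, source = path)
}

#' Write a fragment space to JSON
#' @param space a fragspace
#' @param path output path
#' @return invisibly the path
#' @export
write_space <- function(space, path) {
  jsonlite::write_json(space_to_list(space), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# Assembly ------------------------------------------------------------------------

frag_by_id <- function(node, frag_id) {
  for (fr in node$fragments) if (fr$id == frag_id) return(fr)
  stop("node '", node$id, "' has no fragment '", frag_id, "'")
}

graph_node <- function(graph, node_id) {
  for (nd in graph$nodes) if (nd$id == node_id) return(nd)
  stop("graph '", graph$id, "' has no node '", node_id, "'")
}

# find the linker atom of a fragment mol and the unique real atom it binds
linker_anchor <- function(mol, linker_name, frag_id) {
  li <- which(mol$ptype == "linker" & mol$pname == linker_name)
  if (length(li) != 1) {
    stop("fragment '", frag_id, "' does not carry exactly one linker '",
         linker_name, "'")
  }
  b <- mol$bonds
  nb <- c(b$b[b$a == li], b$a[b$b == li])
  real_nb <- nb[mol$ptype[nb] == "none"]
  if (length(real_nb) != 1) {
    stop("linker '", linker_name, "' in fragment '", frag_id,
         "' must bind exactly one real atom")
  }
  list(linker = li, anchor = real_nb)
}

#' Assemble a product molecule from a topology graph and fragment selection
#'
#' One fragment is chosen per node; every edge wires the real atoms adjacent
#' to the two referenced linker placeholders with the edge's bond order, after
#' which all placeholder atoms are removed. Ring-formation edges use the same
#' mechanics (a ring split across two fragments is completed by its pair of
#' edges); ring placeholder atoms are padding duplicated by the partner
#' fragment's real atoms and are dropped.
#'
#' @param graph a topology_graph
#' @param selection named character vector or list: node id -> fragment id
#' @return a placeholder-free connected molgraph; attribute
#'   \code{"provenance"} records graph and fragment ids
#' @export
assemble_product <- function(graph, selection) {
  ids <- node_ids(graph)
  sel <- unlist(selection)
  if (!setequal(names(sel), ids) || length(sel) != length(ids)) {
    stop("selection must pick exactly one fragment for each of: ",
         paste(ids, collapse = ", "))
  }
  frs <- lapply(ids, function(nid) frag_by_id(graph_node(graph, nid),
                                              sel[[nid]]))
  names(frs) <- ids
  # concatenate fragment graphs
  offset <- stats::setNames(integer(length(ids)), ids)
  symbol <- character(0); charge <- integer(0); aromatic <- logical(0)
  ptype <- character(0); pname <- character(0); hcount <- integer(0)
  bonds <- data.frame(a = integer(0), b = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  for (nid in ids) {
    m <- frs[[nid]]$mol
    offset[nid] <- length(symbol)
    bonds <- rbind(bonds, data.frame(a = m$bonds$a + offset[nid],
                                     b = m$bonds$b + offset[nid],
                                     order = m$bonds$order,
                                     stringsAsFactors = FALSE))
    symbol <- c(symbol, m$symbol); charge <- c(charge, m$charge)
    aromatic <- c(aromatic, m$aromatic); ptype <- c(ptype, m$ptype)
    pname <- c(pname, m$pname); hcount <- c(hcount, m$hcount)
  }
  # per-atom bond-order sums as parsed (placeholder bonds included): the
  # reference state the fragments' implicit H counts were derived from
  sum_orig <- numeric(length(symbol))
  for (k in seq_len(nrow(bonds))) {
    v <- BOND_VALENCE[[bonds$order[k]]]
    sum_orig[bonds$a[k]] <- sum_orig[bonds$a[k]] + v
    sum_orig[bonds$b[k]] <- sum_orig[bonds$b[k]] + v
  }
  consumed <- integer(0)
  for (e in graph$edges) {
    aa <- linker_anchor(frs[[e$a]]$mol, e$linker_a, frs[[e$a]]$id)
    bb <- linker_anchor(frs[[e$b]]$mol, e$linker_b, frs[[e$b]]$id)
    consumed <- c(consumed, aa$linker + offset[e$a], bb$linker + offset[e$b])
    bonds <- rbind(bonds, data.frame(a = aa$anchor + offset[e$a],
                                     b = bb$anchor + offset[e$b],
                                     order = e$order,
                                     stringsAsFactors = FALSE))
  }
  # unresolved named linkers (validate_space prevents this for valid spaces)
  leftover <- which(ptype == "linker" & !seq_along(ptype) %in% consumed)
  if (length(leftover) > 0) {
    stop("unresolved linker placeholder '", pname[leftover[1]],
         "' after applying all edges")
  }
  drop <- which(ptype != "none")
  keep <- setdiff(seq_along(symbol), drop)
  sum_before <- sum_orig[keep]
  map <- integer(length(symbol))
  map[keep] <- seq_along(keep)
  kb <- bonds[bonds$a %in% keep & bonds$b %in% keep, , drop = FALSE]
  kb$a <- map[kb$a]; kb$b <- map[kb$b]
  out <- new_molgraph(symbol[keep], charge[keep], aromatic[keep],
                      ptype[keep], pname[keep], hcount[keep], kb)
  # correct implicit H where the placeholder bond order differed from the
  # connecting edge order (e.g. single written in the fragment, aromatic on
  # the edge)
  sum_after <- numeric(n_atoms(out))
  for (k in seq_len(nrow(out$bonds))) {
    v <- BOND_VALENCE[[out$bonds$order[k]]]
    sum_after[out$bonds$a[k]] <- sum_after[out$bonds$a[k]] + v
    sum_after[out$bonds$b[k]] <- sum_after[out$bonds$b[k]] + v
  }
  delta <- ceiling(sum_after) - ceiling(sum_before)
  adj <- which(delta != 0)
  out$hcount[adj] <- pmax(0L, out$hcount[adj] - as.integer(delta[adj]))
  if (!is_connected_mol(out)) {
    stop("assembled product is not connected (graph '", graph$id, "')")
  }
  attr(out, "provenance") <- list(graph = graph$id, fragments = unname(sel[ids]),
                                  nodes = ids)
  out
}

#' Enumerate every product of a fragment space (brute-force oracle)
#'
#' Refuses spaces larger than \code{limit}: enumeration is the test oracle,
#' not the search path.
#' @param space a fragspace
#' @param limit hard cap on \code{\link{space_size}}
#' @return list of entries: \code{mol}, \code{graph}, \code{fragments}
#'   (character vector of fragment ids), \code{smiles}, \code{code}
#'   (canonical structure code for deduplication)
#' @export
enumerate_products <- function(space, limit = 1e5) {
  sz <- space_size(space)
  if (sz > limit) {
    stop("space has ", format(sz, big.mark = ","),
         " products, over the enumeration limit of ",
         format(limit, big.mark = ","))
  }
  out <- vector("list", 0)
  for (g in space$graphs) {
    ids <- node_ids(g)
    pools <- lapply(g$nodes, function(nd) {
      vapply(nd$fragments, `[[`, character(1), "id")
    })
    idx <- rep(1L, length(pools))
    sizes <- vapply(pools, length, integer(1))
    repeat {
      sel <- stats::setNames(
        mapply(function(p, i) p[[i]], pools, idx), ids)
      mol <- assemble_product(g, sel)
      out[[length(out) + 1L]] <- list(
        mol = mol, graph = g$id, fragments = unname(sel),
        smiles = write_smiles(mol), code = canonical_code(mol))
      # odometer increment
      pos <- 1L
      while (pos <= length(idx)) {
        idx[pos] <- idx[pos] + 1L
        if (idx[pos] <= sizes[pos]) break
        idx[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > length(idx)) break
    }
  }
  out
}

# Fingerprint precomputation -------------------------------------------------------

#' Precompute fragment fingerprints for a descriptor
#'
#' Returns the space with a fingerprint cache filled for the given
#' descriptor; searches reuse the cache instead of recomputing fragment
#' fingerprints.
#' @param space a fragspace
#' @param descriptor descriptor name
#' @return the space with \code{fp_cache[[tag]]} populated
#' @export
precompute_fingerprints <- function(space, descriptor) {
  d <- parse_descriptor(descriptor)
  cache <- lapply(space$graphs, function(g) {
    per_node <- lapply(g$nodes, function(nd) {
      fps <- lapply(nd$fragments, function(fr) {
        compute_fingerprint(fr$mol, d$tag)
      })
      names(fps) <- vapply(nd$fragments, `[[`, character(1), "id")
      fps
    })
    names(per_node) <- node_ids(g)
    per_node
  })
  names(cache) <- vapply(space$graphs, `[[`, character(1), "id")
  space$fp_cache[[d$tag]] <- cache
  space
}

space_frag_fp <- function(space, tag, graph_id, node_id, frag_id) {
  space$fp_cache[[tag]][[graph_id]][[node_id]][[frag_id]]
}
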