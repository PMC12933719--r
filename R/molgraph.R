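# Molecular graphs ------------------------------------------------------------
#
# A minimal labeled-graph substrate shared by fragments, queries and assembled
# products. Atoms carry element symbol, formal charge, aromatic flag and a
# placeholder kind: "none" for real atoms, "linker" for named attachment
# points, "ring" for unnamed ring-padding dummies. Hydrogens are implicit
# (hcount), heavy-atom graphs only.

BOND_ORDERS <- c("single", "double", "triple", "aromatic")
BOND_CHAR <- c(single = "-", double = "=", triple = "#", aromatic = ":")
BOND_VALENCE <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# default valences for implicit-H assignment (organic subset)
DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

ATOMIC_WEIGHT <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

new_molgraph <- function(symbol, charge, aromatic, ptype, pname, hcount,
                         bonds) {
  n <- length(symbol)
  stopifnot(
    length(charge) == n, length(aromatic) == n, length(ptype) == n,
    length(pname) == n, length(hcount) == n
  )
  if (nrow(bonds) > 0) {
    swap <- bonds$a > bonds$b
    tmp <- bonds$a[swap]
    bonds$a[swap] <- bonds$b[swap]
    bonds$b[swap] <- tmp
  }
  structure(
    list(
      symbol = as.character(symbol), charge = as.integer(charge),
      aromatic = as.logical(aromatic), ptype = as.character(ptype),
      pname = as.character(pname), hcount = as.integer(hcount),
      bonds = data.frame(
        a = as.integer(bonds$a), b = as.integer(bonds$b),
        order = as.character(bonds$order), stringsAsFactors = FALSE
      )
    ),
    class = "molgraph"
  )
}

#' Number of atoms in a molecular graph (placeholders included)
#' @param mol a molgraph
#' @return integer atom count
#' @export
n_atoms <- function(mol) length(mol$symbol)

#' Heavy atom count of a molecular graph
#'
#' Placeholder (dummy) atoms are excluded: the count reflects real atoms only,
#' so fragment sizes are comparable to the real-atom counts of query
#' substructures.
#' @param mol a molgraph
#' @return integer number of non-placeholder atoms
#' @export
heavy_atom_count <- function(mol) sum(mol$ptype == "none")

is_placeholder <- function(mol) mol$ptype != "none"

#' Validate a molecular graph
#'
#' Checks structural invariants: bond endpoints valid and distinct, linker
#' placeholders named, ring placeholders unnamed, placeholders of degree >= 1.
#' @param mol a molgraph
#' @return invisibly TRUE; errors otherwise
#' @export
validate_mol <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  if (nrow(b) > 0) {
    if (any(b$a < 1 | b$a > n | b$b < 1 | b$b > n)) {
      stop("bond references an atom index out of range")
    }
    if (any(b$a == b$b)) stop("bond connects an atom to itself")
    if (any(!b$order %in% BOND_ORDERS)) stop("unknown bond order")
    if (anyDuplicated(paste(b$a, b$b))) stop("duplicate bond")
  }
  lk <- mol$ptype == "linker"
  if (any(lk & (is.na(mol$pname) | mol$pname == ""))) {
    stop("linker placeholder without a name")
  }
  if (any(mol$ptype == "ring" & !is.na(mol$pname))) {
    stop("ring placeholder must be unnamed")
  }
  ph <- which(is_placeholder(mol))
  if (length(ph) > 0) {
    deg <- atom_degrees(mol)
    if (any(deg[ph] < 1)) stop("placeholder atom with degree 0")
  }
  invisible(TRUE)
}

atom_degrees <- function(mol) {
  deg <- integer(n_atoms(mol))
  if (nrow(mol$bonds) > 0) {
    t1 <- tabulate(mol$bonds$a, nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds$b, nbins = n_atoms(mol))
    deg <- t1 + t2
  }
  deg
}

adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a[k]]] <- c(adj[[b$a[k]]], b$b[k])
    adj[[b$b[k]]] <- c(adj[[b$b[k]]], b$a[k])
  }
  adj
}

# bond index lookup: matrix-free map "a|b" -> row in bonds (a < b)
bond_index_map <- function(mol) {
  b <- mol$bonds
  stats::setNames(seq_len(nrow(b)), paste(b$a, b$b, sep = "|"))
}

bond_between <- function(map, i, j) {
  key <- if (i < j) paste(i, j, sep = "|") else paste(j, i, sep = "|")
  idx <- map[key]
  if (is.na(idx)) NA_integer_ else unname(idx)
}

# connected components; returns integer membership vector
mol_components <- function(mol, drop_bonds = integer(0)) {
  n <- n_atoms(mol)
  b <- mol$bonds
  if (length(drop_bonds) > 0) b <- b[-drop_bonds, , drop = FALSE]
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$a[k]]] <- c(adj[[b$a[k]]], b$b[k])
    adj[[b$b[k]]] <- c(adj[[b$b[k]]], b$a[k])
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

is_connected_mol <- function(mol) {
  n_atoms(mol) == 0 || max(mol_components(mol)) == 1L
}

# bridge detection (Tarjan); returns logical vector over bonds.
# A bond is a bridge iff it lies on no cycle.
mol_bridges <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  adj <- vector("list", n) # each entry: list of c(neighbor, bond index)
  for (i in seq_len(n)) adj[[i]] <- list()
  for (k in seq_len(nb)) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    adj[[a]][[length(adj[[a]]) + 1L]] <- c(b, k)
    adj[[b]][[length(adj[[b]]) + 1L]] <- c(a, k)
  }
  disc <- integer(n); low <- integer(n)
  bridge <- logical(nb)
  timer <- 0L
  # iterative DFS to avoid deep recursion
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, pe = 0L, i = 1L))
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      v <- top$v
      if (top$i <= length(adj[[v]])) {
        ent <- adj[[v]][[top$i]]
        stack[[length(stack)]]$i <- top$i + 1L
        u <- ent[1]; e <- ent[2]
        if (e == top$pe) next
        if (disc[u] != 0L) {
          low[v] <- min(low[v], disc[u])
        } else {
          timer <- timer + 1L
          disc[u] <- low[u] <- timer
          stack[[length(stack) + 1L]] <- list(v = u, pe = e, i = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0) {
          parent <- stack[[length(stack)]]$v
          low[parent] <- min(low[parent], low[v])
          if (low[v] > disc[parent]) bridge[top$pe] <- TRUE
        }
      }
    }
  }
  bridge
}

# ring bonds = non-bridge bonds; ring atoms = atoms on >= 1 ring bond
ring_bonds <- function(mol) !mol_bridges(mol)

ring_atom_flags <- function(mol) {
  rb <- ring_bonds(mol)
  flags <- logical(n_atoms(mol))
  if (any(rb)) {
    flags[unique(c(mol$bonds$a[rb], mol$bonds$b[rb]))] <- TRUE
  }
  flags
}

# incident ring-bond count per atom; used by the SMARTS R<n> heuristic
ring_bond_degree <- function(mol) {
  rb <- ring_bonds(mol)
  deg <- integer(n_atoms(mol))
  if (any(rb)) {
    deg <- tabulate(mol$bonds$a[rb], nbins = n_atoms(mol)) +
      tabulate(mol$bonds$b[rb], nbins = n_atoms(mol))
  }
  deg
}

# ring systems: connected components of the subgraph of ring bonds; returns
# list of atom index vectors
ring_systems <- function(mol) {
  rb <- which(ring_bonds(mol))
  if (length(rb) == 0) return(list())
  keep <- rep(TRUE, nrow(mol$bonds))
  keep[rb] <- FALSE
  comp <- mol_components(mol, drop_bonds = which(keep))
  ratoms <- which(ring_atom_flags(mol))
  split(ratoms, comp[ratoms])
}

implied_hcount <- function(symbol, aromatic, charge, order_sum) {
  vals <- DEFAULT_VALENCE[[symbol]]
  if (is.null(vals)) return(0L)
  # charge shifts the usual valence for N+ (4), O+ (3), etc.
  vals <- vals + charge
  need <- ceiling(order_sum)
  ok <- vals[vals >= need]
  if (length(ok) == 0) return(0L)
  as.integer(ok[1] - need)
}

recompute_implicit_h <- function(mol) {
  n <- n_atoms(mol)
  osum <- numeric(n)
  b <- mol$bonds
  if (nrow(b) > 0) {
    v <- BOND_VALENCE[b$order]
    for (k in seq_len(nrow(b))) {
      osum[b$a[k]] <- osum[b$a[k]] + v[k]
      osum[b$b[k]] <- osum[b$b[k]] + v[k]
    }
  }
  h <- integer(n)
  for (i in seq_len(n)) {
    if (mol$ptype[i] != "none") next
    h[i] <- implied_hcount(mol$symbol[i], mol$aromatic[i], mol$charge[i],
                           osum[i])
  }
  h
}

#' Molecular weight including implicit hydrogens
#' @param mol a molgraph (placeholder atoms contribute nothing)
#' @return numeric weight in Dalton
#' @export
molecular_weight <- function(mol) {
  real <- mol$ptype == "none"
  w <- ATOMIC_WEIGHT[mol$symbol[real]]
  if (any(is.na(w))) stop("no atomic weight for: ",
                          paste(unique(mol$symbol[real][is.na(w)]),
                                collapse = ", "))
  sum(w) + sum(mol$hcount[real]) * ATOMIC_WEIGHT[["H"]]
}

# atom labels used by fingerprints: placeholders are wildcards so that border
# features of fragments can match wildcard-capped query substructures
fp_atom_labels <- function(mol) {
  lab <- ifelse(mol$aromatic, tolower(mol$symbol), mol$symbol)
  chg <- ifelse(mol$charge == 0L, "",
                sprintf("%+d", mol$charge))
  lab <- paste0(lab, chg)
  lab[is_placeholder(mol)] <- "*"
  lab
}

# SMILES parsing ---------------------------------------------------------------

ORGANIC_ALIPHATIC <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
ORGANIC_AROMATIC <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with charge and explicit H
#' counts, aromatic (lowercase) atoms, branches, ring-bond closures (including
#' \code{\%nn}) and dummy atoms. Dummy atoms written \code{[*:n]} become named
#' linker placeholders (linker name \code{"n"}); a bare \code{[*]} becomes an
#' unnamed ring placeholder. Stereochemistry and isotopes are accepted and
#' ignored. Aromaticity is taken as written (no perception/kekulization): all
#' molecules in a workflow must use one consistent aromatic writing style.
#'
#' @param smiles a single SMILES string
#' @return a molgraph
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles)) {
    stop("smiles must be a single string")
  }
  s <- smiles
  nchars <- nchar(s)
  symbol <- character(0); charge <- integer(0); aromatic <- logical(0)
  ptype <- character(0); pname <- character(0); hcount <- integer(0)
  explicit_h <- logical(0)
  ba <- integer(0); bb <- integer(0); bord <- character(0)
  prev_stack <- integer(0)
  prev <- 0L
  pending_bond <- NA_character_
  ring_open <- list() # digit -> list(atom, bond)
  i <- 1L
  fail <- function(msg) {
    stop(sprintf("SMILES parse error at position %d in '%s': %s", i, s, msg))
  }
  add_atom <- function(sym, chg, arom, pt, pn, hc, hx) {
    symbol[length(symbol) + 1L] <<- sym
    charge[length(charge) + 1L] <<- chg
    aromatic[length(aromatic) + 1L] <<- arom
    ptype[length(ptype) + 1L] <<- pt
    pname[length(pname) + 1L] <<- pn
    hcount[length(hcount) + 1L] <<- hc
    explicit_h[length(explicit_h) + 1L] <<- hx
    idx <- length(symbol)
    if (prev > 0L) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (aromatic[prev] && arom) "aromatic" else "single"
      }
      ba[length(ba) + 1L] <<- prev
      bb[length(bb) + 1L] <<- idx
      bord[length(bord) + 1L] <<- ord
    }
    prev <<- idx
    pending_bond <<- NA_character_
    idx
  }
  close_ring <- function(digit) {
    key <- as.character(digit)
    if (!is.null(ring_open[[key]])) {
      opened <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      ord <- pending_bond
      if (!is.na(opened$bond)) {
        if (!is.na(ord) && ord != opened$bond) fail("conflicting ring bond orders")
        ord <- opened$bond
      }
      if (is.na(ord)) {
        ord <- if (aromatic[opened$atom] && aromatic[prev]) "aromatic" else "single"
      }
      if (opened$atom == prev) fail("ring closure to same atom")
      ba[length(ba) + 1L] <<- opened$atom
      bb[length(bb) + 1L] <<- prev
      bord[length(bord) + 1L] <<- ord
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond)
    }
    pending_bond <<- NA_character_
  }
  while (i <= nchars) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, nchars), fixed = TRUE)
      if (j < 0) fail("unclosed bracket atom")
      body <- substr(s, i + 1L, i + j - 2L)
      i <- i + j
      m <- regmatches(body, regexec(
        "^([0-9]*)(\\*|[A-Z][a-z]?|as|se|[bcnops])(@{0,2})(H([0-9]*))?([+-]+[0-9]*|)?(:([0-9]+))?$",
        body))[[1]]
      if (length(m) == 0) fail(paste0("cannot parse bracket atom [", body, "]"))
      sym <- m[3]
      hc <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
      chg_s <- m[7]
      chg <- 0L
      if (!is.na(chg_s) && chg_s != "") {
        sign <- if (substr(chg_s, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", chg_s)
        nsym <- nchar(gsub("[^+-]", "", chg_s))
        chg <- if (digits == "") sign * nsym else sign * as.integer(digits)
      }
      amap <- m[9]
      if (sym == "*") {
        if (!is.na(amap) && amap != "") {
          add_atom("*", 0L, FALSE, "linker", amap, 0L, TRUE)
        } else {
          add_atom("*", 0L, FALSE, "ring", NA_character_, 0L, TRUE)
        }
      } else {
        arom <- sym %in% c(ORGANIC_AROMATIC, "as", "se")
        sym2 <- if (arom) {
          paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
        } else sym
        add_atom(sym2, chg, arom, "none", NA_character_, hc, TRUE)
      }
    } else if (ch == "(") {
      if (prev == 0L) fail("branch with no preceding atom")
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0) fail("unmatched ')'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- switch(ch, "-" = "single", "=" = "double",
                             "#" = "triple", ":" = "aromatic",
                             "/" = "single", "\\" = "single")
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) fail("ring closure before any atom")
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      dd <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", dd)) fail("'%' needs two digits")
      close_ring(dd)
      i <- i + 3L
    } else if (ch == ".") {
      fail("disconnected SMILES ('.') not supported")
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(two, 0L, FALSE, "none", NA_character_, 0L, FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, 0L, FALSE, "none", NA_character_, 0L, FALSE)
        i <- i + 1L
      } else if (ch %in% ORGANIC_AROMATIC) {
        add_atom(toupper(ch), 0L, TRUE, "none", NA_character_, 0L, FALSE)
        i <- i + 1L
      } else {
        fail(paste0("unexpected character '", ch, "'"))
      }
    }
  }
  if (length(ring_open) > 0) fail("unclosed ring bond")
  if (length(prev_stack) > 0) fail("unclosed branch")
  if (length(symbol) == 0) fail("empty SMILES")
  mol <- new_molgraph(symbol, charge, aromatic, ptype, pname, hcount,
                      data.frame(a = ba, b = bb, order = bord,
                                 stringsAsFactors = FALSE))
  # implicit hydrogens for organic-subset atoms written without brackets
  imp <- recompute_implicit_h(mol)
  mol$hcount <- ifelse(explicit_h, mol$hcount, imp)
  validate_mol(mol)
  mol
}

# SMILES writing ---------------------------------------------------------------

smiles_atom_token <- function(mol, i, implied) {
  if (mol$ptype[i] == "linker") return(paste0("[*:", mol$pname[i], "]"))
  if (mol$ptype[i] == "ring") return("[*]")
  sym <- mol$symbol[i]
  disp <- if (mol$aromatic[i]) tolower(sym) else sym
  plain <- mol$charge[i] == 0L && sym %in% ORGANIC_ALIPHATIC &&
    mol$hcount[i] == implied[i] &&
    (!mol$aromatic[i] || tolower(sym) %in% ORGANIC_AROMATIC)
  if (plain) return(disp)
  h <- mol$hcount[i]
  hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  chg <- mol$charge[i]
  cs <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-" else
    sprintf("%+d", chg)
  paste0("[", disp, hs, cs, "]")
}

#' Write a molecular graph as a SMILES string
#'
#' Inverse of \code{\link{parse_smiles}} up to graph isomorphism: the output
#' re-parses to a graph with identical canonical code. With
#' \code{canonical = TRUE} atoms are visited in canonical order so that
#' isomorphic graphs yield identical strings.
#'
#' @param mol a molgraph
#' @param canonical visit atoms in canonical order?
#' @return a SMILES string
#' @export
write_smiles <- function(mol, canonical = FALSE) {
  n <- n_atoms(mol)
  if (n == 0) stop("cannot write an empty molecule")
  if (max(mol_components(mol)) > 1L) stop("molecule must be connected")
  order_rank <- if (canonical) canonical_ranks(mol) else seq_len(n)
  adj <- vector("list", n)
  b <- mol$bonds
  bmap <- bond_index_map(mol)
  for (k in seq_len(nrow(b))) {
    adj[[b$a[k]]] <- c(adj[[b$a[k]]], b$b[k])
    adj[[b$b[k]]] <- c(adj[[b$b[k]]], b$a[k])
  }
  for (i in seq_len(n)) adj[[i]] <- adj[[i]][order(order_rank[adj[[i]]])]
  implied <- recompute_implicit_h(mol)
  # pass 1: recursive spanning DFS; back edges become ring closures
  visited <- logical(n)
  tree_children <- vector("list", n)
  ring_pairs <- list()
  done <- new.env(parent = emptyenv())
  root <- which.min(order_rank)
  dfs <- function(v) {
    visited[v] <<- TRUE
    for (u in adj[[v]]) {
      key <- if (v < u) paste(v, u) else paste(u, v)
      if (!is.null(done[[key]])) next
      assign(key, TRUE, envir = done)
      if (visited[u]) {
        ring_pairs[[length(ring_pairs) + 1L]] <<- c(u, v) # u emitted first
      } else {
        tree_children[[v]] <<- c(tree_children[[v]], u)
        dfs(u)
      }
    }
  }
  dfs(root)
  # assign ring closure digits at both endpoints
  ring_at <- vector("list", n)
  for (di in seq_along(ring_pairs)) {
    rp <- ring_pairs[[di]]
    d <- if (di <= 9L) as.character(di) else paste0("%", sprintf("%02d", di))
    ring_at[[rp[1]]] <- c(ring_at[[rp[1]]], list(list(other = rp[2], d = d)))
    ring_at[[rp[2]]] <- c(ring_at[[rp[2]]], list(list(other = rp[1], d = d)))
  }
  bond_str <- function(i, j) {
    k <- bond_between(bmap, i, j)
    ord <- mol$bonds$order[k]
    both_arom <- mol$aromatic[i] && mol$aromatic[j]
    if (ord == "aromatic") {
      if (both_arom) "" else ":"
    } else if (ord == "single") {
      if (both_arom) "-" else ""
    } else BOND_CHAR[[ord]]
  }
  # pass 2: recursive emit
  emit <- function(v, from) {
    out <- if (from > 0L) bond_str(from, v) else ""
    out <- paste0(out, smiles_atom_token(mol, v, implied))
    for (rc in ring_at[[v]]) {
      out <- paste0(out, bond_str(v, rc$other), rc$d)
    }
    kids <- tree_children[[v]]
    nk <- length(kids)
    for (ki in seq_along(kids)) {
      sub <- emit(kids[ki], v)
      if (ki < nk) out <- paste0(out, "(", sub, ")") else
        out <- paste0(out, sub)
    }
    out
  }
  emit(root, 0L)
}

# Canonical identity ------------------------------------------------------------

canon_atom_labels <- function(mol) {
  paste(fp_atom_labels(mol), mol$hcount,
        ifelse(mol$ptype == "linker", paste0("L", mol$pname), mol$ptype),
        sep = "#")
}

refine_colors <- function(colors, adj_lab) {
  n <- length(colors)
  repeat {
    sigs <- vapply(seq_len(n), function(i) {
      nb <- adj_lab[[i]]
      if (length(nb$nbr) == 0) return(paste0(colors[i], "|"))
      paste0(colors[i], "|",
             paste(sort(paste0(nb$lab, ":", colors[nb$nbr])), collapse = ","))
    }, character(1))
    new_colors <- match(sigs, sort(unique(sigs)))
    if (length(unique(new_colors)) == length(unique(colors))) {
      return(new_colors)
    }
    colors <- new_colors
  }
}

mol_code_for_order <- function(mol, rank) {
  # rank: canonical position of each atom (permutation)
  labs <- canon_atom_labels(mol)
  inv <- order(rank)
  atom_part <- paste(labs[inv], collapse = ",")
  b <- mol$bonds
  if (nrow(b) > 0) {
    ra <- rank[b$a]; rb <- rank[b$b]
    lo <- pmin(ra, rb); hi <- pmax(ra, rb)
    es <- paste0(lo, "-", hi, ":", b$order)
    edge_part <- paste(sort(es), collapse = ";")
  } else edge_part <- ""
  paste0(atom_part, "/", edge_part)
}

canonical_label_search <- function(mol, colors, adj_lab) {
  n <- length(colors)
  if (length(unique(colors)) == n) {
    rank <- match(seq_len(n), order(colors))
    return(list(code = mol_code_for_order(mol, rank), rank = rank))
  }
  # individualize: smallest non-singleton cell with the smallest color
  tab <- table(colors)
  cell_color <- as.integer(names(tab)[tab > 1][1])
  members <- which(colors == cell_color)
  best <- NULL
  for (v in members) {
    c2 <- colors * 2L
    c2[v] <- c2[v] - 1L
    c2 <- match(c2, sort(unique(c2)))
    c2 <- refine_colors(c2, adj_lab)
    res <- canonical_label_search(mol, c2, adj_lab)
    if (is.null(best) || res$code < best$code) best <- res
  }
  best
}

canonical_state <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(list(code = "", rank = integer(0)))
  adj_lab <- rep(list(list(nbr = integer(0), lab = character(0))), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a[k]; j <- b$b[k]
    adj_lab[[i]]$nbr <- c(adj_lab[[i]]$nbr, j)
    adj_lab[[i]]$lab <- c(adj_lab[[i]]$lab, b$order[k])
    adj_lab[[j]]$nbr <- c(adj_lab[[j]]$nbr, i)
    adj_lab[[j]]$lab <- c(adj_lab[[j]]$lab, b$order[k])
  }
  labs <- canon_atom_labels(mol)
  colors <- match(labs, sort(unique(labs)))
  colors <- refine_colors(colors, adj_lab)
  canonical_label_search(mol, colors, adj_lab)
}

#' Canonical structure code of a molecular graph
#'
#' A string invariant under atom reordering: two molgraphs have equal codes
#' iff they are isomorphic with matching element/charge/aromaticity/H-count,
#' placeholder kind and bond orders. Computed by iterative partition
#' refinement with individualization backtracking (exact, no hashing).
#' Used for product deduplication and exact-match lookups.
#'
#' @param mol a molgraph
#' @return a single string
#' @export
canonical_code <- function(mol) canonical_state(mol)$code

canonical_ranks <- function(mol) canonical_state(mol)$rank

#' Canonical SMILES of a molecular graph
#'
#' SMILES written in canonical atom order; equal for isomorphic graphs that
#' use the same aromaticity writing convention.
#' @param mol a molgraph
#' @return a SMILES string
#' @export
canonical_smiles <- function(mol) write_smiles(mol, canonical = TRUE)

# induced subgraph with optional placeholder caps. atoms: original indices;
# caps: data.frame(at = original atom index the cap bonds to, order = bond
# order of the severed bond, name = optional linker name (NA for an unnamed
# wildcard cap)). Returns list(mol, map) with map[original] = new.
induced_subgraph <- function(mol, atoms, caps = NULL) {
  atoms <- sort(unique(as.integer(atoms)))
  map <- integer(n_atoms(mol))
  map[atoms] <- seq_along(atoms)
  b <- mol$bonds
  keep <- b$a %in% atoms & b$b %in% atoms
  nb <- data.frame(a = map[b$a[keep]], b = map[b$b[keep]],
                   order = b$order[keep], stringsAsFactors = FALSE)
  symbol <- mol$symbol[atoms]; charge <- mol$charge[atoms]
  aromatic <- mol$aromatic[atoms]; ptype <- mol$ptype[atoms]
  pname <- mol$pname[atoms]; hcount <- mol$hcount[atoms]
  if (!is.null(caps) && nrow(caps) > 0) {
    for (k in seq_len(nrow(caps))) {
      nm <- if ("name" %in% names(caps)) caps$name[k] else NA_character_
      symbol <- c(symbol, "*"); charge <- c(charge, 0L)
      aromatic <- c(aromatic, FALSE)
      ptype <- c(ptype, if (is.na(nm)) "ring" else "linker")
      pname <- c(pname, nm); hcount <- c(hcount, 0L)
      nb <- rbind(nb, data.frame(a = map[caps$at[k]],
                                 b = length(symbol),
                                 order = caps$order[k],
                                 stringsAsFactors = FALSE))
    }
  }
  list(
    mol = new_molgraph(symbol, charge, aromatic, ptype, pname, hcount, nb),
    map = map
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms (%d heavy), %d bonds\n",
              n_atoms(x), heavy_atom_count(x), nrow(x$bonds)))
  cat("  ", write_smiles(x), "\n", sep = "")
  invisible(x)
}
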