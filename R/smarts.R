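# SMARTS subset -----------------------------------------------------------------
#
# A restricted SMARTS dialect sufficient for substructure marking and
# preservation checks: wildcards, element primitives (aromatic/aliphatic),
# atomic numbers (#n), ring membership (r, R, R<n>), H counts, charges and
# '!' negation combined with ';'/'&' (logical AND); bonds -, =, #, :, ~ and
# the single-or-aromatic default; branches and ring closures. Disjunction
# (','), recursive SMARTS and ring-size primitives are not supported.
#
# R<n> is interpreted heuristically: an atom is "in n rings" when it has at
# least n+1 incident ring bonds (2 for a plain ring atom, 3+ for a fusion
# atom), which covers fused polycyclics without an SSSR computation.

# elements recognised as two-letter symbols inside brackets
TWO_LETTER_ELEMS <- c("Cl", "Br", "Si", "Se", "As", "Li", "Na", "Mg", "Al",
                      "Ca", "Fe", "Zn", "Cu", "Mn", "Sn")

# parse one ';'/'&'-separated bracket part, which may itself concatenate
# several primitives (e.g. "OH", "NH2", "!#1")
smarts_parse_part <- function(txt) {
  prims <- list()
  i <- 1L
  nc <- nchar(txt)
  grab_digits <- function(j) {
    k <- j
    while (k <= nc && grepl("[0-9]", substr(txt, k, k))) k <- k + 1L
    list(num = if (k > j) as.integer(substr(txt, j, k - 1L)) else NA_integer_,
         next_i = k)
  }
  while (i <= nc) {
    neg <- FALSE
    while (i <= nc && substr(txt, i, i) == "!") {
      neg <- !neg
      i <- i + 1L
    }
    if (i > nc) stop("dangling '!' in SMARTS primitive '", txt, "'")
    ch <- substr(txt, i, i)
    two <- substr(txt, i, i + 1L)
    p <- NULL
    if (ch == "*") {
      p <- list(kind = "any"); i <- i + 1L
    } else if (ch == "#") {
      g <- grab_digits(i + 1L)
      if (is.na(g$num)) stop("'#' needs an atomic number in '", txt, "'")
      p <- list(kind = "anum", value = g$num); i <- g$next_i
    } else if (ch == "a") {
      p <- list(kind = "arom"); i <- i + 1L
    } else if (ch == "A") {
      p <- list(kind = "aliph"); i <- i + 1L
    } else if (ch == "r") {
      g <- grab_digits(i + 1L)
      if (!is.na(g$num)) stop("ring-size primitive r<n> is not supported")
      p <- list(kind = "ring"); i <- i + 1L
    } else if (ch == "R") {
      g <- grab_digits(i + 1L)
      p <- list(kind = "ringcount", value = if (is.na(g$num)) 1L else g$num)
      i <- g$next_i
    } else if (ch == "H") {
      g <- grab_digits(i + 1L)
      p <- list(kind = "hcount", value = if (is.na(g$num)) 1L else g$num)
      i <- g$next_i
    } else if (ch %in% c("+", "-")) {
      sign <- if (ch == "+") 1L else -1L
      j <- i + 1L
      reps <- 1L
      while (j <= nc && substr(txt, j, j) == ch) {
        reps <- reps + 1L
        j <- j + 1L
      }
      g <- grab_digits(j)
      chg <- if (!is.na(g$num)) sign * g$num else sign * reps
      p <- list(kind = "charge", value = chg); i <- g$next_i
    } else if (two %in% TWO_LETTER_ELEMS) {
      p <- list(kind = "elem", value = two, aromatic = FALSE); i <- i + 2L
    } else if (grepl("^[A-Z]$", ch)) {
      p <- list(kind = "elem", value = ch, aromatic = FALSE); i <- i + 1L
    } else if (grepl("^[bcnops]$", ch)) {
      p <- list(kind = "elem", value = toupper(ch), aromatic = TRUE)
      i <- i + 1L
    } else {
      stop("unsupported SMARTS primitive '", substr(txt, i, nc),
           "' in '", txt, "'")
    }
    p$neg <- neg
    prims[[length(prims) + 1L]] <- p
  }
  if (length(prims) == 0) stop("empty SMARTS primitive")
  prims
}

#' Parse a SMARTS pattern (restricted dialect)
#'
#' See the package vignette for the supported primitive subset. Unsupported
#' constructs raise an error rather than matching silently.
#' @param smarts a single SMARTS string
#' @return a smarts_pattern object
#' @export
parse_smarts <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1 || is.na(smarts) ||
      smarts == "") {
    stop("smarts must be a single nonempty string")
  }
  s <- smarts
  nchars <- nchar(s)
  atoms <- list()
  ba <- integer(0); bb <- integer(0); btype <- character(0)
  prev_stack <- integer(0)
  prev <- 0L
  pending <- NA_character_
  ring_open <- list()
  i <- 1L
  fail <- function(msg) {
    stop(sprintf("SMARTS parse error at position %d in '%s': %s", i, s, msg))
  }
  add_atom <- function(prims) {
    atoms[[length(atoms) + 1L]] <<- prims
    idx <- length(atoms)
    if (prev > 0L) {
      tp <- if (is.na(pending)) "default" else pending
      ba[length(ba) + 1L] <<- prev
      bb[length(bb) + 1L] <<- idx
      btype[length(btype) + 1L] <<- tp
    }
    prev <<- idx
    pending <<- NA_character_
  }
  close_ring <- function(digit) {
    key <- as.character(digit)
    if (!is.null(ring_open[[key]])) {
      opened <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      tp <- pending
      if (!is.na(opened$bond)) {
        if (!is.na(tp) && tp != opened$bond) fail("conflicting ring bond types")
        tp <- opened$bond
      }
      if (is.na(tp)) tp <- "default"
      ba[length(ba) + 1L] <<- opened$atom
      bb[length(bb) + 1L] <<- prev
      btype[length(btype) + 1L] <<- tp
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pending)
    }
    pending <<- NA_character_
  }
  bond_of <- function(ch) {
    switch(ch, "-" = "single", "=" = "double", "#" = "triple",
           ":" = "aromatic", "~" = "any", NA_character_)
  }
  while (i <= nchars) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, nchars), fixed = TRUE)
      if (j < 0) fail("unclosed bracket atom")
      body <- substr(s, i + 1L, i + j - 2L)
      i <- i + j
      parts <- strsplit(body, "[;&]")[[1]]
      parts <- parts[parts != ""]
      if (length(parts) == 0) fail("empty bracket atom")
      add_atom(do.call(c, lapply(parts, smarts_parse_part)))
    } else if (ch == "(") {
      if (prev == 0L) fail("branch with no preceding atom")
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0) fail("unmatched ')'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- bond_of(ch)
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
    } else if (ch == "*") {
      add_atom(list(list(kind = "any", neg = FALSE)))
      i <- i + 1L
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(list(list(kind = "elem", value = two, aromatic = FALSE,
                           neg = FALSE)))
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(list(list(kind = "elem", value = ch, aromatic = FALSE,
                           neg = FALSE)))
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(list(list(kind = "elem", value = toupper(ch),
                           aromatic = TRUE, neg = FALSE)))
        i <- i + 1L
      } else {
        fail(paste0("unexpected character '", ch, "'"))
      }
    }
  }
  if (length(ring_open) > 0) fail("unclosed ring bond")
  if (length(prev_stack) > 0) fail("unclosed branch")
  if (length(atoms) == 0) fail("no atoms in pattern")
  structure(list(
    atoms = atoms,
    bonds = data.frame(a = ba, b = bb, type = btype,
                       stringsAsFactors = FALSE),
    source = smarts
  ), class = "smarts_pattern")
}

#' @export
print.smarts_pattern <- function(x, ...) {
  cat(sprintf("<smarts_pattern> %s (%d atoms, %d bonds)\n", x$source,
              length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

smarts_atom_ok <- function(prims, ctx, ai) {
  if (ctx$placeholder[ai]) {
    # placeholders only satisfy pure wildcards
    for (p in prims) {
      ok <- p$kind == "any"
      if (p$neg) ok <- !ok
      if (!ok) return(FALSE)
    }
    return(TRUE)
  }
  for (p in prims) {
    ok <- switch(p$kind,
      any = TRUE,
      arom = ctx$aromatic[ai],
      aliph = !ctx$aromatic[ai],
      anum = !is.na(ctx$anum[ai]) && ctx$anum[ai] == p$value,
      ring = ctx$inring[ai],
      ringcount = if (p$value == 0L) !ctx$inring[ai] else
        ctx$ringdeg[ai] >= p$value + 1L,
      hcount = ctx$hcount[ai] == p$value,
      charge = ctx$charge[ai] == p$value,
      elem = ctx$symbol[ai] == p$value && ctx$aromatic[ai] == p$aromatic,
      stop("unknown primitive kind ", p$kind)
    )
    if (p$neg) ok <- !ok
    if (!ok) return(FALSE)
  }
  TRUE
}

smarts_bond_ok <- function(type, order, arom_a, arom_b) {
  switch(type,
    any = TRUE,
    default = order == "aromatic" || order == "single",
    single = order == "single",
    double = order == "double",
    triple = order == "triple",
    aromatic = order == "aromatic"
  )
}

smarts_context <- function(mol) {
  list(
    symbol = mol$symbol,
    aromatic = mol$aromatic,
    charge = mol$charge,
    hcount = mol$hcount,
    inring = ring_atom_flags(mol),
    ringdeg = ring_bond_degree(mol),
    placeholder = is_placeholder(mol),
    anum = unname(ATOMIC_NUMBER[mol$symbol])
  )
}

#' Match a SMARTS pattern against a molecule
#'
#' Backtracking subgraph matching of the restricted SMARTS dialect. Matches
#' are injective assignments of pattern atoms to molecule atoms honouring all
#' pattern bonds.
#'
#' @param mol a molgraph
#' @param pattern a smarts_pattern or SMARTS string
#' @param first_only stop after the first match?
#' @param max_matches cap on the number of matches collected
#' @return list of integer vectors (molecule atom index per pattern atom)
#' @export
smarts_matches <- function(mol, pattern, first_only = FALSE,
                           max_matches = 10000L) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  stopifnot(inherits(pattern, "smarts_pattern"))
  np <- length(pattern$atoms)
  n <- n_atoms(mol)
  if (n == 0 || np > n) return(list())
  ctx <- smarts_context(mol)
  bmap <- bond_index_map(mol)
  adj <- adjacency_list(mol)
  # order pattern atoms so that each after the first touches a placed one
  pb <- pattern$bonds
  placed <- 1L
  order_idx <- 1L
  remaining <- setdiff(seq_len(np), 1L)
  anchors <- list(NULL) # per ordered atom: (prev ordered pos, bond type) list
  while (length(remaining) > 0) {
    found <- FALSE
    for (r in remaining) {
      touch <- which((pb$a == r & pb$b %in% order_idx) |
                     (pb$b == r & pb$a %in% order_idx))
      if (length(touch) > 0) {
        order_idx <- c(order_idx, r)
        remaining <- setdiff(remaining, r)
        found <- TRUE
        break
      }
    }
    if (!found) stop("disconnected SMARTS patterns are not supported")
  }
  pos_of <- match(seq_len(np), order_idx)
  # per ordered position: constraints to earlier positions
  cons <- vector("list", np)
  for (k in seq_len(nrow(pb))) {
    pa <- pos_of[pb$a[k]]; pbq <- pos_of[pb$b[k]]
    hi <- max(pa, pbq); lo <- min(pa, pbq)
    cons[[hi]] <- c(cons[[hi]], list(list(lo = lo, type = pb$type[k])))
  }
  results <- list()
  assign_vec <- integer(np)
  used <- logical(n)
  prims_in_order <- pattern$atoms[order_idx]
  backtrack <- function(pos) {
    if (length(results) >= max_matches) return(TRUE)
    if (pos > np) {
      res <- integer(np)
      res[order_idx] <- assign_vec[seq_len(np)]
      results[[length(results) + 1L]] <<- res
      return(first_only)
    }
    cands <- if (pos == 1L) seq_len(n) else {
      # neighbors of the first anchored earlier atom
      anchor <- cons[[pos]][[1]]$lo
      adj[[assign_vec[anchor]]]
    }
    for (ai in cands) {
      if (used[ai]) next
      if (!smarts_atom_ok(prims_in_order[[pos]], ctx, ai)) next
      ok <- TRUE
      for (cn in cons[[pos]]) {
        bj <- bond_between(bmap, assign_vec[cn$lo], ai)
        if (is.na(bj) ||
            !smarts_bond_ok(cn$type, mol$bonds$order[bj], NA, NA)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign_vec[pos] <<- ai
      used[ai] <<- TRUE
      done <- backtrack(pos + 1L)
      used[ai] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  backtrack(1L)
  results
}

#' Does a molecule contain a SMARTS pattern?
#' @inheritParams smarts_matches
#' @return TRUE/FALSE
#' @export
smarts_match <- function(mol, pattern) {
  length(smarts_matches(mol, pattern, first_only = TRUE)) > 0
}

#' Atoms of a molecule covered by any match of a SMARTS pattern
#' @inheritParams smarts_matches
#' @return sorted integer vector of atom indices (empty when no match)
#' @export
smarts_marked_atoms <- function(mol, pattern) {
  m <- smarts_matches(mol, pattern)
  sort(unique(unlist(m)))
}
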