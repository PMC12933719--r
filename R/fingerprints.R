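# Fingerprints and similarity ---------------------------------------------------
#
# Two sparse count descriptors over molecular graphs:
#   csfpA.B — one feature per connected induced subgraph with between A and B
#             atoms, identified by an exact canonical signature (no hashing).
#   ecfpD   — circular atom environments for radii 0..D/2, identified by a
#             recursively built neighbourhood signature, one feature per
#             (radius, signature) pair.
# Placeholder atoms (fragment linkers, ring dummies, substructure caps)
# participate as wildcard atoms "*" so border features of fragments can match
# the wildcard-capped border features of query substructures.

#' Parse a fingerprint descriptor name
#'
#' Accepts names like \code{"csfp1.4"} (connected subgraphs with 1 to 4
#' atoms; an optional leading \code{"f"} as in \code{"fCSFP2.2"} is ignored)
#' and \code{"ecfp4"} (circular environments with diameter 4).
#' @param descriptor descriptor name string
#' @return a list with \code{type} and size parameters
#' @export
parse_descriptor <- function(descriptor) {
  d <- tolower(descriptor)
  m <- regmatches(d, regexec("^f?csfp([0-9]+)\\.([0-9]+)$", d))[[1]]
  if (length(m) == 3) {
    lo <- as.integer(m[2]); hi <- as.integer(m[3])
    if (lo < 1 || lo > hi) stop("invalid csfp size range in '", descriptor, "'")
    return(list(type = "csfp", min_atoms = lo, max_atoms = hi,
                tag = paste0("csfp", lo, ".", hi)))
  }
  m <- regmatches(d, regexec("^f?ecfp_?([0-9]+)$", d))[[1]]
  if (length(m) == 2) {
    dia <- as.integer(m[2])
    if (dia %% 2 != 0) stop("ecfp diameter must be even in '", descriptor, "'")
    return(list(type = "ecfp", diameter = dia, tag = paste0("ecfp", dia)))
  }
  stop("unknown descriptor '", descriptor,
       "' (expected e.g. 'csfp1.4' or 'ecfp4')")
}

new_molfp <- function(counts, heavy, tag, marked = character(0)) {
  structure(list(counts = counts, heavy = heavy, tag = tag,
                 marked = marked),
            class = "molfp")
}

#' @export
print.molfp <- function(x, ...) {
  cat(sprintf("<molfp %s> %d features, total count %d\n", x$tag,
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Connected-subgraph fingerprint
#'
#' One feature per connected induced subgraph whose atom count (wildcards
#' included) lies in \code{[min_atoms, max_atoms]}; the count of a feature is
#' the number of distinct atom sets mapping to its canonical signature.
#'
#' @param mol a molgraph
#' @param min_atoms,max_atoms inclusive subgraph size bounds (atoms)
#' @param marked optional integer vector of marked atom indices; features with
#'   at least one instance made entirely of marked real atoms are recorded as
#'   the fingerprint's marked feature set
#' @return a molfp: sparse feature -> count map plus per-feature heavy atom
#'   counts (wildcards excluded)
#' @export
compute_csfp <- function(mol, min_atoms, max_atoms, marked = integer(0)) {
  tag <- paste0("csfp", min_atoms, ".", max_atoms)
  n <- n_atoms(mol)
  if (n == 0) {
    return(new_molfp(stats::setNames(integer(0), character(0)),
                     stats::setNames(integer(0), character(0)), tag))
  }
  is_real <- mol$ptype == "none"
  is_marked <- logical(n)
  is_marked[marked] <- TRUE
  res <- cpp_csfp(fp_atom_labels(mol), is_real, is_marked,
                  mol$bonds$a, mol$bonds$b,
                  unname(BOND_CHAR[mol$bonds$order]),
                  as.integer(min_atoms), as.integer(max_atoms))
  counts <- stats::setNames(res$count, res$sig)
  heavy <- stats::setNames(res$heavy, res$sig)
  new_molfp(counts, heavy, tag, marked = res$sig[res$marked > 0])
}

#' Circular (ECFP-like) fingerprint
#'
#' Environment features for every atom at radii 0..diameter/2. Feature
#' identity is an exact recursive neighbourhood signature (element, charge,
#' aromaticity, heavy degree and H count at radius 0; sorted bond+neighbour
#' signatures beyond), prefixed by the radius, so each layer contributes its
#' own features. No folding, no cross-layer deduplication.
#'
#' @param mol a molgraph
#' @param diameter even integer >= 0
#' @inheritParams compute_csfp
#' @return a molfp
#' @export
compute_ecfp <- function(mol, diameter, marked = integer(0)) {
  if (diameter < 0 || diameter %% 2 != 0) {
    stop("diameter must be an even integer >= 0")
  }
  tag <- paste0("ecfp", diameter)
  n <- n_atoms(mol)
  if (n == 0) {
    return(new_molfp(stats::setNames(integer(0), character(0)),
                     stats::setNames(integer(0), character(0)), tag))
  }
  rmax <- diameter %/% 2
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  labs <- fp_atom_labels(mol)
  deg <- atom_degrees(mol)
  init <- ifelse(labs == "*", "*",
                 paste0(labs, "d", deg, "h", mol$hcount))
  is_real <- mol$ptype == "none"
  is_marked <- logical(n)
  is_marked[marked] <- TRUE
  ids <- init
  covered <- lapply(seq_len(n), function(i) i)
  sig <- character(0); cnt <- integer(0); hvy <- integer(0); mkd <- character(0)
  record_layer <- function(r, ids, covered) {
    key <- paste0("r", r, ":", ids)
    for (u in unique(key)) {
      idx <- which(key == u)
      sig <<- c(sig, u)
      cnt <<- c(cnt, length(idx))
      hvy <<- c(hvy, sum(is_real[covered[[idx[1]]]]))
      fully <- vapply(idx, function(i) {
        cov <- covered[[i]]
        all(is_real[cov]) && all(is_marked[cov])
      }, logical(1))
      if (any(fully)) mkd <<- c(mkd, u)
    }
  }
  record_layer(0L, ids, covered)
  r <- 0L
  while (r < rmax) {
    r <- r + 1L
    new_ids <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (length(nb) == 0) return(paste0("(", ids[i], "|)"))
      parts <- vapply(nb, function(u) {
        k <- bond_between(bmap, i, u)
        paste0(BOND_CHAR[[mol$bonds$order[k]]], ids[u])
      }, character(1))
      paste0("(", ids[i], "|", paste(sort(parts), collapse = ","), ")")
    }, character(1))
    new_cov <- lapply(seq_len(n), function(i) {
      sort(unique(c(covered[[i]], unlist(covered[adj[[i]]]))))
    })
    ids <- new_ids
    covered <- new_cov
    record_layer(r, ids, covered)
  }
  counts <- stats::setNames(cnt, sig)
  heavy <- stats::setNames(hvy, sig)
  new_molfp(counts, heavy, tag, marked = unique(mkd))
}

#' Compute a fingerprint by descriptor name
#' @param mol a molgraph
#' @param descriptor descriptor name, see \code{\link{parse_descriptor}}
#' @param marked optional marked atom indices
#' @return a molfp
#' @export
compute_fingerprint <- function(mol, descriptor, marked = integer(0)) {
  d <- parse_descriptor(descriptor)
  if (d$type == "csfp") {
    compute_csfp(mol, d$min_atoms, d$max_atoms, marked = marked)
  } else {
    compute_ecfp(mol, d$diameter, marked = marked)
  }
}

#' Marked feature set of a molecule under an atom marking
#'
#' Returns the feature ids of all fingerprint features that consist entirely
#' of marked atoms (the set M used for weighting). Only features actually
#' present in the molecule's fingerprint are eligible; features containing
#' wildcard atoms are never marked.
#'
#' @param mol a molgraph
#' @param marking integer vector of marked atom indices
#' @param descriptor descriptor name
#' @return character vector of feature ids
#' @export
marked_feature_set <- function(mol, marking, descriptor) {
  marking <- as.integer(marking)
  if (length(marking) > 0 &&
      (min(marking) < 1 || max(marking) > n_atoms(mol))) {
    stop("marking contains invalid atom indices")
  }
  compute_fingerprint(mol, descriptor, marked = marking)$marked
}

#' Feature weighting specification
#'
#' Encodes the weight function over fingerprint features: features in the
#' marked set get weight \code{k} (times the feature's heavy atom count when
#' \code{weight_by_size}), every other feature weight 1. Marked features with
#' fewer than \code{min_feature_size} heavy atoms also get weight 1.
#'
#' @param marked character vector of marked feature ids (the set M)
#' @param k weighting factor, a real >= 1
#' @param min_feature_size smallest feature size (heavy atoms) eligible for
#'   up-weighting
#' @param weight_by_size multiply the weight of each marked feature by its
#'   heavy atom count?
#' @return a feature_weighting object
#' @export
feature_weighting <- function(marked = character(0), k = 1,
                              min_feature_size = 1, weight_by_size = FALSE) {
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k), k >= 1,
            min_feature_size >= 1)
  structure(list(marked = unique(as.character(marked)), k = as.numeric(k),
                 min_feature_size = as.integer(min_feature_size),
                 weight_by_size = isTRUE(weight_by_size)),
            class = "feature_weighting")
}

fp_union_frame <- function(a, b) {
  feats <- union(names(a$counts), names(b$counts))
  ca <- a$counts[feats]; ca[is.na(ca)] <- 0L
  cb <- b$counts[feats]; cb[is.na(cb)] <- 0L
  hv <- a$heavy[feats]
  hb <- b$heavy[feats]
  hv[is.na(hv)] <- hb[is.na(hv)]
  list(feats = feats, a = unname(ca), b = unname(cb), heavy = unname(hv))
}

#' Tanimoto (Ruzicka) similarity of two count fingerprints
#'
#' The count-vector generalization sum(min) / sum(max), ranging from 0 (no
#' common features) to 1 (identity). Two empty fingerprints give 0 by
#' convention.
#'
#' @param a,b molfp objects with the same descriptor tag
#' @return a number in [0, 1]
#' @export
tanimoto <- function(a, b) {
  if (!inherits(a, "molfp") || !inherits(b, "molfp")) {
    stop("tanimoto expects molfp objects")
  }
  if (a$tag != b$tag) {
    stop("descriptor mismatch: '", a$tag, "' vs '", b$tag, "'")
  }
  u <- fp_union_frame(a, b)
  den <- sum(pmax(u$a, u$b))
  if (den == 0) return(0)
  sum(pmin(u$a, u$b)) / den
}

#' Weighted Tanimoto similarity
#'
#' sum(w * min) / sum(w * max) with per-feature weights from a
#' \code{\link{feature_weighting}}. With an empty marked set or k = 1 this is
#' exactly \code{\link{tanimoto}}. Equivalent to the plain Tanimoto computed
#' on fingerprints whose marked entries are replicated k-fold (integer k).
#'
#' @param a,b molfp objects with the same descriptor tag
#' @param wgt a feature_weighting
#' @return a number in [0, 1]
#' @export
weighted_tanimoto <- function(a, b, wgt) {
  if (!inherits(wgt, "feature_weighting")) {
    stop("wgt must be a feature_weighting")
  }
  if (a$tag != b$tag) {
    stop("descriptor mismatch: '", a$tag, "' vs '", b$tag, "'")
  }
  u <- fp_union_frame(a, b)
  w <- rep(1, length(u$feats))
  if (wgt$k > 1 && length(wgt$marked) > 0) {
    hit <- u$feats %in% wgt$marked & u$heavy >= wgt$min_feature_size
    w[hit] <- if (wgt$weight_by_size) wgt$k * u$heavy[hit] else wgt$k
  }
  den <- sum(w * pmax(u$a, u$b))
  if (den == 0) return(0)
  sum(w * pmin(u$a, u$b)) / den
}
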