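#' Path-based hashed chemical fingerprint
#'
#' Enumerates all linear fragments (simple bond paths) of the molecular
#' graph up to \code{max_bonds} bonds, encodes each as an element/bond-order
#' string read in its lexicographically smaller direction, and hashes every
#' distinct fragment onto \code{bits_per_pattern} positions of a
#' \code{length}-bit string. Defaults follow the 1024-bit / 6-bond / 2-bit
#' parameterization used for human-metabolite libraries.
#'
#' @param mol a \code{molecule} or SMILES string.
#' @param length fingerprint length in bits.
#' @param max_bonds maximum fragment length in bonds.
#' @param bits_per_pattern positions set per fragment.
#' @return logical vector of class \code{fingerprint}.
#' @export
compound_fingerprint <- function(mol, length = 1024L, max_bonds = 6L,
                                 bits_per_pattern = 2L) {
  if (is.character(mol)) mol <- mol_from_smiles(mol)
  pats <- linear_fragments(mol, max_bonds)
  bits <- rep(FALSE, length)
  for (p in pats) {
    for (k in seq_len(bits_per_pattern)) {
      bits[1L + str_hash(p, k) %% length] <- TRUE
    }
  }
  structure(bits, class = "fingerprint",
            params = list(length = length, max_bonds = max_bonds,
                          bits_per_pattern = bits_per_pattern))
}

# distinct simple-path strings up to max_bonds bonds
linear_fragments <- function(mol, max_bonds) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(character(0))
  adj <- mol_adjacency(mol)
  elem <- mol$atoms$elem
  out <- new.env(parent = emptyenv())
  walk <- function(path_atoms, path_str, rev_str, depth) {
    canon <- if (path_str <= rev_str) path_str else rev_str
    assign(canon, TRUE, envir = out)
    if (depth >= max_bonds) return()
    a <- path_atoms[length(path_atoms)]
    nb <- adj[[a]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      b <- nb[k, 1]
      if (b %in% path_atoms) next
      o <- nb[k, 2]
      walk(c(path_atoms, b),
           paste0(path_str, o, elem[b]),
           paste0(elem[b], o, rev_str),
           depth + 1L)
    }
  }
  for (a in seq_len(n)) walk(a, elem[a], elem[a], 0L)
  ls(out)
}

# deterministic polynomial string hash (variant k selects the base)
str_hash <- function(s, k = 1L) {
  base <- c(31, 131, 257, 523)[k]
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * base + code) %% 1048573
  h
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint>", sum(x), "of", length(x), "bits set\n")
  invisible(x)
}

#' Tanimoto similarity and dissimilarity of two fingerprints
#'
#' sim = B(a & b) / B(a | b) with B the set-bit count; diss = 1 - sim. Two
#' all-zero fingerprints are identical by convention (sim 1, diss 0).
#'
#' @param a,b equal-length bit vectors.
#' @return list with \code{sim} and \code{diss}.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  u <- sum(a | b)
  sim <- if (u == 0) 1 else sum(a & b) / u
  list(sim = sim, diss = 1 - sim)
}

#' Segmented reaction fingerprint
#'
#' Eight chemical fingerprint sections: slots 1-4 hold the substrate
#' fingerprints, slots 5-8 the product fingerprints, each side sorted by
#' the compounds' structure keys so that participant order does not matter;
#' unused slots are zero vectors. Two reaction fingerprints are compared by
#' Tanimoto over the concatenated bit string.
#'
#' @param substrates,products lists of \code{molecule}s (or SMILES),
#'   cofactors already removed; at most 4 per side.
#' @param ... fingerprint parameters passed to \code{compound_fingerprint}.
#' @return object of class \code{reaction_fingerprint} (list of 8 segments).
#' @export
reaction_fingerprint <- function(substrates, products, ...) {
  as_mols <- function(xs) lapply(xs, function(x)
    if (is.character(x)) mol_from_smiles(x) else x)
  substrates <- as_mols(substrates)
  products <- as_mols(products)
  if (length(substrates) > 4L || length(products) > 4L) {
    stop("more than 4 compounds on one side; exclude cofactors first")
  }
  len <- 1024L
  side <- function(mols) {
    mols <- mols[order(vapply(mols, mol_key, character(1)))]
    fps <- lapply(mols, compound_fingerprint, ...)
    if (length(fps)) len <<- length(fps[[1]])
    c(fps, rep(list(NULL), 4L - length(fps)))
  }
  segs <- c(side(substrates), side(products))
  segs <- lapply(segs, function(s) if (is.null(s)) rep(FALSE, len) else s)
  structure(segs, class = "reaction_fingerprint")
}

#' Tanimoto dissimilarity between two reaction fingerprints
#' @param a,b \code{reaction_fingerprint}s.
#' @return list with \code{sim} and \code{diss} over the concatenation.
#' @export
reaction_tanimoto <- function(a, b) {
  stopifnot(inherits(a, "reaction_fingerprint"),
            inherits(b, "reaction_fingerprint"))
  tanimoto(unlist(a), unlist(b))
}
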