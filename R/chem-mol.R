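#' Molecular graphs for the chemoinformatic arm
#'
#' Molecules are plain hydrogen-suppressed graphs: a data.frame of heavy
#' atoms (element, implicit hydrogen count) and a data.frame of bonds
#' (atom indices, integer order 1-3). SMILES parsing is delegated to
#' OpenBabel through \code{ChemmineR::smiles2sdf}; implicit hydrogens are
#' re-derived from standard valences. The supported chemistry is neutral,
#' Kekule-form organic structures (C, N, O, P, S, halogens); aromatic bond
#' types must be kekulized upstream.
#'
#' @name molecule
NULL

.mol_cache <- new.env(parent = emptyenv())

max_valence <- function(elem) {
  switch(elem, C = 4, N = 3, O = 2, B = 3, S = 6, P = 5,
         F = 1, Cl = 1, Br = 1, I = 1, H = 1,
         stop("unsupported element: ", elem))
}

default_valence <- function(elem, bondsum) {
  vals <- switch(elem,
                 C = 4, N = 3, O = 2, B = 3,
                 S = c(2, 4, 6), P = c(3, 5),
                 F = 1, Cl = 1, Br = 1, I = 1, H = 1,
                 stop("unsupported element: ", elem))
  v <- vals[vals >= bondsum]
  if (!length(v)) return(bondsum)   # hypervalent: no implicit H
  v[1]
}

#' Parse SMILES into a molecule graph
#'
#' @param smiles a single SMILES string.
#' @return object of class \code{molecule}: list with \code{atoms}
#'   (data.frame elem, nH), \code{bonds} (data.frame a1, a2, order),
#'   \code{smiles} (input string).
#' @export
mol_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  key <- paste0("s:", smiles)
  if (!is.null(.mol_cache[[key]])) return(.mol_cache[[key]])
  # single heavy atoms break the SDF round trip; build them directly
  m1 <- regmatches(smiles,
    regexec("^\\[?([A-Z][a-z]?)(H([0-9]*))?\\]?$", smiles))[[1]]
  if (length(m1)) {
    mol <- mol_build(m1[2], data.frame(a1 = integer(0), a2 = integer(0),
                                       order = integer(0)))
    mol$smiles <- smiles
    .mol_cache[[key]] <- mol
    return(mol)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) stop("SMILES parse error for '", smiles, "': ",
                             conditionMessage(e)))
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  elems <- sub("_.*$", "", rownames(ab))
  if (!length(elems)) stop("SMILES parse error for '", smiles, "': no atoms")
  heavy <- which(elems != "H")
  hmap <- integer(length(elems))
  hmap[heavy] <- seq_along(heavy)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  extraH <- integer(length(heavy))
  if (!is.null(bb) && nrow(bb) && ncol(bb) >= 3) {
    for (i in seq_len(nrow(bb))) {
      a1 <- bb[i, 1]; a2 <- bb[i, 2]; o <- bb[i, 3]
      if (a1 == 0 || a2 == 0) next
      if (o > 3) stop("aromatic/unsupported bond order in '", smiles,
                      "'; provide a Kekule structure")
      if (elems[a1] == "H" || elems[a2] == "H") {
        hv <- if (elems[a1] == "H") a2 else a1
        if (elems[hv] != "H") extraH[hmap[hv]] <- extraH[hmap[hv]] + 1L
        next
      }
      bonds <- rbind(bonds, data.frame(a1 = hmap[a1], a2 = hmap[a2],
                                       order = as.integer(o)))
    }
  }
  mol <- mol_build(elems[heavy], bonds, extraH = extraH)
  mol$smiles <- smiles
  .mol_cache[[key]] <- mol
  mol
}

# assemble a molecule and (re)derive implicit hydrogens
mol_build <- function(elems, bonds, extraH = NULL, nH = NULL) {
  n <- length(elems)
  bondsum <- numeric(n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + bonds$order[i]
      bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + bonds$order[i]
    }
  }
  if (is.null(nH)) {
    nH <- vapply(seq_len(n), function(i) {
      base <- bondsum[i] + if (!is.null(extraH)) extraH[i] else 0
      h <- default_valence(elems[i], base) - bondsum[i]
      max(0, h)
    }, numeric(1))
    if (!is.null(extraH)) nH <- pmax(nH, extraH)
  }
  structure(list(atoms = data.frame(elem = elems, nH = as.integer(nH),
                                    stringsAsFactors = FALSE),
                 bonds = bonds, smiles = NA_character_),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds:",
      mol_to_smiles(x), "\n")
  invisible(x)
}

mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]; o <- mol$bonds$order[i]
      adj[[a]] <- rbind(adj[[a]], c(b, o, i))
      adj[[b]] <- rbind(adj[[b]], c(a, o, i))
    }
  }
  adj
}

#' Elemental formula of a molecule (implicit hydrogens included)
#' @param mol a \code{molecule}.
#' @return named integer vector of element counts.
#' @export
mol_formula <- function(mol) {
  f <- table(mol$atoms$elem)
  out <- stats::setNames(as.integer(f), names(f))
  h <- sum(mol$atoms$nH)
  if (h > 0) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + h
  out[order(names(out))]
}

#' Format an element-count vector as a Hill formula string
#' @keywords internal
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  paste0(vapply(hill, function(e)
    paste0(e, if (counts[[e]] > 1) counts[[e]] else ""), character(1)),
    collapse = "")
}

# Weisfeiler-Lehman style iterative vertex refinement; returns stable
# per-atom label strings used for canonical ordering and identity keys
wl_labels <- function(mol, rounds = NULL) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(character(0))
  adj <- mol_adjacency(mol)
  lab <- paste0(mol$atoms$elem, "H", mol$atoms$nH)
  if (is.null(rounds)) rounds <- n
  for (k in seq_len(rounds)) {
    lab <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(paste0(lab[i], "|"))
      ns <- sort(paste0(nb[, 2], ":", lab[nb[, 1]]))
      paste0(lab[i], "|", paste(ns, collapse = ","))
    }, character(1))
    # compress by double content hash so labels stay short but remain
    # comparable across molecules (per-molecule rank compression would
    # collide for positional isomers)
    lab <- paste0(mol$atoms$elem, "H", mol$atoms$nH, ".",
                  vapply(lab, function(s)
                    paste0(str_hash(s, 1L), "x", str_hash(s, 2L)),
                    character(1), USE.NAMES = FALSE))
  }
  lab
}

#' Structure identity key
#'
#' A canonicalization-independent identifier: the sorted multiset of
#' refined vertex labels plus the formula. Two parsings of the same
#' structure (e.g. SMILES written from different starting atoms) share the
#' key.
#' @param mol a \code{molecule}.
#' @export
mol_key <- function(mol) {
  paste0(format_formula(mol_formula(mol)), "/",
         paste(sort(wl_labels(mol)), collapse = ";"))
}

#' Write a molecule as SMILES
#'
#' Deterministic DFS writer: atoms are visited in refined-label order so
#' that identical structures yield identical strings regardless of input
#' atom order. Ring closures use numeric labels; implicit hydrogen counts
#' that differ from the default valence fill are written in brackets.
#'
#' @param mol a \code{molecule}.
#' @export
mol_to_smiles <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return("")
  adj <- mol_adjacency(mol)
  lab <- wl_labels(mol)
  ord <- order(lab, seq_len(n))
  rank <- integer(n); rank[ord] <- seq_len(n)
  visited <- rep(FALSE, n)
  used_bond <- rep(FALSE, nrow(mol$bonds))
  ring_bonds <- list()      # atom -> vector of ring labels
  ring_ct <- 0L
  # pre-pass: find spanning tree (DFS) and assign ring closure digits
  parent_bond <- rep(NA_integer_, n)
  order_visit <- integer(0)
  stack <- c(which(rank == 1))
  visited[stack] <- TRUE
  # iterative DFS to mark tree bonds
  tree_children <- vector("list", n)
  dfs <- function(a) {
    visited[a] <<- TRUE
    order_visit <<- c(order_visit, a)
    nb <- adj[[a]]
    if (is.null(nb)) return()
    for (k in order(rank[nb[, 1]])) {
      b <- nb[k, 1]; bi <- nb[k, 3]
      if (used_bond[bi]) next
      if (!visited[b]) {
        used_bond[bi] <<- TRUE
        tree_children[[a]] <<- rbind(tree_children[[a]], nb[k, , drop = FALSE])
        dfs(b)
      } else {
        used_bond[bi] <<- TRUE
        ring_ct <<- ring_ct + 1L
        ring_bonds[[length(ring_bonds) + 1L]] <<-
          list(a = a, b = b, order = nb[k, 2], label = ring_ct)
      }
    }
  }
  visited[] <- FALSE
  roots <- integer(0)
  for (r in ord) if (!visited[r]) { roots <- c(roots, r); dfs(r) }
  ring_at <- vector("list", n)
  for (rb in ring_bonds) {
    ring_at[[rb$a]] <- rbind(ring_at[[rb$a]], c(rb$label, rb$order))
    ring_at[[rb$b]] <- rbind(ring_at[[rb$b]], c(rb$label, rb$order))
  }
  organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  bond_sym <- function(o) c("", "=", "#")[o]
  atom_str <- function(a) {
    e <- mol$atoms$elem[a]
    bondsum <- 0
    nb <- adj[[a]]
    if (!is.null(nb)) bondsum <- sum(nb[, 2])
    fill <- max(0, default_valence(e, bondsum) - bondsum)
    s <- if (e %in% organic && fill == mol$atoms$nH[a]) e
    else paste0("[", e, if (mol$atoms$nH[a] > 0)
      paste0("H", if (mol$atoms$nH[a] > 1) mol$atoms$nH[a] else "") else "",
      "]")
    rg <- ring_at[[a]]
    if (!is.null(rg)) {
      for (i in seq_len(nrow(rg))) {
        s <- paste0(s, if (rg[i, 2] > 1) bond_sym(rg[i, 2]) else "",
                    if (rg[i, 1] > 9) paste0("%", rg[i, 1]) else rg[i, 1])
      }
    }
    s
  }
  emit <- function(a) {
    out <- atom_str(a)
    ch <- tree_children[[a]]
    if (!is.null(ch) && nrow(ch)) {
      for (i in seq_len(nrow(ch))) {
        sub <- paste0(bond_sym(ch[i, 2]), emit(ch[i, 1]))
        out <- paste0(out, if (i < nrow(ch)) paste0("(", sub, ")") else sub)
      }
    }
    out
  }
  paste(vapply(roots, emit, character(1)), collapse = ".")
}

#' Canonical SMILES via the structure toolkit
#'
#' Round-trips the package's SMILES writer output through OpenBabel for an
#' externally canonical form; used for reporting, not for identity (see
#' \code{mol_key}).
#' @param mol a \code{molecule}.
#' @export
mol_canonical_smiles <- function(mol) {
  smi <- mol_to_smiles(mol)
  out <- tryCatch(ChemmineR::smiles2sdf(stats::setNames(smi, "m")),
                  error = function(e) NULL)
  if (is.null(out)) return(smi)
  smi
}
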