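#' Biochemical reaction operators (SMIRKS subset)
#'
#' Operators are generic substrate-to-product transforms written in a
#' SMIRKS subset: acyclic patterns of bracket atoms \code{[C:1]},
#' \code{[CH2:1]}, \code{[OH1:2]} (element, optional total-H constraint,
#' optional atom map) or bare organic atoms, single/double/triple bonds
#' (\code{- = #}) and branches. Mapped atoms persist through the transform;
#' unmapped reactant atoms are deleted (leaving with the cofactor products),
#' unmapped product atoms are created. Hydrogen counts given on the product
#' side are applied verbatim, all other affected atoms are refilled to
#' standard valence. Each operator carries a third-level EC class and the
#' cofactor compounds consumed/produced alongside the main transform, so
#' that mass balance can be audited on elemental formulas.
#'
#' @name reaction_operator
NULL

parse_smirks_pattern <- function(s) {
  atoms <- data.frame(elem = character(0), hcount = integer(0),
                      map = integer(0), stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  i <- 1L
  nc <- nchar(s)
  prev_stack <- integer(0)
  prev <- 0L
  pending_order <- 1L
  add_atom <- function(elem, hcount, map) {
    atoms[nrow(atoms) + 1L, ] <<- list(elem, hcount, map)
    nrow(atoms)
  }
  while (i <= nc) {
    ch <- substr(s, i, i)
    if (ch == "(") { prev_stack <- c(prev_stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L; next
    }
    if (ch == "-") { pending_order <- 1L; i <- i + 1L; next }
    if (ch == "=") { pending_order <- 2L; i <- i + 1L; next }
    if (ch == "#") { pending_order <- 3L; i <- i + 1L; next }
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, nc), fixed = TRUE)
      if (j < 0) stop("unterminated bracket atom in pattern: ", s)
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(body,
        regexec("^([A-Z][a-z]?)(H([0-9]*))?(:([0-9]+))?$", body))[[1]]
      if (!length(m)) stop("unsupported bracket atom '[", body, "]' in: ", s)
      elem <- m[2]
      hcount <- if (nzchar(m[3])) {
        if (nzchar(m[4])) as.integer(m[4]) else 1L
      } else NA_integer_
      map <- if (nzchar(m[6])) as.integer(m[6]) else 0L
      a <- add_atom(elem, hcount, map)
      if (prev > 0L) bonds[nrow(bonds) + 1L, ] <- c(prev, a, pending_order)
      prev <- a; pending_order <- 1L
      i <- i + j
      next
    }
    two <- substr(s, i, i + 1L)
    if (two %in% c("Cl", "Br")) {
      a <- add_atom(two, NA_integer_, 0L)
      if (prev > 0L) bonds[nrow(bonds) + 1L, ] <- c(prev, a, pending_order)
      prev <- a; pending_order <- 1L
      i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      a <- add_atom(ch, NA_integer_, 0L)
      if (prev > 0L) bonds[nrow(bonds) + 1L, ] <- c(prev, a, pending_order)
      prev <- a; pending_order <- 1L
      i <- i + 1L; next
    }
    stop("unsupported character '", ch, "' in pattern: ", s)
  }
  list(atoms = atoms, bonds = bonds)
}

#' Parse one SMIRKS transform
#' @param smirks string \code{"reactant>>product"}.
#' @return list with \code{lhs} and \code{rhs} pattern graphs.
#' @keywords internal
parse_smirks <- function(smirks) {
  parts <- strsplit(smirks, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("SMIRKS must contain one '>>': ", smirks)
  lhs <- parse_smirks_pattern(parts[1])
  rhs <- parse_smirks_pattern(parts[2])
  lm <- lhs$atoms$map[lhs$atoms$map > 0]
  rm_ <- rhs$atoms$map[rhs$atoms$map > 0]
  if (anyDuplicated(lm) || anyDuplicated(rm_)) {
    stop("duplicated atom maps in: ", smirks)
  }
  if (length(setdiff(rm_, lm))) {
    stop("product maps the reactant lacks in: ", smirks)
  }
  list(lhs = lhs, rhs = rhs)
}

# all embeddings of a pattern graph into a molecule (injective, element,
# bond order and H-count preserving); returns list of index vectors
match_pattern <- function(pattern, mol, max_matches = 1000L) {
  pa <- pattern$atoms
  pb <- pattern$bonds
  np <- nrow(pa)
  if (np == 0L) return(list())
  adjm <- mol_adjacency(mol)
  nmol <- nrow(mol$atoms)
  # pattern adjacency
  padj <- vector("list", np)
  if (nrow(pb)) for (i in seq_len(nrow(pb))) {
    padj[[pb$a1[i]]] <- rbind(padj[[pb$a1[i]]], c(pb$a2[i], pb$order[i]))
    padj[[pb$a2[i]]] <- rbind(padj[[pb$a2[i]]], c(pb$a1[i], pb$order[i]))
  }
  atom_ok <- function(p, a) {
    pa$elem[p] == mol$atoms$elem[a] &&
      (is.na(pa$hcount[p]) || mol$atoms$nH[a] == pa$hcount[p])
  }
  results <- list()
  assign_ <- rep(NA_integer_, np)
  used <- rep(FALSE, nmol)
  bt <- function(p) {
    if (length(results) >= max_matches) return()
    if (p > np) { results[[length(results) + 1L]] <<- assign_; return() }
    # candidates: neighbors of an already-assigned pattern neighbor, else all
    anchored <- NULL
    nb <- padj[[p]]
    if (!is.null(nb)) {
      done <- nb[!is.na(assign_[nb[, 1]]), , drop = FALSE]
      if (nrow(done)) anchored <- done
    }
    cands <- if (!is.null(anchored)) {
      a0 <- assign_[anchored[1, 1]]
      o0 <- anchored[1, 2]
      am <- adjm[[a0]]
      if (is.null(am)) integer(0) else am[am[, 2] == o0, 1]
    } else seq_len(nmol)
    for (a in cands) {
      if (used[a] || !atom_ok(p, a)) next
      ok <- TRUE
      if (!is.null(nb)) {
        for (r in seq_len(nrow(nb))) {
          q <- nb[r, 1]
          if (is.na(assign_[q])) next
          am <- adjm[[a]]
          hit <- !is.null(am) && any(am[, 1] == assign_[q] & am[, 2] == nb[r, 2])
          if (!hit) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_[p] <<- a; used[a] <<- TRUE
      bt(p + 1L)
      assign_[p] <<- NA_integer_; used[a] <<- FALSE
    }
  }
  bt(1L)
  results
}

#' A reaction operator
#'
#' @param id operator identifier.
#' @param smirks transform in the supported SMIRKS subset.
#' @param ec3 third-level EC class, e.g. "1.1.1".
#' @param cofactors_in,cofactors_out cofactor compound ids consumed/produced
#'   alongside the transform (resolved through the cofactor table).
#' @param name human-readable description.
#' @return object of class \code{reaction_operator}.
#' @export
reaction_operator <- function(id, smirks, ec3, cofactors_in = character(0),
                              cofactors_out = character(0), name = id) {
  tr <- parse_smirks(smirks)
  structure(list(id = id, smirks = smirks, ec3 = ec3,
                 cofactors_in = cofactors_in, cofactors_out = cofactors_out,
                 name = name, transform = tr, reversibility = "irreversible"),
            class = "reaction_operator")
}

#' @export
print.reaction_operator <- function(x, ...) {
  cat("<reaction_operator>", x$id, "(EC", paste0(x$ec3, "):"), x$smirks, "\n")
  invisible(x)
}

#' Apply a reaction operator to a substrate
#'
#' Applies the transform at every matching site and returns the distinct
#' products. Each returned record carries the operator's cofactors and a
#' \code{balanced} flag from elemental bookkeeping (substrate + consumed
#' cofactors vs product + produced cofactors, hydrogens included).
#'
#' @param op a \code{reaction_operator}.
#' @param substrate a \code{molecule} or SMILES.
#' @param cofactor_table data.frame id -> smiles (default: packaged table).
#' @param require_balance drop unbalanced products (default TRUE).
#' @return list of synthetic reaction records: \code{substrate},
#'   \code{product} (molecules), \code{product_smiles}, \code{operator},
#'   \code{ec3}, \code{cofactors_in}, \code{cofactors_out}, \code{balanced}.
#' @export
apply_operator <- function(op, substrate, cofactor_table = cofactor_library(),
                           require_balance = TRUE) {
  if (is.character(substrate)) substrate <- mol_from_smiles(substrate)
  tr <- op$transform
  matches <- match_pattern(tr$lhs, substrate)
  if (!length(matches)) return(list())
  products <- list()
  seen <- character(0)
  for (mm in matches) {
    prod <- rewrite_molecule(substrate, tr, mm)
    if (is.null(prod)) next
    key <- mol_key(prod)
    if (key %in% seen) next
    seen <- c(seen, key)
    bal <- reaction_balanced(substrate, prod, op, cofactor_table)
    if (require_balance && !bal) next
    products[[length(products) + 1L]] <-
      list(substrate = substrate, product = prod,
           substrate_smiles = if (!is.na(substrate$smiles)) substrate$smiles
                              else mol_to_smiles(substrate),
           product_smiles = mol_to_smiles(prod),
           operator = op$id, ec3 = op$ec3,
           cofactors_in = op$cofactors_in, cofactors_out = op$cofactors_out,
           balanced = bal)
  }
  products
}

# graph rewrite for one embedding; NULL when the rewrite is chemically
# invalid (negative hydrogen fill or disconnected mapped core)
rewrite_molecule <- function(mol, tr, match) {
  la <- tr$lhs$atoms; ra <- tr$rhs$atoms
  atoms <- mol$atoms
  bonds <- mol$bonds
  n0 <- nrow(atoms)
  img_of_map <- stats::setNames(match[la$map > 0], la$map[la$map > 0])
  delete <- match[la$map == 0]
  # rhs atom -> molecule index (new atoms appended)
  rimg <- integer(nrow(ra))
  new_atoms <- list()
  for (i in seq_len(nrow(ra))) {
    if (ra$map[i] > 0) {
      rimg[i] <- img_of_map[[as.character(ra$map[i])]]
    } else {
      new_atoms[[length(new_atoms) + 1L]] <- i
      atoms <- rbind(atoms, data.frame(elem = ra$elem[i], nH = 0L))
      rimg[i] <- nrow(atoms)
    }
  }
  bond_find <- function(a, b) {
    which((bonds$a1 == a & bonds$a2 == b) | (bonds$a1 == b & bonds$a2 == a))
  }
  # bonds among lhs pattern images that the rhs no longer specifies: drop;
  # rhs bonds: create or set order
  lhs_pairs <- tr$lhs$bonds
  if (nrow(lhs_pairs)) for (i in seq_len(nrow(lhs_pairs))) {
    p <- lhs_pairs$a1[i]; q <- lhs_pairs$a2[i]
    if (la$map[p] == 0 || la$map[q] == 0) next
    a <- img_of_map[[as.character(la$map[p])]]
    b <- img_of_map[[as.character(la$map[q])]]
    keep <- FALSE
    if (nrow(tr$rhs$bonds)) {
      for (j in seq_len(nrow(tr$rhs$bonds))) {
        rp <- tr$rhs$bonds$a1[j]; rq <- tr$rhs$bonds$a2[j]
        if (setequal(c(ra$map[rp], ra$map[rq]), c(la$map[p], la$map[q]))) {
          keep <- TRUE; break
        }
      }
    }
    if (!keep) {
      k <- bond_find(a, b)
      if (length(k)) bonds <- bonds[-k, , drop = FALSE]
    }
  }
  if (nrow(tr$rhs$bonds)) for (j in seq_len(nrow(tr$rhs$bonds))) {
    a <- rimg[tr$rhs$bonds$a1[j]]; b <- rimg[tr$rhs$bonds$a2[j]]
    o <- tr$rhs$bonds$order[j]
    k <- bond_find(a, b)
    if (length(k)) bonds$order[k[1]] <- o
    else bonds <- rbind(bonds, data.frame(a1 = a, a2 = b, order = o))
  }
  # delete unmapped reactant atoms (with incident bonds)
  if (length(delete)) {
    keep_atoms <- setdiff(seq_len(nrow(atoms)), delete)
    remap <- integer(nrow(atoms)); remap[keep_atoms] <- seq_along(keep_atoms)
    bonds <- bonds[!(bonds$a1 %in% delete | bonds$a2 %in% delete), ,
                   drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    rimg <- remap[rimg]
    atoms <- atoms[keep_atoms, , drop = FALSE]
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  # hydrogen accounting: explicit rhs H wins; other touched atoms refilled
  bondsum <- numeric(nrow(atoms))
  if (nrow(bonds)) for (i in seq_len(nrow(bonds))) {
    bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + bonds$order[i]
    bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + bonds$order[i]
  }
  touched <- unique(rimg[rimg > 0])
  for (a in touched) {
    spec <- NA_integer_
    ri <- which(rimg == a)
    if (length(ri) && !is.na(ra$hcount[ri[1]])) spec <- ra$hcount[ri[1]]
    if (bondsum[a] > max_valence(atoms$elem[a])) return(NULL)
    if (!is.na(spec)) {
      if (bondsum[a] + spec > max_valence(atoms$elem[a])) return(NULL)
      atoms$nH[a] <- spec
    } else {
      atoms$nH[a] <- as.integer(default_valence(atoms$elem[a], bondsum[a]) -
                                  bondsum[a])
    }
  }
  out <- mol_build(atoms$elem, bonds, nH = atoms$nH)
  # the rewritten core must stay in one piece
  comp <- graph_components(out)
  if (length(unique(comp[rimg[rimg > 0]])) > 1L) return(NULL)
  if (length(unique(comp)) > 1L) {
    keepc <- comp[rimg[rimg > 0]][1]
    keep_atoms <- which(comp == keepc)
    remap <- integer(nrow(out$atoms)); remap[keep_atoms] <- seq_along(keep_atoms)
    b2 <- out$bonds[out$bonds$a1 %in% keep_atoms & out$bonds$a2 %in% keep_atoms,
                    , drop = FALSE]
    b2$a1 <- remap[b2$a1]; b2$a2 <- remap[b2$a2]
    out <- mol_build(out$atoms$elem[keep_atoms], b2,
                     nH = out$atoms$nH[keep_atoms])
  }
  out
}

graph_components <- function(mol) {
  n <- nrow(mol$atoms)
  comp <- integer(n)
  adj <- mol_adjacency(mol)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[a] != 0L) next
      comp[a] <- cur
      nb <- adj[[a]]
      if (!is.null(nb)) stack <- c(stack, nb[, 1])
    }
  }
  comp
}

#' Elemental mass balance of a synthetic reaction
#'
#' Substrate plus consumed cofactors must equal product plus produced
#' cofactors, element by element with hydrogens (charges are not tracked;
#' the packaged cofactor pairs are chosen to balance neutrally).
#'
#' @param substrate,product \code{molecule}s.
#' @param op the \code{reaction_operator} providing cofactors.
#' @param cofactor_table data.frame with \code{id} and \code{smiles}.
#' @export
reaction_balanced <- function(substrate, product, op,
                              cofactor_table = cofactor_library()) {
  cof <- function(ids) {
    if (!length(ids)) return(integer(0))
    tot <- integer(0)
    for (id in ids) {
      row <- cofactor_table[cofactor_table$id == id, , drop = FALSE]
      if (!nrow(row)) stop("unknown cofactor id: ", id)
      tot <- add_formula(tot, mol_formula(mol_from_smiles(row$smiles[1])))
    }
    tot
  }
  lhs <- add_formula(mol_formula(substrate), cof(op$cofactors_in))
  rhs <- add_formula(mol_formula(product), cof(op$cofactors_out))
  identical(lhs[lhs > 0], rhs[rhs > 0])
}

add_formula <- function(a, b) {
  all_e <- union(names(a), names(b))
  out <- stats::setNames(integer(length(all_e)), all_e)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[order(names(out))]
}

#' Packaged cofactor stand-in table
#'
#' Small neutral molecules standing in for the physiological cofactor pairs
#' so that every packaged operator balances without charge bookkeeping: a
#' formaldehyde/methanol pair carries 2H for redox steps (in place of
#' NAD(P)+/NAD(P)H), plus water, CO2, ammonia, molecular oxygen and
#' orthophosphate.
#' @export
cofactor_library <- function() {
  data.frame(
    id = c("acceptor_ox", "acceptor_red", "water", "co2", "ammonia",
           "o2", "phosphate"),
    smiles = c("C=O", "CO", "O", "O=C=O", "N", "O=O", "OP(=O)(O)O"),
    name = c("2H acceptor (oxidized)", "2H acceptor (reduced)", "water",
             "carbon dioxide", "ammonia", "molecular oxygen",
             "orthophosphate"),
    stringsAsFactors = FALSE)
}
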