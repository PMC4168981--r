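#' Load a reaction-operator library from SMIRKS text
#'
#' One operator per row: id, smirks, ec3, cofactors_in, cofactors_out
#' (comma-joined ids, "-" for none), name. The packaged curated library
#' (12 operators covering redox, hydration/dehydration, decarboxylation,
#' amination/deamination, phosphorylation and hydroxylation chemistry) is
#' returned when \code{path} is missing; user libraries in the same format
#' are accepted.
#'
#' @param path TSV file; default the packaged library.
#' @return list of \code{reaction_operator}s.
#' @export
read_operator_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bro_operators.tsv", package = "oncoflux")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "bro_operators.tsv")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split_ids <- function(x) {
    if (is.na(x) || x == "-" || !nzchar(x)) character(0)
    else strsplit(x, ",", fixed = TRUE)[[1]]
  }
  ops <- lapply(seq_len(nrow(tab)), function(i) {
    reaction_operator(tab$id[i], tab$smirks[i], tab$ec3[i],
                      cofactors_in = split_ids(tab$cofactors_in[i]),
                      cofactors_out = split_ids(tab$cofactors_out[i]),
                      name = tab$name[i])
  })
  stats::setNames(ops, tab$id)
}

#' Select candidate substrates from a compound library
#'
#' Keeps library compounds whose fingerprint Tanimoto dissimilarity to the
#' native substrate is at most \code{tc_cutoff}, excluding the native
#' substrate itself (structure identity) and any configured cofactors.
#'
#' @param native \code{molecule} or SMILES of the native substrate.
#' @param library data.frame with columns \code{compound} and \code{smiles}.
#' @param tc_cutoff dissimilarity cutoff in [0, 1].
#' @param exclude compound ids to drop (cofactors).
#' @return the library rows retained, with a \code{tcdiss} column, sorted.
#' @export
select_candidates <- function(native, library, tc_cutoff,
                              exclude = character(0)) {
  if (!nrow(library)) stop("empty compound library")
  if (is.character(native)) native <- mol_from_smiles(native)
  fp0 <- compound_fingerprint(native)
  key0 <- mol_key(native)
  keep <- !(library$compound %in% exclude)
  lib <- library[keep, , drop = FALSE]
  lib$tcdiss <- vapply(lib$smiles, function(s)
    tanimoto(fp0, compound_fingerprint(s))$diss, numeric(1))
  self <- vapply(lib$smiles, function(s) mol_key(mol_from_smiles(s)) == key0,
                 logical(1))
  lib <- lib[!self & lib$tcdiss <= tc_cutoff, , drop = FALSE]
  lib <- lib[order(lib$tcdiss, lib$compound), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Enumerate synthetic reactions from candidates and operators
#'
#' Cross product of candidate substrates and operators, expanded over all
#' matching sites, mass-balance filtered, and deduplicated by (substrate
#' structure, product structure, EC3). When the enumeration for one native
#' reaction would exceed \code{max_activities}, the native reaction is
#' excluded from the analysis and reported (large/complex compounds
#' generate combinatorial activity explosions).
#'
#' @param candidates data.frame with \code{compound} and \code{smiles}.
#' @param operators list of \code{reaction_operator}s.
#' @param max_activities cap per native reaction (default 30000).
#' @return list with \code{reactions} (list of synthetic-reaction records)
#'   and \code{capped} (logical: cap exceeded, enumeration discarded).
#' @export
enumerate_synthetic_reactions <- function(candidates, operators,
                                          max_activities = 30000) {
  if (!nrow(candidates)) stop("no candidate substrates")
  out <- list()
  seen <- character(0)
  capped <- FALSE
  for (i in seq_len(nrow(candidates))) {
    sub <- mol_from_smiles(candidates$smiles[i])
    for (op in operators) {
      prods <- apply_operator(op, sub)
      for (p in prods) {
        key <- paste(mol_key(p$substrate), mol_key(p$product), p$ec3,
                     sep = ">>")
        if (key %in% seen) next
        seen <- c(seen, key)
        p$compound <- candidates$compound[i]
        out[[length(out) + 1L]] <- p
        if (length(out) > max_activities) {
          return(list(reactions = list(), capped = TRUE,
                      n_enumerated = length(out)))
        }
      }
    }
  }
  list(reactions = out, capped = capped, n_enumerated = length(out))
}

#' Call gain-of-function promiscuity pairs
#'
#' Compares each synthetic reaction with the native reaction at the
#' reaction-fingerprint level and saves pairs whose Tanimoto dissimilarity
#' is at most the cutoff (low dissimilarity = structurally plausible
#' promiscuous activity). The default cutoff is calibrated at run time from
#' the canonical neomorphic case: the dissimilarity between the packaged
#' isocitrate-oxidation reaction and the alpha-ketoglutarate ->
#' 2-hydroxyglutarate reduction, plus a configured margin.
#'
#' @param native list with \code{substrates} and \code{products} (SMILES or
#'   molecules, cofactors excluded).
#' @param synthetic list of synthetic-reaction records from
#'   \code{enumerate_synthetic_reactions}.
#' @param reaction_tc_cutoff dissimilarity cutoff; \code{NULL} uses the
#'   calibrated default.
#' @param margin added to the calibration dissimilarity when deriving the
#'   default cutoff.
#' @return data.frame with \code{compound}, \code{operator}, \code{ec3},
#'   \code{substrate}, \code{product}, \code{substrate_tcdiss},
#'   \code{reaction_tcdiss}; attribute \code{"cutoff"}.
#' @export
call_gof_pairs <- function(native, synthetic, reaction_tc_cutoff = NULL,
                           margin = 0.05) {
  rfp_native <- reaction_fingerprint(native$substrates, native$products)
  if (!any(unlist(rfp_native))) stop("degenerate native reaction fingerprint")
  if (is.null(reaction_tc_cutoff)) {
    reaction_tc_cutoff <- gof_calibration_cutoff(margin)
  }
  nat_sub_fp <- lapply(native$substrates, compound_fingerprint)
  rows <- lapply(synthetic, function(sr) {
    rfp <- reaction_fingerprint(list(sr$substrate), list(sr$product))
    rd <- reaction_tanimoto(rfp_native, rfp)$diss
    sfp <- compound_fingerprint(sr$substrate)
    sd_ <- min(vapply(nat_sub_fp, function(f) tanimoto(f, sfp)$diss,
                      numeric(1)))
    data.frame(compound = if (!is.null(sr$compound)) sr$compound else NA,
               operator = sr$operator, ec3 = sr$ec3,
               substrate = sr$substrate_smiles, product = sr$product_smiles,
               substrate_tcdiss = sd_, reaction_tcdiss = rd,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- tab[tab$reaction_tcdiss <= reaction_tc_cutoff, , drop = FALSE]
  out <- out[order(out$reaction_tcdiss), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- reaction_tc_cutoff
  out
}

#' Calibrated reaction-dissimilarity cutoff from the IDH-analog pair
#'
#' Computes TCdiss between the packaged native isocitrate ->
#' alpha-ketoglutarate oxidation and the neomorphic alpha-ketoglutarate ->
#' 2-hydroxyglutarate reduction (both without cofactors), and adds the
#' margin.
#' @param margin slack above the calibration dissimilarity.
#' @export
gof_calibration_cutoff <- function(margin = 0.05) {
  lib <- generate_compound_library()
  smi <- stats::setNames(lib$smiles, lib$compound)
  nat <- reaction_fingerprint(list(smi[["isocitrate"]]),
                              list(smi[["alpha_ketoglutarate"]]))
  neo <- reaction_fingerprint(list(smi[["alpha_ketoglutarate"]]),
                              list(smi[["2_hydroxyglutarate"]]))
  min(1, reaction_tanimoto(nat, neo)$diss + margin)
}

#' Maximum common substructure of two molecules
#'
#' Largest connected common subgraph (matching elements and bond orders,
#' hydrogen counts ignored), found by backtracking over atom
#' correspondences with a best-so-far bound.
#'
#' @param a,b \code{molecule}s.
#' @return a \code{molecule} representing the common subgraph pattern
#'   (hydrogens zeroed), or NULL when no common atom exists.
#' @export
mcs_pair <- function(a, b) {
  if (nrow(a$atoms) > nrow(b$atoms)) { tmp <- a; a <- b; b <- tmp }
  na <- nrow(a$atoms)
  adja <- mol_adjacency(a); adjb <- mol_adjacency(b)
  best <- list(size = 0L, map = NULL)
  nodes <- 0L
  node_cap <- 200000L
  # grow connected mappings from every seed pair; map entries: NA = open,
  # -1 = excluded in this branch, >0 = matched b-atom
  grow <- function(map) {
    nodes <<- nodes + 1L
    if (nodes > node_cap) return()
    size <- sum(!is.na(map) & map > 0L)
    if (size > best$size) best <<- list(size = size, map = map)
    if (size + sum(is.na(map)) <= best$size) return()
    # frontier: open a-atoms adjacent to matched ones
    frontier <- integer(0)
    for (i in which(!is.na(map) & map > 0L)) {
      nb <- adja[[i]]
      if (!is.null(nb)) frontier <- c(frontier, nb[is.na(map[nb[, 1]]), 1])
    }
    frontier <- unique(frontier)
    if (!length(frontier)) return()
    p <- frontier[1]
    nb <- adja[[p]]
    matched_nb <- nb[!is.na(map[nb[, 1]]) & map[nb[, 1]] > 0L, , drop = FALSE]
    cands <- integer(0)
    if (nrow(matched_nb)) {
      bm <- adjb[[map[matched_nb[1, 1]]]]
      if (!is.null(bm)) cands <- bm[bm[, 2] == matched_nb[1, 2], 1]
    }
    taken <- map[!is.na(map) & map > 0L]
    for (cnd in cands) {
      if (cnd %in% taken) next
      if (b$atoms$elem[cnd] != a$atoms$elem[p]) next
      ok <- TRUE
      for (r in seq_len(nrow(matched_nb))) {
        q <- matched_nb[r, 1]
        bmq <- adjb[[cnd]]
        hit <- !is.null(bmq) && any(bmq[, 1] == map[q] & bmq[, 2] == matched_nb[r, 2])
        if (!hit) { ok <- FALSE; break }
      }
      if (!ok) next
      map[p] <- cnd
      grow(map)
      map[p] <- NA_integer_
    }
    # also consider never mapping p (prune it from this branch)
    map[p] <- -1L
    grow(map)
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nrow(b$atoms))) {
      if (a$atoms$elem[i] != b$atoms$elem[j]) next
      map <- rep(NA_integer_, na)
      map[i] <- j
      grow(map)
    }
  }
  if (best$size < 1L) return(NULL)
  sel <- which(!is.na(best$map) & best$map > 0)
  remap <- integer(na); remap[sel] <- seq_along(sel)
  bonds <- a$bonds[a$bonds$a1 %in% sel & a$bonds$a2 %in% sel, , drop = FALSE]
  # keep only bonds present in b as well
  adjb_ok <- vapply(seq_len(nrow(bonds)), function(k) {
    bm <- adjb[[best$map[bonds$a1[k]]]]
    !is.null(bm) && any(bm[, 1] == best$map[bonds$a2[k]] &
                        bm[, 2] == bonds$order[k])
  }, logical(1))
  bonds <- bonds[adjb_ok, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  mol_build(a$atoms$elem[sel], bonds, nH = rep(0L, length(sel)))
}

#' Dominant common substructure of a compound set
#'
#' Greedy multi-way MCS: starts from the two most similar compounds
#' (fingerprint Tanimoto), folds in the remaining compounds one at a time,
#' and reports the final pattern with its support (fraction of compounds
#' containing it). Dominant when support reaches \code{support_threshold}
#' and the pattern has at least \code{min_atoms} atoms.
#'
#' @param compounds list of \code{molecule}s or SMILES (>= 1).
#' @param support_threshold dominance support (default 0.5).
#' @param min_atoms minimum pattern size (default 3).
#' @return list with \code{pattern} (molecule or NULL), \code{smiles},
#'   \code{support}, \code{dominant}, \code{degenerate}.
#' @export
dominant_substructure <- function(compounds, support_threshold = 0.5,
                                  min_atoms = 3L) {
  mols <- lapply(compounds, function(x)
    if (is.character(x)) mol_from_smiles(x) else x)
  if (length(mols) == 0L) stop("no compounds")
  if (length(mols) == 1L) {
    return(list(pattern = mols[[1]], smiles = mol_to_smiles(mols[[1]]),
                support = 1, dominant = TRUE, degenerate = TRUE))
  }
  fps <- lapply(mols, compound_fingerprint)
  k <- length(mols)
  best <- c(1L, 2L); best_sim <- -1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- tanimoto(fps[[i]], fps[[j]])$sim
    if (s > best_sim) { best_sim <- s; best <- c(i, j) }
  }
  pattern <- mcs_pair(mols[[best[1]]], mols[[best[2]]])
  for (i in setdiff(seq_len(k), best)) {
    if (is.null(pattern)) break
    pattern <- mcs_pair(pattern, mols[[i]])
  }
  if (is.null(pattern) || nrow(pattern$atoms) == 0L) {
    return(list(pattern = NULL, smiles = NA_character_, support = 0,
                dominant = FALSE, degenerate = FALSE))
  }
  pat_query <- list(atoms = data.frame(elem = pattern$atoms$elem,
                                       hcount = NA_integer_,
                                       map = 0L, stringsAsFactors = FALSE),
                    bonds = pattern$bonds)
  support <- mean(vapply(mols, function(m)
    length(match_pattern(pat_query, m, max_matches = 1L)) > 0, logical(1)))
  list(pattern = pattern, smiles = mol_to_smiles(pattern), support = support,
       dominant = support >= support_threshold &&
         nrow(pattern$atoms) >= min_atoms,
       degenerate = FALSE)
}

#' Run the gain-of-function arm for one native reaction
#'
#' Candidate selection around the native substrates, operator enumeration,
#' promiscuity-pair calling at the calibrated cutoff, and substructure
#' summaries of the called substrates and products.
#'
#' @param native list with \code{substrates}, \code{products} (SMILES).
#' @param library compound library data.frame (\code{compound},
#'   \code{smiles}).
#' @param operators operator list (default packaged).
#' @param tc_cutoff substrate-level candidate cutoff.
#' @param reaction_tc_cutoff pair-calling cutoff (NULL = calibrated).
#' @param max_activities enumeration cap.
#' @return list with \code{candidates}, \code{synthetic}, \code{pairs},
#'   \code{substrate_summary}, \code{product_summary}, \code{capped}.
#' @export
run_gof_arm <- function(native, library,
                        operators = read_operator_library(),
                        tc_cutoff = 0.6, reaction_tc_cutoff = NULL,
                        max_activities = 30000) {
  cands <- do.call(rbind, lapply(native$substrates, function(s)
    select_candidates(s, library, tc_cutoff)))
  cands <- cands[!duplicated(cands$compound), , drop = FALSE]
  if (!nrow(cands)) {
    return(list(candidates = cands, synthetic = list(),
                pairs = NULL, capped = FALSE))
  }
  enum <- enumerate_synthetic_reactions(cands, operators, max_activities)
  if (enum$capped) {
    return(list(candidates = cands, synthetic = list(), pairs = NULL,
                capped = TRUE, n_enumerated = enum$n_enumerated))
  }
  pairs <- call_gof_pairs(native, enum$reactions, reaction_tc_cutoff)
  subs_sum <- prods_sum <- NULL
  if (nrow(pairs) >= 1L) {
    subs_sum <- dominant_substructure(unique(pairs$substrate))
    prods_sum <- dominant_substructure(unique(pairs$product))
  }
  list(candidates = cands, synthetic = enum$reactions, pairs = pairs,
       substrate_summary = subs_sum, product_summary = prods_sum,
       capped = FALSE)
}
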