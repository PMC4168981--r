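test_that("fingerprints canonicalize, stay within length and see structure", {
  f1 <- compound_fingerprint("CCO")
  f2 <- compound_fingerprint("OCC")
  f3 <- compound_fingerprint("C(O)C")
  expect_identical(as.logical(f1), as.logical(f2))
  expect_identical(as.logical(f1), as.logical(f3))
  expect_length(f1, 1024)
  f_methane <- compound_fingerprint("C")
  expect_gt(sum(f_methane), 0)
  expect_lt(sum(f_methane), 10)            # sparse single-atom pattern
  expect_lte(sum(compound_fingerprint("OCC1OC(O)C(O)C(O)C1O")), 1024)
  expect_error(compound_fingerprint("not a smiles ((("), "parse")
})

test_that("tanimoto matches the bit-loop oracle and its axioms", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  got <- tanimoto(a, b)
  expect_equal(got$sim, 1 / 3)
  expect_equal(got$diss, 2 / 3)
  expect_equal(tanimoto(a, a)$diss, 0)
  expect_equal(tanimoto(logical(8), logical(8))$sim, 1)
  expect_error(tanimoto(a, b[1:3]), "length")
  set.seed(7)
  for (k in 1:20) {
    x <- runif(64) < 0.3
    y <- runif(64) < 0.3
    want <- oracle_tanimoto(x, y)
    got <- tanimoto(x, y)
    expect_identical(got$sim, want$sim)
    expect_equal(got$sim + got$diss, 1)
    expect_identical(got$sim, tanimoto(y, x)$sim)
  }
})

test_that("reaction fingerprints have 8 sorted segments", {
  rf1 <- reaction_fingerprint(list("CCO", "CC(=O)O"), list("CCOC(=O)C"))
  rf2 <- reaction_fingerprint(list("CC(=O)O", "CCO"), list("CCOC(=O)C"))
  expect_length(rf1, 8)
  expect_identical(unlist(rf1), unlist(rf2))   # substrate order irrelevant
  # product-side difference is confined to product slots
  rfA <- reaction_fingerprint(list("CCO"), list("CCC=O"))
  rfB <- reaction_fingerprint(list("CCO"), list("CCCC=O"))
  expect_identical(unlist(rfA[1:4]), unlist(rfB[1:4]))
  expect_false(identical(unlist(rfA[5:8]), unlist(rfB[5:8])))
  expect_gt(reaction_tanimoto(rfA, rfB)$diss, 0)
  # empty product side -> zero vectors
  rf0 <- reaction_fingerprint(list("CCO"), list())
  expect_false(any(unlist(rf0[5:8])))
  expect_error(reaction_fingerprint(as.list(rep("C", 5)), list("C")),
               "cofactors")
})

test_that("candidate selection honors the cutoff limits", {
  lib <- generate_compound_library()
  akg <- lib$smiles[lib$compound == "alpha_ketoglutarate"]
  # cutoff 0: only exact structural matches (none besides itself -> empty)
  expect_equal(nrow(select_candidates(akg, lib, tc_cutoff = 0)), 0)
  # cutoff 1: whole library minus the native itself and exclusions
  all_ <- select_candidates(akg, lib, tc_cutoff = 1)
  expect_equal(nrow(all_), nrow(lib) - 1)
  excl <- select_candidates(akg, lib, tc_cutoff = 1,
                            exclude = c("urea", "glycerol"))
  expect_equal(nrow(excl), nrow(lib) - 3)
  # planted analog ranks above the decoys at an intermediate cutoff
  mid <- select_candidates(akg, lib, tc_cutoff = 0.5)
  expect_true("2_hydroxyglutarate" %in% mid$compound)
  expect_false(any(c("hexanol", "ethanolamine", "urea", "glycerol",
                     "isopropanol", "ribitol") %in% mid$compound))
  expect_lt(mid$tcdiss[mid$compound == "2_hydroxyglutarate"],
            min(mid$tcdiss[mid$compound %in% c("octanoate")], 1))
  expect_error(select_candidates(akg, lib[0, ], 0.5), "empty")
})

test_that("operators transform canonical cases with balanced cofactors", {
  ops <- read_operator_library()
  # secondary alcohol oxidation: isopropanol -> acetone
  r <- apply_operator(ops$alcohol_ox_sec, "CC(C)O")
  expect_length(r, 1)
  expect_equal(mol_key(r[[1]]$product), mol_key(mol_from_smiles("CC(=O)C")))
  expect_true(r[[1]]$balanced)
  expect_equal(r[[1]]$cofactors_in, "acceptor_ox")
  # no match on an alkane
  expect_length(apply_operator(ops$alcohol_ox_sec, "CCCC"), 0)
  # two inequivalent alcohol sites give two distinct ketones
  r2 <- apply_operator(ops$alcohol_ox_sec, "CCC(O)CC(C)O")
  expect_length(r2, 2)
  expect_length(unique(vapply(r2, function(x) mol_key(x$product),
                              character(1))), 2)
  # ketone reduction of the 2-oxo acid yields the 2-hydroxy analog
  r3 <- apply_operator(ops$ketone_red, "OC(=O)CCC(=O)C(=O)O")
  expect_true(mol_key(mol_from_smiles("OC(=O)CCC(O)C(=O)O")) %in%
              vapply(r3, function(x) mol_key(x$product), character(1)))
  # hydration of a fumarate-like alkene gives the malate-like alcohol
  r4 <- apply_operator(ops$alkene_hydration, "OC(=O)C=CC(=O)O")
  expect_true(mol_key(mol_from_smiles("OC(=O)CC(O)C(=O)O")) %in%
              vapply(r4, function(x) mol_key(x$product), character(1)))
})

test_that("mass balance agrees with the independent formula oracle", {
  ops <- read_operator_library()
  cof <- cofactor_library()
  subs <- c("CC(C)O", "CCO", "CC=O", "OC(=O)C=CC(=O)O", "CC(=O)C(=O)O",
            "CCCC(=O)O", "CC(N)C")
  n_checked <- 0
  for (op in ops) {
    for (s in subs) {
      for (p in apply_operator(op, s, require_balance = FALSE)) {
        lhs <- oracle_formula(s)
        for (id in p$cofactors_in) {
          lhs <- paste0(lhs, "+", oracle_formula(cof$smiles[cof$id == id]))
        }
        rhs <- oracle_formula(p$product_smiles)
        for (id in p$cofactors_out) {
          rhs <- paste0(rhs, "+", oracle_formula(cof$smiles[cof$id == id]))
        }
        # element-count both sides with a regex tally
        tally <- function(x) {
          out <- new.env()
          for (f in strsplit(x, "+", fixed = TRUE)[[1]]) {
            for (m in regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]) {
              el <- gsub("[0-9]", "", m)
              ct <- gsub("[^0-9]", "", m)
              ct <- if (nzchar(ct)) as.integer(ct) else 1L
              prev <- mget(el, envir = out, ifnotfound = 0L)[[1]]
              assign(el, prev + ct, envir = out)
            }
          }
          unlist(mget(ls(out), envir = out))
        }
        want_balanced <- identical(tally(lhs), tally(rhs))
        expect_identical(p$balanced, want_balanced)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 15)
})

test_that("enumeration deduplicates and enforces the activity cap", {
  ops <- read_operator_library()
  cands <- data.frame(compound = c("diol", "butanol"),
                      smiles = c("CCC(O)CC(C)O", "CCCCO"),
                      stringsAsFactors = FALSE)
  enum <- enumerate_synthetic_reactions(cands, ops[c("alcohol_ox_sec",
                                                     "alcohol_ox_prim")])
  expect_false(enum$capped)
  keys <- vapply(enum$reactions, function(r)
    paste(mol_key(r$substrate), mol_key(r$product), r$ec3), character(1))
  expect_false(anyDuplicated(keys) > 0)
  # same product through two operators with the same ec3 collapses
  expect_lte(length(enum$reactions), 3)
  capped <- enumerate_synthetic_reactions(cands, ops, max_activities = 2)
  expect_true(capped$capped)
  expect_length(capped$reactions, 0)
  expect_error(enumerate_synthetic_reactions(cands[0, ], ops), "candidate")
})

test_that("GoF pair calling saves the planted neomorphic pair", {
  lib <- generate_compound_library()
  smi <- stats::setNames(lib$smiles, lib$compound)
  native <- list(substrates = list(smi[["isocitrate"]]),
                 products = list(smi[["alpha_ketoglutarate"]]))
  # identity: the native reaction itself has dissimilarity zero
  self <- list(list(substrate = mol_from_smiles(smi[["isocitrate"]]),
                    product = mol_from_smiles(smi[["alpha_ketoglutarate"]]),
                    substrate_smiles = smi[["isocitrate"]],
                    product_smiles = smi[["alpha_ketoglutarate"]],
                    operator = "self", ec3 = "1.1.1", balanced = TRUE))
  saved <- call_gof_pairs(native, self)
  expect_equal(nrow(saved), 1)
  expect_equal(saved$reaction_tcdiss, 0)
  # planted arm end to end
  res <- run_gof_arm(native, lib)
  expect_false(res$capped)
  k2hg <- mol_key(mol_from_smiles(smi[["2_hydroxyglutarate"]]))
  planted <- any(res$pairs$operator == "ketone_red" &
                 vapply(res$pairs$product, function(s)
                   mol_key(mol_from_smiles(s)) == k2hg, logical(1)))
  expect_true(planted)
  # decoy-origin synthetic reactions are overwhelmingly rejected
  decoy_ids <- lib$compound[lib$role == "decoy"]
  n_decoy_syn <- sum(vapply(res$synthetic, function(r)
    r$compound %in% decoy_ids, logical(1)))
  n_decoy_saved <- sum(res$pairs$compound %in% decoy_ids)
  expect_gte(n_decoy_syn, 5)
  expect_lte(n_decoy_saved / max(1, n_decoy_syn), 0.1)
  # maximally dissimilar fixture reaction is not saved
  far <- list(list(substrate = mol_from_smiles("NCCN"),
                   product = mol_from_smiles("NCCCN"),
                   substrate_smiles = "NCCN", product_smiles = "NCCCN",
                   operator = "x", ec3 = "9.9.9", balanced = TRUE))
  expect_equal(nrow(call_gof_pairs(native, far)), 0)
})

test_that("maximum common substructure finds shared scaffolds", {
  # n-alkanols C3-C6 share the full propanol chain
  alkanols <- c("CCCO", "CCCCO", "CCCCCO", "CCCCCCO")
  out <- dominant_substructure(alkanols)
  expect_true(out$dominant)
  expect_equal(out$support, 1)
  expect_true(grepl("O", out$smiles))
  # oracle: the MCS of the set is propanol itself (4 heavy atoms)
  expect_equal(nrow(out$pattern$atoms), 4)
  # identical compounds: pattern is the compound
  same <- dominant_substructure(c("CC(=O)O", "CC(=O)O", "OC(C)=O"))
  expect_equal(nrow(same$pattern$atoms), 4)
  expect_equal(same$support, 1)
  # disjoint chemotypes: nothing dominant
  hetero <- dominant_substructure(c("CCCCCC", "OCC(O)C(O)CO", "NC(=O)N"),
                                  min_atoms = 3)
  expect_false(hetero$dominant)
  # single compound: degenerate self-pattern
  single <- dominant_substructure(list("CCO"))
  expect_true(single$degenerate)
  expect_equal(single$support, 1)
})

test_that("pairwise MCS equals the exhaustive oracle on small molecules", {
  # oracle: all common connected subgraph sizes via brute enumeration of
  # subsets of the smaller molecule's atoms
  brute_mcs_size <- function(sa, sb) {
    a <- mol_from_smiles(sa); b <- mol_from_smiles(sb)
    pat <- function(mol, atoms) {
      sub <- list(atoms = data.frame(elem = mol$atoms$elem[atoms],
                                     hcount = NA_integer_, map = 0L),
                  bonds = local({
                    bb <- mol$bonds[mol$bonds$a1 %in% atoms &
                                    mol$bonds$a2 %in% atoms, , drop = FALSE]
                    bb$a1 <- match(bb$a1, atoms); bb$a2 <- match(bb$a2, atoms)
                    bb
                  }))
      sub
    }
    n <- nrow(a$atoms)
    best <- 0
    for (size in n:1) {
      if (size <= best) break
      for (atoms in utils::combn(n, size, simplify = FALSE)) {
        p <- pat(a, atoms)
        # connectivity of the subset
        madj <- mol_build(p$atoms$elem, p$bonds, nH = rep(0L, size))
        if (length(unique(oncoflux:::graph_components(madj))) > 1) next
        if (length(oncoflux:::match_pattern(p, b, max_matches = 1L))) {
          best <- size
          break
        }
      }
    }
    best
  }
  cases <- list(c("CCO", "CCC"), c("CC(C)O", "CCO"),
                c("OC(=O)CCC(=O)O", "OC(=O)CC(=O)O"),
                c("CC(N)C(=O)O", "CCC(=O)O"))
  for (cs in cases) {
    got <- mcs_pair(mol_from_smiles(cs[1]), mol_from_smiles(cs[2]))
    expect_equal(nrow(got$atoms), brute_mcs_size(cs[1], cs[2]),
                 info = paste(cs, collapse = " vs "))
  }
})
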