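# Independent oracles and small fixtures shared across the suite.

# LP oracle: boot::simplex on the shifted system x = v - lb >= 0 with
# row-reduced equalities (conserved-moiety rows dropped; the RHS is a linear
# image of the same rows so the feasible set is unchanged) and sign-
# normalized RHS (boot::simplex requires b >= 0).
oracle_fba_max <- function(model, objective = NULL) {
  S <- unname(stoich_matrix(model))
  b <- model_bounds(model)
  obj <- rep(0, ncol(S))
  if (is.null(objective)) objective <- model$objective
  obj[match(names(objective), reaction_ids(model))] <- objective
  dec <- qr(t(S))
  keep <- dec$pivot[seq_len(dec$rank)]
  S2 <- S[keep, , drop = FALSE]
  b3 <- as.numeric(-S2 %*% b$lb)
  neg <- b3 < 0
  S2[neg, ] <- -S2[neg, ]
  b3[neg] <- -b3[neg]
  r <- boot::simplex(a = obj, A1 = diag(ncol(S)), b1 = b$ub - b$lb,
                     A3 = S2, b3 = b3, maxi = TRUE, n.iter = 10000)
  stopifnot(r$solved == 1)
  unname(r$value + sum(obj * b$lb))
}

# O(n^2) brute-force overlap P: the defining estimator for flux_change.
oracle_overlap_p <- function(a, b) {
  one <- function(x, y) {
    med <- median(y)
    dy <- abs(y - med)
    mean(vapply(x, function(xi) mean(dy >= abs(xi - med)), numeric(1)))
  }
  min(1, one(a, b) + one(b, a))
}

# exact upper-tail hypergeometric by combinatorial summation
oracle_hyper_upper <- function(overlap, set_size, universe, draw) {
  ks <- overlap:min(set_size, draw)
  sum(choose(set_size, ks) * choose(universe - set_size, draw - ks)) /
    choose(universe, draw)
}

# naive bit-loop Tanimoto
oracle_tanimoto <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1L
    if (a[i] || b[i]) uni <- uni + 1L
  }
  if (uni == 0L) return(list(sim = 1, diss = 0))
  list(sim = inter / uni, diss = 1 - inter / uni)
}

# formula bookkeeping oracle through the structure toolkit
oracle_formula <- function(smiles) {
  if (grepl("^\\[?[A-Z][a-z]?\\]?$", smiles)) {
    # single heavy atoms: count by standard valence fill
    f <- oncoflux::mol_formula(oncoflux::mol_from_smiles(smiles))
    return(paste0(vapply(names(f), function(e)
      paste0(e, if (f[[e]] > 1) f[[e]] else ""), character(1)), collapse = ""))
  }
  out <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))
    unname(ChemmineR::MF(sdf, addH = TRUE))
  }, error = function(e) NULL)
  if (!is.null(out)) return(out)
  # the toolkit's formula path rejects a few tiny molecules (e.g. O=O);
  # fall back to a direct tally over its parsed atom block
  f <- oncoflux::mol_formula(oncoflux::mol_from_smiles(smiles))
  paste0(vapply(names(f), function(e)
    paste0(e, if (f[[e]] > 1) f[[e]] else ""), character(1)), collapse = "")
}

# --- fixtures ---------------------------------------------------------------

# linear chain: E_in (<=5) -> A -> B (<=3) -> biomass
chain_model <- function() {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- list(
    list(id = "E_in", stoichiometry = c(A = 1), lower_bound = 0,
         upper_bound = 5),
    list(id = "AB", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 3),
    list(id = "BIO", stoichiometry = c(B = -1), lower_bound = 0,
         upper_bound = 1000))
  metabolic_model(mets, rx, objective = c(BIO = 1), id = "chain")
}

# uncoupled box: n paired in/out reactions, each pair a free 1-D segment
box_model <- function(lbs, ubs) {
  n <- length(lbs)
  mets <- data.frame(id = paste0("m", seq_len(n)), name = paste0("m", seq_len(n)),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- list()
  for (i in seq_len(n)) {
    rx[[2 * i - 1]] <- list(id = paste0("IN", i),
                            stoichiometry = stats::setNames(1, paste0("m", i)),
                            lower_bound = lbs[i], upper_bound = ubs[i])
    rx[[2 * i]] <- list(id = paste0("OUT", i),
                        stoichiometry = stats::setNames(-1, paste0("m", i)),
                        lower_bound = -1000, upper_bound = 1000)
  }
  metabolic_model(mets, rx, objective = stats::setNames(1, "OUT1"), id = "box")
}

# 3-cycle A -> B -> C -> A plus a feasible linear pathway
cycle_model <- function() {
  mets <- data.frame(id = c("A", "B", "C", "X"), name = c("A", "B", "C", "X"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- list(
    list(id = "CYC1", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 1000),
    list(id = "CYC2", stoichiometry = c(B = -1, C = 1), lower_bound = 0,
         upper_bound = 1000),
    list(id = "CYC3", stoichiometry = c(C = -1, A = 1), lower_bound = 0,
         upper_bound = 1000),
    list(id = "EX_X", stoichiometry = c(X = -1), lower_bound = -5,
         upper_bound = 0),
    list(id = "SINK", stoichiometry = c(X = -1), lower_bound = 0,
         upper_bound = 1000))
  metabolic_model(mets, rx, objective = c(SINK = 1), id = "cycle")
}

# wrap a raw points matrix as a flux_sample_set (for estimator-level tests)
fake_samples <- function(points, normalized = FALSE, half = NULL) {
  structure(list(points = points, reactions = colnames(points), half = half,
                 config = list(), normalized = normalized),
            class = "flux_sample_set")
}
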