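#' Default currency (cofactor) metabolite species
#'
#' Ubiquitous cofactors excluded from metabolite-level oncometabolite calls
#' and from the reaction-adjacency relation (otherwise ATP/NAD make every
#' pair of reactions neighbors).
#' @export
currency_species <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "fad", "fadh2",
    "co2", "o2", "h2o", "h", "pi", "ppi", "coa", "bm")
}

#' Differential flux statistics between two sampled conditions
#'
#' For each shared reaction an empirical overlap P-value is computed: with
#' the comparison set's median as center, the probability of finding a flux
#' value in one condition at least as extreme as a value drawn from the
#' other, symmetrized over both orderings and capped at 1 (identical
#' distributions give exactly 1, disjoint supports give ~0). P-values are
#' Benjamini-Hochberg adjusted across reactions. Fold change is the ratio of
#' mean absolute fluxes (A over B, pseudo-floor avoids division by zero);
#' direction is the sign of that shift for condition A relative to B.
#'
#' @param samplesA,samplesB normalized \code{flux_sample_set}s (condition A
#'   is typically the cancer/deficient model, B the matched normal).
#' @param min_points warn below this many points per condition.
#' @return data.frame with \code{reaction}, \code{p_value}, \code{q_value},
#'   \code{fold_change}, \code{direction}.
#' @export
flux_change <- function(samplesA, samplesB, min_points = 1000) {
  if (!isTRUE(samplesA$normalized) || !isTRUE(samplesB$normalized)) {
    stop("flux_change expects normalized sample sets")
  }
  shared <- intersect(colnames(samplesA$points), colnames(samplesB$points))
  if (!length(shared)) stop("no shared reactions")
  if (nrow(samplesA$points) < min_points || nrow(samplesB$points) < min_points) {
    warning("fewer than ", min_points, " sample points; P-value resolution limited")
  }
  floor_ <- 1e-9
  rows <- lapply(shared, function(r) {
    a <- samplesA$points[, r]
    b <- samplesB$points[, r]
    p <- overlap_p(a, b)
    ma <- mean(abs(a)); mb <- mean(abs(b))
    fold <- (ma + floor_) / (mb + floor_)
    data.frame(reaction = r, p_value = p,
               fold_change = fold,
               direction = if (fold >= 1) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("reaction", "p_value", "q_value", "fold_change", "direction")]
}

# Symmetrized empirical overlap probability; the O(n^2) double loop in the
# tests is the defining oracle, this is its sorted O(n log n) equivalent.
overlap_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  one_sided <- function(x, y) {
    # mean over x of the fraction of y at least as extreme as x,
    # extremeness measured from y's median
    dy <- sort(abs(y - stats::median(y)))
    dx <- abs(x - stats::median(y))
    n_lt <- findInterval(dx, dy, left.open = TRUE)  # strictly smaller
    mean((length(dy) - n_lt) / length(dy))
  }
  min(1, one_sided(a, b) + one_sided(b, a))
}

#' Build an enzyme-deficient model
#'
#' Deletes the gene from the (cancer) model and verifies that the deficient
#' network still admits flux states suitable for sub-optimal sampling: FBA
#' must be feasible with a positive optimum so that the optimality-fraction
#' bound defines a non-degenerate polytope. Models failing the check are
#' reported as infeasible and excluded from the LoF arm.
#'
#' @param model the context (cancer) model.
#' @param gene the loss-of-function gene.
#' @param tol positive-growth tolerance.
#' @return list with \code{feasible}; when feasible, \code{model} (deficient)
#'   and \code{objective_value}; else \code{reason}.
#' @export
build_deficient_model <- function(model, gene, tol = 1e-6) {
  def <- delete_genes(model, gene)
  sol <- tryCatch(fba(def), error = function(e) NULL)
  if (is.null(sol)) {
    return(list(feasible = FALSE, gene = gene, reason = "FBA infeasible"))
  }
  if (sol$objective_value <= tol) {
    return(list(feasible = FALSE, gene = gene, reason = "zero growth optimum"))
  }
  list(feasible = TRUE, gene = gene, model = def,
       objective_value = sol$objective_value)
}

#' Call loss-of-function oncometabolites around a deficient enzyme
#'
#' Restricts the differential flux table to the reactions catalyzed by the
#' deleted gene plus the reactions sharing a (non-currency) metabolite with
#' them, keeps those passing the significance rule (raw P below
#' \code{p_cut} and effect fold change at least \code{fold_cut}), and emits
#' their substrates and products, minus currency metabolites, tagged by
#' compartment.
#'
#' @param samples_deficient,samples_normal normalized sample sets.
#' @param gene the deleted gene.
#' @param model the model defining topology (pre-deletion cancer model).
#' @param p_cut,fold_cut significance thresholds (defaults 0.001 and 2).
#' @param currency currency species excluded from adjacency and emission.
#' @param changes optionally a precomputed \code{flux_change} table.
#' @return data.frame with \code{metabolite} (species), \code{compartment},
#'   \code{met_id}, \code{gene}, \code{evidence} (comma-joined significant
#'   reactions adjacent to the metabolite).
#' @export
call_lof_oncometabolites <- function(samples_deficient, samples_normal, gene,
                                     model, p_cut = 0.001, fold_cut = 2,
                                     currency = currency_species(),
                                     changes = NULL) {
  rxns_gene <- reactions_of_gene(model, gene)
  if (!length(rxns_gene)) stop("gene ", gene, " catalyzes no reaction")
  if (is.null(changes)) {
    changes <- flux_change(samples_deficient, samples_normal)
  }
  met_tab <- model$metabolites
  species_of <- stats::setNames(
    if ("species" %in% names(met_tab)) met_tab$species else met_tab$name,
    met_tab$id)
  noncurrency_mets <- function(r) {
    ids <- names(model$reactions[[r]]$stoichiometry)
    ids[!(species_of[ids] %in% currency)]
  }
  seed_mets <- unique(unlist(lapply(rxns_gene, noncurrency_mets)))
  neighborhood <- reaction_ids(model)[vapply(reaction_ids(model), function(r)
    length(intersect(noncurrency_mets(r), seed_mets)) > 0, logical(1))]
  tab <- changes[changes$reaction %in% neighborhood, , drop = FALSE]
  eff <- pmax(tab$fold_change, 1 / tab$fold_change)
  sig <- tab$reaction[tab$p_value < p_cut & eff >= fold_cut]
  if (!length(sig)) {
    return(data.frame(metabolite = character(0), compartment = character(0),
                      met_id = character(0), gene = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  emitted <- unique(unlist(lapply(sig, noncurrency_mets)))
  ev <- vapply(emitted, function(mid) {
    adj <- sig[vapply(sig, function(r) mid %in% noncurrency_mets(r), logical(1))]
    paste(adj, collapse = ",")
  }, character(1))
  out <- data.frame(metabolite = unname(species_of[emitted]),
                    compartment = met_tab$compartment[match(emitted, met_tab$id)],
                    met_id = emitted, gene = gene, evidence = unname(ev),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Accuracy of flux-change direction against expression change
#'
#' Maps significantly changed reactions to genes through the GPRs, removes
#' ambiguous genes (linked to both increasing and decreasing reactions) and
#' isoenzyme-catalyzed reactions (a single isoenzyme need not follow the
#' flux), then scores predicted up/down against the sign of the expression
#' delta: accuracy = (TP + TN) / (TP + TN + FP + FN). Significance comes
#' from a permutation null that shuffles the predicted direction labels.
#'
#' @param changes \code{flux_change} table.
#' @param expr_delta named numeric vector, gene -> expression change
#'   (cancer minus normal, any monotone scale; only the sign is used).
#' @param model model defining GPRs.
#' @param p_cut,fold_cut significance rule for "changed" reactions.
#' @param n_perm permutation count (default 10,000).
#' @param seed RNG seed for the permutation null.
#' @return list with \code{tp}, \code{tn}, \code{fp}, \code{fn},
#'   \code{accuracy}, \code{permutation_p}, \code{n_permutations},
#'   \code{predictions} (data.frame gene/predicted/observed).
#' @export
flux_expression_accuracy <- function(changes, expr_delta, model,
                                     p_cut = 0.001, fold_cut = 2,
                                     n_perm = 10000, seed = 1L) {
  eff <- pmax(changes$fold_change, 1 / changes$fold_change)
  sig <- changes[changes$p_value < p_cut & eff >= fold_cut, , drop = FALSE]
  rg <- reaction_gene_map(model)
  iso <- vapply(reaction_ids(model), function(r) {
    genes <- rg[[r]]
    if (length(genes) < 2L) return(FALSE)
    any(vapply(genes, function(g) {
      pres <- stats::setNames(model$genes %in% g, model$genes)
      gpr_eval(model$reactions[[r]]$gpr_tree, pres, default = FALSE)
    }, logical(1)))
  }, logical(1))
  sig <- sig[!iso[sig$reaction], , drop = FALSE]
  gene_dir <- list()
  for (i in seq_len(nrow(sig))) {
    for (g in rg[[sig$reaction[i]]]) {
      gene_dir[[g]] <- union(gene_dir[[g]], sig$direction[i])
    }
  }
  unambiguous <- names(gene_dir)[vapply(gene_dir, length, integer(1)) == 1L]
  unambiguous <- intersect(unambiguous, names(expr_delta))
  if (!length(unambiguous)) {
    stop("no unambiguous gene predictions; accuracy undefined")
  }
  predicted <- vapply(gene_dir[unambiguous], `[[`, character(1), 1L)
  observed <- ifelse(expr_delta[unambiguous] > 0, "up", "down")
  tp <- sum(predicted == "up" & observed == "up")
  tn <- sum(predicted == "down" & observed == "down")
  fp <- sum(predicted == "up" & observed == "down")
  fn <- sum(predicted == "down" & observed == "up")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  set.seed(seed)
  perm_acc <- replicate(n_perm, {
    pp <- sample(predicted)
    mean(pp == observed)
  })
  p <- (sum(perm_acc >= acc) + 1) / (n_perm + 1)
  list(tp = tp, tn = tn, fp = fp, fn = fn, accuracy = acc,
       permutation_p = p, n_permutations = n_perm,
       predictions = data.frame(gene = unambiguous,
                                predicted = unname(predicted),
                                observed = unname(observed),
                                stringsAsFactors = FALSE))
}

#' Enrichment of experimental essential genes among predictions
#'
#' Upper-tail hypergeometric test of the overlap between in silico and
#' in vivo essential gene sets over a common universe, reported with the
#' probit z transform (higher z = stronger enrichment).
#'
#' @param in_silico,in_vivo,universe character vectors of gene ids.
#' @return list with \code{overlap}, \code{p_value}, \code{z_score}.
#' @export
essentiality_enrichment <- function(in_silico, in_vivo, universe) {
  stopifnot(all(in_silico %in% universe), all(in_vivo %in% universe))
  if (!length(in_silico)) {
    return(list(overlap = 0L, p_value = 1,
                z_score = stats::qnorm(1e-16)))
  }
  k <- length(intersect(in_silico, in_vivo))
  p <- stats::phyper(k - 1, length(in_vivo),
                     length(universe) - length(in_vivo),
                     length(in_silico), lower.tail = FALSE)
  list(overlap = k, p_value = p,
       z_score = stats::qnorm(pmax(pmin(1 - p, 1 - 1e-16), 1e-16)))
}

#' Run the loss-of-function arm end to end on a synthetic scenario
#'
#' Generates the cohort, screens mutations, extracts cancer and normal
#' context models, builds a deficient model per selected LoF gene, samples
#' deficient vs normal flux spaces, and calls oncometabolites.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @param n_points,n_steps sampling effort per model.
#' @param optimality_fraction sub-optimality bound for sampling.
#' @param p_cut,fold_cut calling thresholds.
#' @return list with \code{screen}, \code{lof_genes}, \code{context},
#'   \code{calls} (one data.frame per feasible deficient model),
#'   \code{infeasible} (genes excluded).
#' @export
run_lof_pipeline <- function(scenario = synthetic_scenario(),
                             n_points = 1000, n_steps = 60,
                             optimality_fraction = 0.9,
                             p_cut = 0.001, fold_cut = 2) {
  model <- generate_toy_model(scenario)
  expr <- generate_expression(scenario, model)
  muts <- generate_mutations(scenario, model)
  scr <- mutation_screen(muts, scenario$n_samples_cancer, model)
  lof_genes <- scr$gene[scr$selected & grepl("LoF", scr$arm)]
  calls_c <- presence_calls(expr$cancer, threshold = scenario$detection_threshold)
  calls_n <- presence_calls(expr$normal, threshold = scenario$detection_threshold)
  ctx_c <- gimme_extract(model, calls_c, required_fraction = optimality_fraction)
  ctx_n <- gimme_extract(model, calls_n, required_fraction = optimality_fraction)
  seed0 <- scenario$seed * 1000L
  samp_n <- achr_sample(ctx_n$model, n_points, n_steps,
                        optimality_fraction, seed = seed0 + 21L)
  calls <- list()
  infeasible <- character(0)
  for (i in seq_along(lof_genes)) {
    g <- lof_genes[i]
    def <- build_deficient_model(ctx_c$model, g)
    if (!def$feasible) {
      infeasible <- c(infeasible, g)
      next
    }
    samp_d <- achr_sample(def$model, n_points, n_steps,
                          optimality_fraction, seed = seed0 + 30L + i)
    kept <- filter_zero_and_loop_reactions(samp_d, samp_n, ctx_c$model)
    nd <- normalize_fluxes(samp_d, kept)
    nn <- normalize_fluxes(samp_n, kept)
    calls[[g]] <- call_lof_oncometabolites(nd, nn, g, ctx_c$model,
                                           p_cut = p_cut, fold_cut = fold_cut)
  }
  list(screen = scr, lof_genes = lof_genes,
       context = list(cancer = ctx_c, normal = ctx_n),
       calls = calls, infeasible = infeasible)
}
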