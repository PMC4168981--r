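#' Present/absent expression calls
#'
#' A gene is detected in a sample when its value reaches the detection
#' threshold, and called present when it is detected in strictly more than
#' \code{consensus} of the samples (the strict ">" means 99 detections out
#' of 100 at consensus 0.99 still yield an absent call).
#'
#' @param expr genes x samples numeric matrix (rownames = gene ids).
#' @param threshold detection threshold (e.g. 10 mapped reads for RNA-seq
#'   style counts); platform-specific calls can be emulated by pre-scaling.
#' @param consensus sample-consensus fraction in (0, 1].
#' @param platform free-text provenance tag.
#' @return named logical vector of class \code{presence_calls} (TRUE =
#'   present) with provenance attributes.
#' @export
presence_calls <- function(expr, threshold = 10, consensus = 0.99,
                           platform = "generic") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (consensus <= 0 || consensus > 1) stop("consensus outside (0, 1]")
  if (anyDuplicated(rownames(expr))) {
    stop("duplicated genes in expression matrix: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]),
               collapse = ", "))
  }
  det <- expr >= threshold
  calls <- rowSums(det) > consensus * ncol(expr)
  structure(calls, class = "presence_calls", platform = platform,
            threshold = threshold, consensus = consensus)
}

#' Combined growth/energy objective with max-flux scaling
#'
#' Builds the linear objective a * v_biomass / max(v_biomass) +
#' b * v_atp / max(v_atp): each term is scaled by its maximum achievable
#' flux (FBA with that reaction as sole objective) so that biomass and ATP
#' production contribute comparably; a = b = 1 weighs them equally, and
#' b = 0 recovers plain biomass maximization.
#'
#' @param model a \code{metabolic_model}.
#' @param terms character vector of reaction ids (e.g. biomass and ATP
#'   demand); weights \code{a}, \code{b}, ... matched positionally.
#' @param weights numeric coefficients, one per term (default all 1).
#' @return named numeric objective vector (reaction id -> weight / scale)
#'   with attribute \code{"scales"}.
#' @export
scale_objective <- function(model, terms, weights = rep(1, length(terms))) {
  stopifnot(length(weights) == length(terms))
  unknown <- setdiff(terms, reaction_ids(model))
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  scales <- vapply(terms, function(r) {
    fba(model, objective = stats::setNames(1, r))$objective_value
  }, numeric(1))
  zero <- terms[scales <= 1e-12]
  if (length(zero)) {
    stop("objective term(s) with zero maximum flux cannot be scaled: ",
         paste(zero, collapse = ", "))
  }
  keep <- weights != 0
  obj <- stats::setNames(weights[keep] / scales[keep], terms[keep])
  attr(obj, "scales") <- stats::setNames(scales, terms)
  obj
}

#' Medium specification
#'
#' Reads a medium from a YAML config: a named map
#' \code{uptakes} (exchange reaction id -> maximum uptake, applied as a
#' negative lower bound) and an optional \code{forced} map (reaction id ->
#' minimum flux, e.g. forced CO2/biomass secretion or glucose uptake).
#'
#' @param path YAML file.
#' @return list with \code{uptakes} and \code{forced}.
#' @export
read_medium <- function(path) {
  m <- yaml::read_yaml(path)
  list(uptakes = unlist(m$uptakes), forced = unlist(m$forced))
}

#' Apply a medium to a model
#'
#' Closes every exchange uptake (lower bound 0), then opens the listed
#' uptakes to their bounds and sets forced minimum fluxes. Application is
#' idempotent.
#'
#' @param model a \code{metabolic_model}.
#' @param medium list with \code{uptakes} (exchange id -> uptake rate,
#'   positive number = allowed uptake magnitude) and optional \code{forced}
#'   (reaction id -> minimum flux).
#' @export
apply_medium <- function(model, medium) {
  ex <- reaction_ids(model)[vapply(model$reactions, function(r)
    isTRUE(r$is_exchange), logical(1))]
  unknown <- setdiff(names(medium$uptakes), reaction_ids(model))
  if (length(unknown)) stop("unknown exchange ids: ",
                            paste(unknown, collapse = ", "))
  model <- set_bounds(model, ex, lb = 0)
  if (length(medium$uptakes)) {
    model <- set_bounds(model, names(medium$uptakes),
                        lb = -abs(unname(medium$uptakes)))
  }
  if (length(medium$forced)) {
    unknown <- setdiff(names(medium$forced), reaction_ids(model))
    if (length(unknown)) stop("unknown forced-flux ids: ",
                              paste(unknown, collapse = ", "))
    model <- set_bounds(model, names(medium$forced),
                        lb = unname(medium$forced))
  }
  model
}

#' GIMME context-specific model extraction
#'
#' Given presence/absence calls, finds the flux state that achieves at least
#' \code{required_fraction} of the objective optimum while minimizing total
#' flux through reactions whose GPR is unsatisfied by the present genes
#' (uniform penalty 1 per absent reaction, |v| linearized with auxiliary
#' magnitude variables). Reactions with absent GPRs that carry no flux in
#' that solution are removed; reactions with satisfied or empty GPRs are
#' always kept. The minimized penalty sum is reported as the inconsistency
#' score.
#'
#' @param model a \code{metabolic_model} (medium already applied).
#' @param calls \code{presence_calls} (or named logical vector); genes not
#'   covered by the calls are treated as present.
#' @param objective optional named objective vector (default: the model's).
#' @param required_fraction fraction of the optimum to preserve (default
#'   0.9, matching the sub-optimal sampling bound).
#' @return list with \code{model} (the context sub-network),
#'   \code{inconsistency} (minimized penalty), \code{removed} (reaction
#'   ids), \code{penalized} (absent-GPR reaction ids), \code{flux}
#'   (the penalty-program solution).
#' @export
gimme_extract <- function(model, calls, objective = NULL,
                          required_fraction = 0.9) {
  if (required_fraction <= 0 || required_fraction > 1) {
    stop("required_fraction outside (0, 1]")
  }
  obj <- objective_vector(model, objective)
  if (all(obj == 0)) stop("model has an empty objective")
  present <- stats::setNames(as.logical(calls), names(calls))
  absent_rxn <- vapply(reaction_ids(model), function(r) {
    tree <- model$reactions[[r]]$gpr_tree
    if (is.null(tree)) return(FALSE)      # spontaneous: never penalized
    !gpr_eval(tree, present, default = TRUE)
  }, logical(1))
  pen_rxns <- reaction_ids(model)[absent_rxn]
  opt <- fba(model, objective = if (is.null(objective)) NULL else objective)
  bounds <- model_bounds(model)
  S <- stoich_matrix(model)
  n <- length(obj)
  k <- length(pen_rxns)
  if (k == 0L) {
    return(list(model = model, inconsistency = 0, removed = character(0),
                penalized = character(0), flux = fba(model)$values))
  }
  # variables: v (n) then y_r >= |v_r| for penalized reactions (k)
  idx <- match(pen_rxns, reaction_ids(model))
  Sx <- cbind(S, matrix(0, nrow(S), k))
  # inequalities: v_r - y_r <= 0 and -v_r - y_r <= 0; objective floor
  ineq <- matrix(0, 2L * k + 1L, n + k)
  for (j in seq_len(k)) {
    ineq[2L * j - 1L, idx[j]] <- 1;  ineq[2L * j - 1L, n + j] <- -1
    ineq[2L * j,      idx[j]] <- -1; ineq[2L * j,      n + j] <- -1
  }
  ineq[2L * k + 1L, seq_len(n)] <- -obj
  rhs <- c(rep(0, 2L * k), -required_fraction * opt$objective_value)
  ymax <- pmax(abs(bounds$lb[idx]), abs(bounds$ub[idx]))
  sol <- lp_solve(c(rep(0, n), rep(1, k)), Sx,
                  c(bounds$lb, rep(0, k)), c(bounds$ub, ymax),
                  maximize = FALSE, extraA = ineq, extrab = rhs)
  if (!sol$feasible) {
    stop("GIMME infeasible at required_fraction ", required_fraction,
         "; try a lower fraction")
  }
  v <- sol$v[seq_len(n)]
  names(v) <- reaction_ids(model)
  inconsistency <- sum(abs(v[pen_rxns]))
  removed <- pen_rxns[abs(v[pen_rxns]) <= 1e-9]
  ctx <- subset_model(model, setdiff(reaction_ids(model), removed))
  list(model = ctx, inconsistency = inconsistency, removed = removed,
       penalized = pen_rxns, flux = v)
}

#' Correlation between expression structure and network structure
#'
#' Two-step correlation of correlations across three or more conditions:
#' step one computes pairwise Pearson correlations between conditions of
#' (i) the binary gene presence-call vectors and (ii) the binary
#' reaction-presence vectors of the extracted models; step two correlates,
#' for each condition, its row of gene-level correlations with its row of
#' reaction-level correlations (diagonal excluded). Significance per
#' condition is assessed by shuffling the reaction-presence vectors.
#'
#' @param call_list named list of logical gene-call vectors (same genes).
#' @param model_list named list of context models (reaction presence is
#'   scored over the union of reaction ids); same names as
#'   \code{call_list}.
#' @param n_perm permutation count for the null.
#' @param seed RNG seed.
#' @return data.frame with \code{condition}, \code{pcc},
#'   \code{permutation_p}, \code{degenerate}.
#' @export
structure_expression_correlation <- function(call_list, model_list,
                                             n_perm = 1000, seed = 1L) {
  stopifnot(identical(names(call_list), names(model_list)))
  if (length(call_list) < 3) {
    stop("need at least three conditions: correlation of correlations is ",
         "undefined below that")
  }
  genes <- Reduce(intersect, lapply(call_list, names))
  G <- vapply(call_list, function(v) as.numeric(v[genes]),
              numeric(length(genes)))
  all_rxns <- sort(unique(unlist(lapply(model_list, reaction_ids))))
  R <- vapply(model_list, function(m) as.numeric(all_rxns %in% reaction_ids(m)),
              numeric(length(all_rxns)))
  cor_pairs <- function(M) {
    k <- ncol(M)
    out <- matrix(1, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- binary_cor(M[, i], M[, j])
    }
    out
  }
  final_pcc <- function(cg, cr) {
    vapply(seq_len(ncol(G)), function(i) {
      a <- cg[i, -i]; b <- cr[i, -i]
      binary_cor(a, b)
    }, numeric(1))
  }
  cg <- cor_pairs(G)
  cr <- cor_pairs(R)
  obs <- final_pcc(cg, cr)
  degenerate <- apply(G, 2, function(x) stats::sd(x) == 0) |
    apply(R, 2, function(x) stats::sd(x) == 0)
  set.seed(seed)
  exceed <- numeric(ncol(G))
  for (b in seq_len(n_perm)) {
    Rp <- apply(R, 2, sample)
    perm <- final_pcc(cg, cor_pairs(Rp))
    exceed <- exceed + (perm >= obs)
  }
  data.frame(condition = names(call_list), pcc = obs,
             permutation_p = (exceed + 1) / (n_perm + 1),
             degenerate = unname(degenerate), stringsAsFactors = FALSE)
}

# Pearson correlation with the constant-vector convention: two identical
# constant vectors correlate perfectly (1), otherwise constant input gives 0
# and is flagged upstream as degenerate.
binary_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(x, y))) 1 else 0)
  }
  stats::cor(x, y)
}
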