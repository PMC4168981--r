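#' Linear programming over a flux polytope
#'
#' Internal LP wrapper used by all flux computations. Solves
#' max/min obj'v subject to S v = 0, lb <= v <= ub and optional extra
#' inequality rows A v <= b (handled through bounded slack variables).
#' Backed by the package's bounded-variable revised simplex.
#'
#' @param obj objective coefficients (length = n reactions).
#' @param S stoichiometric matrix (may have zero rows).
#' @param lb,ub finite bounds.
#' @param maximize logical.
#' @param extraA,extrab optional inequality system A v <= b.
#' @return list with \code{feasible}, and when feasible \code{v} (named flux
#'   vector) and \code{objective} (obj'v).
#' @keywords internal
lp_solve <- function(obj, S, lb, ub, maximize = TRUE,
                     extraA = NULL, extrab = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(ub < lb)) return(list(feasible = FALSE, msg = "ub < lb"))
  if (is.null(S)) S <- matrix(0, 0, n)
  S <- unname(as.matrix(S))
  Acon <- S
  bcon <- rep(0, nrow(S))
  slack_lb <- numeric(0)
  slack_ub <- numeric(0)
  if (!is.null(extraA)) {
    extraA <- matrix(extraA, ncol = n)
    # a'v <= b  becomes  a'v + s = b with 0 <= s <= b - min(a'v over box)
    smax <- vapply(seq_len(nrow(extraA)), function(i) {
      a <- extraA[i, ]
      extrab[i] - sum(ifelse(a > 0, a * lb, a * ub))
    }, numeric(1))
    if (any(smax < -1e-9)) return(list(feasible = FALSE, msg = "inconsistent rows"))
    smax <- pmax(smax, 0)
    k <- nrow(extraA)
    Acon <- rbind(cbind(Acon, matrix(0, nrow(Acon), k)),
                  cbind(extraA, diag(k)))
    bcon <- c(bcon, extrab)
    slack_lb <- rep(0, k)
    slack_ub <- smax
  }
  res <- bounded_simplex(c(as.numeric(obj), rep(0, length(slack_lb))),
                         Acon, bcon,
                         c(lb, slack_lb), c(ub, slack_ub),
                         maximize = maximize)
  if (res$status != "optimal") {
    return(list(feasible = FALSE, msg = res$status))
  }
  v <- res$x[seq_len(n)]
  names(v) <- names(obj)
  list(feasible = TRUE, v = v, objective = sum(obj * v))
}

#' Flux balance analysis
#'
#' Maximizes the model objective c'v over the steady-state flux polytope
#' \{S v = 0, lb <= v <= ub\}.
#'
#' @param model a \code{metabolic_model} with a non-empty objective.
#' @param objective optional named weight vector overriding the model
#'   objective.
#' @param minimize maximize (default) or minimize.
#' @return list of class \code{flux_vector}: \code{values} (named flux
#'   vector) and \code{objective_value}.
#' @export
fba <- function(model, objective = NULL, minimize = FALSE) {
  obj <- objective_vector(model, objective)
  if (all(obj == 0)) stop("model has an empty objective")
  bounds <- model_bounds(model)
  sol <- lp_solve(obj, stoich_matrix(model), bounds$lb, bounds$ub,
                  maximize = !minimize)
  if (!sol$feasible) {
    stop("FBA infeasible for model '", model$id, "': ", sol$msg)
  }
  structure(list(values = sol$v, objective_value = sol$objective),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector> objective =", format(x$objective_value, digits = 8), "\n")
  invisible(x)
}

#' Flux variability of selected reactions
#'
#' Min and max achievable flux per reaction, optionally holding the model
#' objective at a fraction of its optimum.
#'
#' @param model a \code{metabolic_model}.
#' @param rxns reaction ids (default all).
#' @param fraction if > 0, add constraint c'v >= fraction * FBA optimum.
#' @return data.frame with \code{reaction}, \code{min}, \code{max}.
#' @export
fva <- function(model, rxns = reaction_ids(model), fraction = 0) {
  S <- stoich_matrix(model)
  bounds <- model_bounds(model)
  extraA <- NULL; extrab <- NULL
  if (fraction > 0) {
    obj <- objective_vector(model)
    opt <- fba(model)$objective_value
    extraA <- matrix(-obj, nrow = 1)
    extrab <- -fraction * opt
  }
  all_ids <- reaction_ids(model)
  out <- data.frame(reaction = rxns, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rxns)) {
    e <- stats::setNames(numeric(length(all_ids)), all_ids)
    e[rxns[i]] <- 1
    lo <- lp_solve(e, S, bounds$lb, bounds$ub, maximize = FALSE,
                   extraA = extraA, extrab = extrab)
    hi <- lp_solve(e, S, bounds$lb, bounds$ub, maximize = TRUE,
                   extraA = extraA, extrab = extrab)
    if (!lo$feasible || !hi$feasible) stop("FVA subproblem infeasible")
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  out
}

#' Single-gene deletion screen
#'
#' Deletes each gene in turn, re-solves FBA, and classifies the knockout by
#' its growth ratio (knockout objective / wild-type objective):
#' \code{essential} when the ratio falls below 0.90 (growth reduced by more
#' than 10%), \code{reduced_1_10} for ratios in [0.90, 0.99), and
#' \code{no_change} otherwise. A boundary ratio of exactly 0.90 is therefore
#' not essential.
#'
#' @param model a \code{metabolic_model}; wild-type FBA must be feasible with
#'   a positive objective.
#' @param genes genes to screen (default all model genes).
#' @return data.frame with \code{gene}, \code{growth_ratio}, \code{category}.
#' @export
single_gene_deletion_screen <- function(model, genes = model$genes) {
  wt <- tryCatch(fba(model), error = function(e) NULL)
  if (is.null(wt) || wt$objective_value <= 0) {
    stop("wild-type model is infeasible or carries zero objective flux; ",
         "deletion screen aborted")
  }
  S <- stoich_matrix(model)
  bounds <- model_bounds(model)
  obj <- objective_vector(model)
  ratio <- vapply(genes, function(g) {
    del <- delete_genes(model, g)
    closed <- attr(del, "closed_reactions")
    if (length(closed) == 0L) return(1)
    b <- bounds
    b$lb[closed] <- 0; b$ub[closed] <- 0
    sol <- lp_solve(obj, S, b$lb, b$ub, maximize = TRUE)
    if (!sol$feasible) return(0)
    max(0, sol$objective) / wt$objective_value
  }, numeric(1))
  category <- ifelse(ratio < 0.90, "essential",
                     ifelse(ratio < 0.99, "reduced_1_10", "no_change"))
  data.frame(gene = genes, growth_ratio = unname(ratio),
             category = unname(category), stringsAsFactors = FALSE)
}

#' Write a deletion screen as TSV
#' @param screen data.frame from \code{single_gene_deletion_screen}.
#' @param path output file.
#' @export
write_deletion_screen <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
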