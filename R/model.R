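#' Constraint-based metabolic model
#'
#' A light S3 container for a genome-scale (here, toy-scale) metabolic model:
#' metabolites with compartments, reactions with stoichiometry, flux bounds
#' (mmol/gDW/h), boolean gene-protein-reaction (GPR) rules, and a linear
#' objective over reactions. The stoichiometric matrix S is derived on demand
#' with \code{stoich_matrix}.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} and optionally \code{formula}.
#' @param reactions list of reaction specs; each a list with \code{id},
#'   \code{stoichiometry} (named numeric, metabolite id -> signed coefficient),
#'   \code{lower_bound}, \code{upper_bound}, \code{gpr} (string, may be ""),
#'   \code{subsystem}, and optional flags \code{is_exchange},
#'   \code{is_transport}.
#' @param genes character vector of gene ids; defaults to the union of genes
#'   referenced by the GPRs.
#' @param objective named numeric vector, reaction id -> weight.
#' @param id model identifier.
#' @return an object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective = numeric(0), id = "model") {
  stopifnot(is.data.frame(metabolites), all(c("id", "compartment") %in%
            names(metabolites)))
  if (anyDuplicated(metabolites$id)) {
    stop("duplicated metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) stop("duplicated reaction ids")
  names(reactions) <- rxn_ids
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$gpr)) r$gpr <- ""
    if (is.null(r$subsystem)) r$subsystem <- ""
    if (is.null(r$is_exchange)) r$is_exchange <- length(r$stoichiometry) == 1L
    if (is.null(r$is_transport)) r$is_transport <- FALSE
    if (length(r$stoichiometry) == 0L) stop("empty stoichiometry in ", r$id)
    if (r$lower_bound > r$upper_bound) {
      stop("lower_bound > upper_bound in reaction ", r$id)
    }
    r$gpr_tree <- gpr_parse(r$gpr)
    r
  })
  used_mets <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  missing_mets <- setdiff(used_mets, metabolites$id)
  if (length(missing_mets)) {
    stop("reactions reference unknown metabolites: ",
         paste(missing_mets, collapse = ", "))
  }
  gpr_gene_set <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr_tree))))
  if (is.null(genes)) genes <- gpr_gene_set
  extra <- setdiff(gpr_gene_set, genes)
  if (length(extra)) stop("GPR genes missing from gene list: ",
                          paste(extra, collapse = ", "))
  if (length(objective)) {
    bad <- setdiff(names(objective), rxn_ids)
    if (length(bad)) stop("objective names unknown reactions: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 genes = genes, objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      " metabolites:", nrow(x$metabolites),
      " reactions:", length(x$reactions),
      " genes:", length(x$genes), "\n",
      " objective:", if (length(x$objective))
        paste(names(x$objective), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a \code{metabolic_model}.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Stoichiometric matrix S (metabolites x reactions)
#' @param model a \code{metabolic_model}.
#' @return dense numeric matrix with metabolite ids as rownames, reaction ids
#'   as colnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- reaction_ids(model)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Flux bounds of a model
#' @param model a \code{metabolic_model}.
#' @return list with numeric vectors \code{lb}, \code{ub} named by reaction.
#' @export
model_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
       ub = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}

#' Set bounds on named reactions
#' @param model a \code{metabolic_model}.
#' @param rxns reaction ids.
#' @param lb,ub new bounds (recycled).
#' @export
set_bounds <- function(model, rxns, lb = NULL, ub = NULL) {
  unknown <- setdiff(rxns, reaction_ids(model))
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  lb <- if (is.null(lb)) rep(NA_real_, length(rxns)) else rep_len(lb, length(rxns))
  ub <- if (is.null(ub)) rep(NA_real_, length(rxns)) else rep_len(ub, length(rxns))
  for (i in seq_along(rxns)) {
    r <- rxns[i]
    if (!is.na(lb[i])) model$reactions[[r]]$lower_bound <- lb[i]
    if (!is.na(ub[i])) model$reactions[[r]]$upper_bound <- ub[i]
  }
  model
}

#' Objective coefficient vector c over all reactions
#' @keywords internal
objective_vector <- function(model, objective = NULL) {
  if (is.null(objective)) objective <- model$objective
  obj <- stats::setNames(numeric(length(model$reactions)), reaction_ids(model))
  if (length(objective)) obj[names(objective)] <- objective
  obj
}

#' Genes catalysing each reaction
#' @return named list reaction id -> character vector of gene ids.
#' @keywords internal
reaction_gene_map <- function(model) {
  lapply(model$reactions, function(r) gpr_genes(r$gpr_tree))
}

#' Reactions whose GPR references a gene
#' @param model a \code{metabolic_model}.
#' @param gene a single gene id.
#' @return character vector of reaction ids.
#' @export
reactions_of_gene <- function(model, gene) {
  rg <- reaction_gene_map(model)
  names(rg)[vapply(rg, function(g) gene %in% g, logical(1))]
}

#' Restrict a model to a reaction subset
#'
#' Drops all other reactions and any metabolite no longer referenced. Genes
#' are kept as-is (gene list is a superset invariant).
#' @param model a \code{metabolic_model}.
#' @param rxns reaction ids to keep.
#' @export
subset_model <- function(model, rxns) {
  unknown <- setdiff(rxns, reaction_ids(model))
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  keep <- model$reactions[rxns]
  used <- unique(unlist(lapply(keep, function(r) names(r$stoichiometry))))
  mets <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  obj <- model$objective[names(model$objective) %in% rxns]
  metabolic_model(mets, unname(keep), genes = model$genes, objective = obj,
                  id = model$id)
}

#' Close reactions disabled by deleting genes
#'
#' Evaluates every GPR with the deleted genes set to FALSE (all other genes
#' TRUE); reactions whose rule evaluates FALSE get bounds (0, 0). AND requires
#' all genes, OR any gene, so isoenzyme (OR) reactions survive single
#' deletions while enzyme-complex (AND) reactions do not.
#'
#' @param model a \code{metabolic_model}.
#' @param genes gene ids to delete; must all exist in \code{model$genes}.
#' @return the model with affected reaction bounds set to (0, 0).
#' @export
delete_genes <- function(model, genes) {
  genes <- unique(genes)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) stop("unknown genes: ", paste(unknown, collapse = ", "))
  present <- stats::setNames(rep(FALSE, length(genes)), genes)
  closed <- character(0)
  for (r in reaction_ids(model)) {
    tree <- model$reactions[[r]]$gpr_tree
    if (is.null(tree)) next
    if (!gpr_eval(tree, present, default = TRUE)) closed <- c(closed, r)
  }
  if (length(closed)) model <- set_bounds(model, closed, lb = 0, ub = 0)
  attr(model, "closed_reactions") <- closed
  model
}
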