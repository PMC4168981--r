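#' Mutation classes of the screen vocabulary
#' @keywords internal
mutation_classes <- function() {
  c("missense", "nonsense", "frameshift_indel", "inframe_indel", "silent",
    "splice_site")
}

lof_classes <- function() c("nonsense", "frameshift_indel", "splice_site")
gof_classes <- function() "missense"

#' Read a mutation table from MAF-like TSV
#' @param path TSV with columns gene, sample, mclass and optionally fis.
#' @export
read_mutation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "mclass")
  if (!all(need %in% names(tab))) {
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tab$mclass), mutation_classes())
  if (length(bad)) stop("unknown mutation classes: ", paste(bad, collapse = ", "))
  class(tab) <- c("mutation_table", "data.frame")
  tab
}

#' Per-sample and per-class mutation summary
#'
#' @param table a mutation table (gene, sample, mclass).
#' @return list with \code{per_sample} (distinct mutated genes per sample,
#'   plus \code{median} and \code{mean}) and \code{per_class} (percentages
#'   summing to 100).
#' @export
mutation_summary <- function(table) {
  if (nrow(table) == 0L) {
    warning("empty mutation table")
    return(list(per_sample = data.frame(sample = character(0),
                                        n_genes = integer(0)),
                median = NA_real_, mean = NA_real_,
                per_class = numeric(0)))
  }
  per_sample <- stats::aggregate(gene ~ sample, data = table,
                                 FUN = function(g) length(unique(g)))
  names(per_sample)[2] <- "n_genes"
  cls <- table(factor(table$mclass, levels = mutation_classes()))
  list(per_sample = per_sample,
       median = stats::median(per_sample$n_genes),
       mean = mean(per_sample$n_genes),
       per_class = stats::setNames(100 * as.numeric(cls) / nrow(table),
                                   names(cls)))
}

#' Recurrence filter over mutated genes
#'
#' Recurrence is the fraction of distinct mutated samples; genes at or above
#' the threshold are retained. When a model is supplied, transporter-only
#' genes (catalyzing only reactions that move an identical metabolite
#' species between compartments) are excluded, since they do not perform
#' chemical transformations.
#'
#' @param table mutation table.
#' @param n_samples cohort size used as the recurrence denominator.
#' @param threshold recurrence fraction (default 0.05).
#' @param model optional \code{metabolic_model} enabling the transporter
#'   exclusion.
#' @param classes restrict to these mutation classes before counting.
#' @return data.frame with \code{gene}, \code{n_mutated_samples},
#'   \code{recurrence}, sorted by recurrence.
#' @export
recurrence_filter <- function(table, n_samples, threshold = 0.05,
                              model = NULL, classes = NULL) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (threshold <= 0 || threshold > 1) stop("threshold outside (0, 1]")
  if (!is.null(classes)) table <- table[table$mclass %in% classes, , drop = FALSE]
  if (nrow(table) == 0L) {
    return(data.frame(gene = character(0), n_mutated_samples = integer(0),
                      recurrence = numeric(0)))
  }
  cnt <- stats::aggregate(sample ~ gene, data = table,
                          FUN = function(s) length(unique(s)))
  names(cnt)[2] <- "n_mutated_samples"
  cnt$recurrence <- cnt$n_mutated_samples / n_samples
  cnt <- cnt[cnt$recurrence >= threshold, , drop = FALSE]
  if (!is.null(model)) {
    cnt <- cnt[!vapply(cnt$gene, function(g) transporter_only(model, g),
                       logical(1)), , drop = FALSE]
  }
  cnt <- cnt[order(-cnt$recurrence, cnt$gene), , drop = FALSE]
  rownames(cnt) <- NULL
  cnt
}

# TRUE when a gene catalyzes only pure transport reactions (same metabolite
# species on both sides, different compartments, no transformation)
transporter_only <- function(model, gene) {
  rxns <- reactions_of_gene(model, gene)
  if (!length(rxns)) return(FALSE)
  species_of <- stats::setNames(
    if ("species" %in% names(model$metabolites)) model$metabolites$species
    else model$metabolites$name,
    model$metabolites$id)
  all(vapply(rxns, function(r) {
    st <- model$reactions[[r]]$stoichiometry
    subs <- species_of[names(st)[st < 0]]
    prods <- species_of[names(st)[st > 0]]
    length(subs) > 0 && length(prods) > 0 && setequal(subs, prods)
  }, logical(1)))
}

#' Classify genes into loss-/gain-of-function arms
#'
#' A gene joins the LoF arm when its nonsense/frameshift/splice-site records
#' alone meet the recurrence threshold, and the GoF arm when its missense
#' records alone do; both arms are possible, silent and in-frame indel
#' records count toward neither.
#'
#' @param table mutation table.
#' @param n_samples recurrence denominator.
#' @param threshold recurrence fraction.
#' @return named list gene -> character vector subset of c("LoF", "GoF").
#' @export
classify_arms <- function(table, n_samples, threshold = 0.05) {
  bad <- setdiff(unique(table$mclass), mutation_classes())
  if (length(bad)) stop("unknown mutation classes: ", paste(bad, collapse = ", "))
  lof <- recurrence_filter(table, n_samples, threshold, classes = lof_classes())
  gof <- recurrence_filter(table, n_samples, threshold, classes = gof_classes())
  genes <- unique(table$gene)
  out <- lapply(genes, function(g) {
    arms <- character(0)
    if (g %in% lof$gene) arms <- c(arms, "LoF")
    if (g %in% gof$gene) arms <- c(arms, "GoF")
    arms
  })
  stats::setNames(out, genes)
}

#' Isoenzyme redundancy filter
#'
#' Removes genes whose mutational loss every associated reaction can absorb:
#' a gene is dropped iff each reaction it participates in has a GPR that
#' stays satisfiable with that gene absent (all other genes present). Genes
#' absent from every GPR are removed with a note.
#'
#' @param genes candidate gene ids.
#' @param model a \code{metabolic_model}.
#' @return character vector of retained genes; attribute \code{"notes"}
#'   records genes removed for lacking any GPR.
#' @export
isoenzyme_filter <- function(genes, model) {
  notes <- character(0)
  keep <- vapply(genes, function(g) {
    rxns <- reactions_of_gene(model, g)
    if (!length(rxns)) {
      notes <<- c(notes, paste0(g, ": absent from all GPRs"))
      return(FALSE)
    }
    # retained iff some reaction actually loses activity without the gene
    any(vapply(rxns, function(r) {
      pres <- stats::setNames(model$genes != g, model$genes)
      !gpr_eval(model$reactions[[r]]$gpr_tree, pres, default = TRUE)
    }, logical(1)))
  }, logical(1))
  out <- genes[keep]
  attr(out, "notes") <- notes
  out
}

#' Functional-impact score filter
#'
#' A gene is retained when the aggregate (default: maximum) of its
#' mutations' FIS values reaches \code{min_fis}. The default cutoff 1.9
#' corresponds to the "medium impact" convention of conservation-based
#' impact scoring.
#'
#' @param genes candidate genes.
#' @param table mutation table with an \code{fis} column.
#' @param min_fis minimum aggregate FIS; \code{NULL} disables the filter.
#' @param aggregate summary function over a gene's scores.
#' @export
fis_filter <- function(genes, table, min_fis = 1.9, aggregate = max) {
  if (is.null(min_fis)) return(genes)
  if (!"fis" %in% names(table)) stop("mutation table has no fis column")
  sub <- table[table$gene %in% genes, , drop = FALSE]
  missing <- genes[!genes %in% sub$gene[!is.na(sub$fis)]]
  if (length(missing)) {
    stop("FIS missing for genes: ", paste(missing, collapse = ", "))
  }
  agg <- vapply(genes, function(g)
    aggregate(sub$fis[sub$gene == g & !is.na(sub$fis)]), numeric(1))
  genes[agg >= min_fis]
}

#' Hypergeometric pathway enrichment of selected genes
#'
#' Upper-tail hypergeometric P per subsystem (genes map to subsystems via
#' the reactions they catalyze), flagged enriched at P below \code{p_cut}.
#'
#' @param selected selected gene ids.
#' @param model a \code{metabolic_model} whose reaction subsystems define
#'   the pathways.
#' @param universe gene universe (default: all model genes).
#' @param p_cut enrichment threshold (default 0.001).
#' @return data.frame with \code{subsystem}, \code{size}, \code{overlap},
#'   \code{p_value}, \code{enriched}.
#' @export
pathway_enrichment <- function(selected, model, universe = model$genes,
                               p_cut = 0.001) {
  if (!length(universe)) stop("empty gene universe")
  rg <- reaction_gene_map(model)
  subsys_genes <- list()
  for (r in reaction_ids(model)) {
    ss <- model$reactions[[r]]$subsystem
    if (!nzchar(ss)) next
    subsys_genes[[ss]] <- union(subsys_genes[[ss]], rg[[r]])
  }
  rows <- lapply(names(subsys_genes), function(ss) {
    gs <- intersect(subsys_genes[[ss]], universe)
    k <- length(intersect(gs, selected))
    p <- stats::phyper(k - 1, length(gs), length(universe) - length(gs),
                       length(intersect(selected, universe)),
                       lower.tail = FALSE)
    data.frame(subsystem = ss, size = length(gs), overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$enriched <- out$p_value < p_cut
  out[order(out$p_value), , drop = FALSE]
}

#' The full gene-selection funnel
#'
#' Combines recurrence (with transporter exclusion), arm classification,
#' isoenzyme filter and FIS filter into one table; a gene is selected when
#' it passes all filters and belongs to at least one arm.
#'
#' @param table mutation table.
#' @param n_samples recurrence denominator.
#' @param model a \code{metabolic_model}.
#' @param threshold recurrence fraction (default 0.05).
#' @param min_fis FIS cutoff (NULL disables).
#' @return data.frame with one row per recurrent gene and the filter flags.
#' @export
mutation_screen <- function(table, n_samples, model, threshold = 0.05,
                            min_fis = 1.9) {
  rec <- recurrence_filter(table, n_samples, threshold, model = model)
  arms <- classify_arms(table, n_samples, threshold)
  iso_keep <- isoenzyme_filter(rec$gene, model)
  fis_keep <- tryCatch(fis_filter(rec$gene, table, min_fis),
                       error = function(e) stop(e))
  out <- rec
  out$arm <- vapply(out$gene, function(g)
    paste(arms[[g]], collapse = "+"), character(1))
  out$passed_isoenzyme <- out$gene %in% iso_keep
  out$passed_fis <- out$gene %in% fis_keep
  out$selected <- nzchar(out$arm) & out$passed_isoenzyme & out$passed_fis
  out
}
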