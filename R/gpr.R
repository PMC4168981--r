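#' Gene-protein-reaction (GPR) rule handling
#'
#' GPR rules are boolean AND/OR expressions over gene identifiers, e.g.
#' \code{"(g1 and g2) or g3"}. \code{and}/\code{or} are case-insensitive;
#' parentheses are required when the two operators are mixed so that the
#' grammar is unambiguous.
#'
#' @param gpr a GPR string; \code{""} or \code{NA} denotes a spontaneous
#'   (gene-independent) reaction.
#' @return \code{gpr_parse} returns a parse tree: either \code{NULL} (empty
#'   rule), a gene id string, or a list with elements \code{op} ("and"/"or")
#'   and \code{args} (list of subtrees).
#' @keywords internal
gpr_parse <- function(gpr) {
  if (is.null(gpr) || length(gpr) == 0L || is.na(gpr)) return(NULL)
  s <- trimws(gpr)
  if (!nzchar(s)) return(NULL)
  toks <- gpr_tokenize(s)
  st <- list(pos = 1L, toks = toks)
  res <- gpr_parse_expr(st)
  if (res$st$pos <= length(toks)) {
    stop("GPR parse error near token '", toks[res$st$pos], "' in: ", gpr)
  }
  res$node
}

gpr_tokenize <- function(s) {
  s <- gsub("(", " ( ", s, fixed = TRUE)
  s <- gsub(")", " ) ", s, fixed = TRUE)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# expression := term { op term }* with a single operator level; mixed
# operators without parentheses are rejected.
gpr_parse_expr <- function(st) {
  first <- gpr_parse_term(st)
  st <- first$st
  args <- list(first$node)
  op <- NULL
  while (st$pos <= length(st$toks) &&
         tolower(st$toks[st$pos]) %in% c("and", "or")) {
    this_op <- tolower(st$toks[st$pos])
    if (is.null(op)) op <- this_op
    if (this_op != op) {
      stop("ambiguous GPR: 'and' and 'or' mixed without parentheses")
    }
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_term(st)
    st <- nxt$st
    args <- c(args, list(nxt$node))
  }
  node <- if (is.null(op)) args[[1]] else list(op = op, args = args)
  list(node = node, st = st)
}

gpr_parse_term <- function(st) {
  if (st$pos > length(st$toks)) stop("GPR parse error: unexpected end of rule")
  tok <- st$toks[st$pos]
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_expr(st)
    st <- inner$st
    if (st$pos > length(st$toks) || st$toks[st$pos] != ")") {
      stop("GPR parse error: missing ')'")
    }
    st$pos <- st$pos + 1L
    return(list(node = inner$node, st = st))
  }
  if (tok %in% c(")", "and", "or")) {
    stop("GPR parse error: unexpected token '", tok, "'")
  }
  st$pos <- st$pos + 1L
  list(node = tok, st = st)
}

#' Evaluate a GPR parse tree against a gene presence map
#'
#' @param tree parse tree from \code{gpr_parse}.
#' @param present named logical vector (or function gene -> logical); genes
#'   missing from the map take \code{default}.
#' @param default value assumed for genes not named in \code{present}.
#' @return logical; empty rules evaluate to \code{TRUE} (spontaneous).
#' @keywords internal
gpr_eval <- function(tree, present, default = TRUE) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) {
    if (tree %in% names(present)) return(isTRUE(unname(present[tree])))
    return(default)
  }
  vals <- vapply(tree$args, gpr_eval, logical(1), present = present,
                 default = default)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR parse tree
#' @keywords internal
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Render a parse tree back to a canonical GPR string
#' @keywords internal
gpr_deparse <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_deparse(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
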