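# Gene-protein-reaction (GPR) boolean rules.
#
# A rule is a boolean expression over gene identifiers with AND (enzyme
# complex) and OR (isozymes) connectives. The empty rule means the reaction is
# not gene-associated and is never disabled by a knockout.

#' Parse a GPR rule string into an expression tree
#'
#' Accepts the COBRA conventions: \code{and}/\code{or} (case-insensitive),
#' \code{&&}/\code{||}, \code{&}/\code{|} and parentheses. Gene identifiers may
#' contain letters, digits, \code{_}, \code{.} and \code{-}.
#'
#' @param rule character scalar; \code{""} or \code{NA} yields the empty rule.
#' @return A list tree with nodes \code{list(op = "and"|"or", args = ...)} and
#'   leaves \code{list(op = "gene", id = ...)}, or \code{NULL} for the empty
#'   rule.
#' @export
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule)) return(NULL)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(NULL)
  toks <- regmatches(rule, gregexpr(
    "\\(|\\)|&&|\\|\\||&|\\||[A-Za-z0-9_.:-]+", rule))[[1]]
  norm <- vapply(toks, function(t) {
    tl <- tolower(t)
    if (tl %in% c("and", "&", "&&")) "AND"
    else if (tl %in% c("or", "|", "||")) "OR"
    else t
  }, character(1), USE.NAMES = FALSE)
  pos <- 1L
  n <- length(norm)
  peek <- function() if (pos <= n) norm[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (identical(peek(), "OR")) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (identical(peek(), "AND")) {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", rule,
                       "'", call. = FALSE)
    if (t == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) {
        stop("GPR parse error: unbalanced parentheses in '", rule, "'",
             call. = FALSE)
      }
      advance()
      return(e)
    }
    if (t %in% c(")", "AND", "OR")) {
      stop("GPR parse error: unexpected token '", t, "' in '", rule, "'",
           call. = FALSE)
    }
    advance()
    list(op = "gene", id = t)
  }
  tree <- parse_or()
  if (pos <= n) {
    stop("GPR parse error: trailing tokens in '", rule, "'", call. = FALSE)
  }
  tree
}

#' Evaluate a GPR tree under a set of deleted genes
#'
#' @param tree parsed rule from [parse_gpr()]; \code{NULL} (empty rule)
#'   evaluates \code{TRUE}.
#' @param deleted character vector of absent gene ids.
#' @return \code{TRUE} if the reaction remains catalysable.
#' @export
eval_gpr <- function(tree, deleted) {
  if (is.null(tree)) return(TRUE)
  switch(tree$op,
    gene = !(tree$id %in% deleted),
    and  = all(vapply(tree$args, eval_gpr, logical(1), deleted = deleted)),
    or   = any(vapply(tree$args, eval_gpr, logical(1), deleted = deleted)),
    stop("corrupt GPR tree node '", tree$op, "'", call. = FALSE))
}

#' List the gene ids referenced by a GPR tree
#' @keywords internal
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$id)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Render a GPR tree back to a normalized rule string
#' @keywords internal
gpr_string <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$op == "gene") return(tree$id)
  sub <- vapply(tree$args, function(a) {
    s <- gpr_string(a)
    if (a$op %in% c("and", "or") && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(sub, collapse = paste0(" ", tree$op, " "))
}
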