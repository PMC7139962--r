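#' @include AllClasses.R
NULL

## Atom selection mini-language
##
## Grammar (lowest to highest precedence):
##   expr    := and_expr ("or" and_expr)*
##   and_expr:= not_expr ("and" not_expr)*
##   not_expr:= "not" not_expr | primary
##   primary := "(" expr ")" | "all" | keyword value+
##   keyword := "resid" | "name" | "resname" | "element"
## Values after "resid" are author residue numbers; values after the other
## keywords are matched verbatim against the atom table.

.SEL_KEYWORDS <- c("resid", "name", "resname", "element")
.SEL_OPS <- c("and", "or", "not", "(", ")")

.selTokenize <- function(expr) {
  s <- gsub("\\(", " ( ", gsub("\\)", " ) ", expr))
  toks <- strsplit(trimws(s), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

.selError <- function(msg, pos) {
  stop(sprintf("selection parse error at token %d: %s", pos, msg),
       call. = FALSE)
}

## Recursive-descent parser producing a logical mask over the atom table.
.selParse <- function(tokens, atoms) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { t <- tokens[pos]; pos <<- pos + 1L; t }

  primary <- function() {
    t <- peek()
    if (is.na(t)) .selError("unexpected end of expression", pos)
    if (t == "(") {
      advance()
      m <- orExpr()
      if (!identical(peek(), ")")) .selError("expected ')'", pos)
      advance()
      return(m)
    }
    if (t == "all") { advance(); return(rep(TRUE, nrow(atoms))) }
    if (!(t %in% .SEL_KEYWORDS))
      .selError(sprintf("expected a keyword, got '%s'", t), pos)
    advance()
    vals <- character()
    while (!is.na(peek()) && !(peek() %in% c(.SEL_KEYWORDS, .SEL_OPS)))
      vals <- c(vals, advance())
    if (!length(vals)) .selError(sprintf("'%s' needs >= 1 value", t), pos)
    switch(t,
      resid   = atoms$author_resid %in% suppressWarnings(as.integer(vals)),
      name    = atoms$name %in% vals,
      resname = atoms$residue_name %in% vals,
      element = atoms$element %in% vals)
  }

  notExpr <- function() {
    if (identical(peek(), "not")) { advance(); return(!notExpr()) }
    primary()
  }

  andExpr <- function() {
    m <- notExpr()
    while (identical(peek(), "and")) { advance(); m <- m & notExpr() }
    m
  }

  orExpr <- function() {
    m <- andExpr()
    while (identical(peek(), "or")) { advance(); m <- m | andExpr() }
    m
  }

  m <- orExpr()
  if (!is.na(peek())) .selError(sprintf("trailing token '%s'", peek()), pos)
  m
}

#' Select atoms by a selection expression
#'
#' Supports author residue id lists (`"resid 51 74"`), atom-name lists
#' (`"name P O3' O5'"`), residue-name lists (`"resname LIG"`), element lists,
#' `all`, and `and`/`or`/`not` with parentheses. The result preserves file
#' order and is deterministic.
#'
#' @param system a [MolecularSystem].
#' @param expr character selection expression.
#' @return an [AtomGroup]; an empty selection is returned (not an error) with
#'   a warning.
#' @examples
#' ## backbone atoms used for RMSD/RMSF of nucleotides:
#' ## selectAtoms(sys, "name P O3' O5' C3' C4' C5'")
#' @export
selectAtoms <- function(system, expr) {
  stopifnot(is(system, "MolecularSystem"))
  mask <- .selParse(.selTokenize(expr), system@atoms)
  idx <- which(mask)
  if (!length(idx))
    warning(sprintf("selection '%s' matched no atoms", expr), call. = FALSE)
  new("AtomGroup", indices = as.integer(idx),
      nAtomsParent = nrow(system@atoms))
}

#' Build an AtomGroup from explicit indices
#' @param system a [MolecularSystem].
#' @param indices 1-based atom indices (order preserved, must be unique).
#' @return an [AtomGroup]
#' @export
atomGroup <- function(system, indices) {
  new("AtomGroup", indices = as.integer(indices),
      nAtomsParent = nrow(system@atoms))
}
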