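# Atom selection mini-language.
#
# Grammar (MDAnalysis/VMD-flavoured, deliberately small):
#   expr    := term ("or" term)*
#   term    := factor ("and" factor)*
#   factor  := "not" factor | "(" expr ")" | keyword value+
#   keyword := name | resname | chain | element | resid
# A keyword takes one or more value tokens (union); resid values may be
# single numbers or inclusive ranges "lo:hi". Matching is case-sensitive
# for names/resnames/chains (PDB convention: upper case).

tokenize_selection <- function(expression) {
  expression <- gsub("\\(", " ( ", expression)
  expression <- gsub("\\)", " ) ", expression)
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Resolve a selection expression against a Structure
#'
#' Supports `name`, `resname`, `chain`, `element` and `resid` (single values
#' or `lo:hi` ranges), combined with `and`, `or`, `not` and parentheses.
#' Resolution is deterministic: the returned indices are sorted ascending
#' (1-based into the atom table).
#'
#' @param x A `Structure`.
#' @param expression Selection string, e.g. `"name CA and chain A"`.
#' @return Sorted integer vector of atom indices (possibly empty).
#' @export
#' @examples
#' s <- new_structure(
#'   data.frame(atom_name = c("CA", "CB"), element = "C", resid = 1,
#'              resname = "ALA", chain = "A"),
#'   matrix(0, 2, 3))
#' select_atoms(s, "name CA")
select_atoms <- function(x, expression) {
  stopifnot(inherits(x, "Structure"))
  if (is.null(expression) || !nzchar(trimws(expression)))
    stop("empty selection expression")
  toks <- tokenize_selection(expression)
  env <- new.env(parent = emptyenv())
  env$toks <- toks; env$pos <- 1L
  peek <- function() if (env$pos <= length(env$toks)) env$toks[env$pos] else NA_character_
  advance <- function() { t <- peek(); env$pos <- env$pos + 1L; t }
  keywords <- c("name", "resname", "chain", "element", "resid")
  stoppers <- c(keywords, "and", "or", "not", "(", ")")
  a <- x$atoms

  parse_keyword <- function(kw) {
    vals <- character(0)
    while (!is.na(peek()) && !(peek() %in% stoppers)) vals <- c(vals, advance())
    if (!length(vals)) stop("selection keyword '", kw, "' needs a value")
    if (kw == "resid") {
      mask <- rep(FALSE, nrow(a))
      for (v in vals) {
        if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
          rng <- as.integer(strsplit(v, ":")[[1]])
          mask <- mask | (a$resid >= rng[1] & a$resid <= rng[2])
        } else if (grepl("^-?[0-9]+$", v)) {
          mask <- mask | (a$resid == as.integer(v))
        } else stop("bad resid value '", v, "' in selection")
      }
      mask
    } else {
      col <- switch(kw, name = a$atom_name, resname = a$resname,
                    chain = a$chain, element = a$element)
      col %in% vals
    }
  }

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of selection expression")
    if (t == "not") { advance(); return(!parse_factor()) }
    if (t == "(") {
      advance()
      m <- parse_expr()
      if (!identical(peek(), ")")) stop("unbalanced parenthesis in selection")
      advance()
      return(m)
    }
    if (t %in% keywords) { advance(); return(parse_keyword(t)) }
    stop("unexpected token '", t, "' in selection")
  }
  parse_term <- function() {
    m <- parse_factor()
    while (identical(peek(), "and")) { advance(); m <- m & parse_factor() }
    m
  }
  parse_expr <- function() {
    m <- parse_term()
    while (identical(peek(), "or")) { advance(); m <- m | parse_term() }
    m
  }

  mask <- parse_expr()
  if (!is.na(peek())) stop("trailing token '", peek(), "' in selection")
  sort(which(mask))
}

# Residue node table for a set of atom indices: unique (chain, resid) in
# ascending (chain, resid) order, with the atom indices per node.
residue_nodes <- function(x, idx) {
  a <- x$atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resid, sep = "\r")
  ord <- order(a$chain, a$resid)
  ukey <- unique(key[ord])
  first <- match(ukey, key)
  data.frame(chain = a$chain[first], resid = a$resid[first],
             resname = a$resname[first], stringsAsFactors = FALSE)
}
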