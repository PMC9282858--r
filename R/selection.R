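#' @title Atom selection grammar
#' @description A small boolean selection language over the topology atom
#'   table. Primitives:
#'   \itemize{
#'     \item `chain A B` - one or more chain identifiers
#'     \item `resid 171-177 220` - residue numbers and inclusive ranges
#'       (author numbering)
#'     \item `name CA CG N` - atom names
#'     \item `element C N O` - element symbols
#'     \item `role protein|substrate|lipid|water|other`
#'     \item `backbone` - shorthand for `name N CA C O`
#'     \item `protein`, `substrate`, `lipid`, `water` - role shorthands
#'     \item `all`, `none`
#'   }
#'   combined with `and`, `or`, `not` and parentheses; `and` binds tighter
#'   than `or`. Example: `"chain B and resid 171-177 and backbone"`.
#' @name memdyn-selection
NULL

.sel_tokenize <- function(expr) {
  pat <- "\\(|\\)|[A-Za-z0-9_'*-]+"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1) stop("empty selection expression")
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  rest <- gsub(pat, "", expr)
  rest <- gsub("[[:space:]]", "", rest)
  if (nzchar(rest)) {
    stop("selection syntax error: unexpected character(s) '", rest, "'")
  }
  data.frame(tok = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

# recursive-descent parser over a token stream held in an environment
.sel_parse <- function(env) {
  node <- .sel_parse_term(env)
  while (!is.null(.sel_peek(env)) && identical(tolower(.sel_peek(env)), "or")) {
    .sel_next(env)
    rhs <- .sel_parse_term(env)
    node <- list(op = "or", a = node, b = rhs)
  }
  node
}

.sel_parse_term <- function(env) {
  node <- .sel_parse_factor(env)
  while (!is.null(.sel_peek(env)) && identical(tolower(.sel_peek(env)), "and")) {
    .sel_next(env)
    rhs <- .sel_parse_factor(env)
    node <- list(op = "and", a = node, b = rhs)
  }
  node
}

.sel_keywords <- c("and", "or", "not", "chain", "resid", "name", "element",
                   "role", "backbone", "protein", "substrate", "lipid",
                   "water", "all", "none", "(", ")")

.sel_parse_factor <- function(env) {
  tok <- .sel_peek(env)
  if (is.null(tok)) .sel_err(env, "unexpected end of expression")
  low <- tolower(tok)
  if (low == "not") {
    .sel_next(env)
    return(list(op = "not", a = .sel_parse_factor(env)))
  }
  if (tok == "(") {
    .sel_next(env)
    node <- .sel_parse(env)
    if (!identical(.sel_peek(env), ")")) .sel_err(env, "expected ')'")
    .sel_next(env)
    return(node)
  }
  if (low %in% c("chain", "resid", "name", "element", "role")) {
    .sel_next(env)
    # role names are valid arguments of 'role', not keywords there
    stopset <- if (low == "role") {
      setdiff(.sel_keywords, c("protein", "substrate", "lipid", "water"))
    } else .sel_keywords
    args <- character(0)
    repeat {
      nxt <- .sel_peek(env)
      if (is.null(nxt) || tolower(nxt) %in% stopset) break
      args <- c(args, nxt)
      .sel_next(env)
    }
    if (!length(args)) .sel_err(env, paste0("'", low, "' needs arguments"))
    return(list(op = low, args = args))
  }
  if (low %in% c("backbone", "protein", "substrate", "lipid", "water",
                 "all", "none")) {
    .sel_next(env)
    return(list(op = low))
  }
  .sel_err(env, paste0("unexpected token '", tok, "'"))
}

.sel_peek <- function(env) {
  if (env$i > nrow(env$toks)) NULL else env$toks$tok[env$i]
}
.sel_next <- function(env) env$i <- env$i + 1L
.sel_err <- function(env, msg) {
  pos <- if (env$i <= nrow(env$toks)) env$toks$pos[env$i] else nchar(env$expr) + 1L
  stop(sprintf("selection syntax error at position %d: %s", pos, msg))
}

.sel_eval <- function(node, atoms) {
  switch(node$op,
    "or"  = .sel_eval(node$a, atoms) | .sel_eval(node$b, atoms),
    "and" = .sel_eval(node$a, atoms) & .sel_eval(node$b, atoms),
    "not" = !.sel_eval(node$a, atoms),
    "chain" = atoms$chain %in% node$args,
    "name" = atoms$name %in% node$args,
    "element" = toupper(atoms$element) %in% toupper(node$args),
    "role" = atoms$role %in% tolower(node$args),
    "resid" = atoms$resid %in% .sel_resid_set(node$args),
    "backbone" = atoms$name %in% c("N", "CA", "C", "O"),
    "protein" = atoms$role == "protein",
    "substrate" = atoms$role == "substrate",
    "lipid" = atoms$role == "lipid",
    "water" = atoms$role == "water",
    "all" = rep(TRUE, nrow(atoms)),
    "none" = rep(FALSE, nrow(atoms)),
    stop("unknown selection node op: ", node$op)
  )
}

.sel_resid_set <- function(args) {
  out <- integer(0)
  for (a in args) {
    if (grepl("^-?[0-9]+--?[0-9]+$", a)) {
      # range "lo-hi"; negative bounds written e.g. "-5--2"
      parts <- regmatches(a, regexec("^(-?[0-9]+)-(-?[0-9]+)$", a))[[1]]
      out <- c(out, seq.int(as.integer(parts[2]), as.integer(parts[3])))
    } else if (grepl("^-?[0-9]+$", a)) {
      out <- c(out, as.integer(a))
    } else {
      stop("selection syntax error: bad resid argument '", a, "'")
    }
  }
  out
}

#' Resolve a selection expression against a topology
#'
#' Resolution is deterministic and order preserving: the returned indices
#' follow topology atom order. An empty result is permitted but flagged
#' with a warning.
#'
#' @param top a `Topology`.
#' @param expr selection string in the grammar of [memdyn-selection].
#' @param name optional selection name.
#' @return object of class `Selection` with fields `name`, `indices`
#'   (1-based atom rows) and `definition`.
#' @export
resolve_selection <- function(top, expr, name = expr) {
  env <- new.env(parent = emptyenv())
  env$toks <- .sel_tokenize(expr)
  env$i <- 1L
  env$expr <- expr
  node <- .sel_parse(env)
  if (env$i <= nrow(env$toks)) .sel_err(env, "trailing tokens")
  mask <- .sel_eval(node, top$atoms)
  idx <- which(mask)
  if (!length(idx)) warning("selection '", expr, "' matched no atoms")
  structure(list(name = name, indices = idx, definition = expr),
            class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat(sprintf("Selection '%s': %d atoms  [%s]\n", x$name,
              length(x$indices), x$definition))
  invisible(x)
}

#' Residues covered by a selection
#' @param top a `Topology`.
#' @param sel a `Selection`.
#' @return integer vector of rows into `top$residues`.
#' @keywords internal
selection_residues <- function(top, sel) {
  unique(findInterval(sel$indices, top$residues$first))
}
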