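#' Parse a gene-protein-reaction (GPR) boolean expression
#'
#' GPR rules state which genes enable a reaction as a boolean expression
#' over gene identifiers, e.g. `"(b0001 and b0002) or b0003"`. Keywords
#' `and`/`or` are matched case-insensitively; `&&` and `||` are accepted
#' as synonyms. Precedence is parentheses > AND > OR; gene tokens keep
#' their original case.
#'
#' @param expr a GPR expression string.
#' @return a `gn_gpr` tree: either a leaf (list with `gene`) or an
#'   internal node (list with `op` in `"and"`/`"or"` and `args`, a list
#'   of subtrees).
#' @export
#' @examples
#' g <- parse_gpr("(b0001 and b0002) or b0003")
#' gpr_genes(g)
#' format_gpr(g)
parse_gpr <- function(expr) {
  if (!is.character(expr) || length(expr) != 1 || is.na(expr)) {
    abort("GPR expression must be a single string")
  }
  toks <- gpr_tokenise(expr)
  if (nrow(toks) == 0) abort("empty GPR expression")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st, expr)
  if (st$pos <= nrow(st$toks)) {
    gpr_syntax_error(expr, st$toks$at[st$pos],
                     paste0("unexpected '", st$toks$text[st$pos], "'"))
  }
  structure(tree, class = "gn_gpr")
}

gpr_tokenise <- function(expr) {
  m <- gregexpr("\\(|\\)|&&|\\|\\||[^()&|[:space:]]+", expr)[[1]]
  if (m[1] == -1) return(tibble(text = character(), type = character(),
                                at = integer()))
  text <- regmatches(expr, gregexpr("\\(|\\)|&&|\\|\\||[^()&|[:space:]]+",
                                    expr))[[1]]
  low <- tolower(text)
  type <- dplyr::case_when(
    text == "(" ~ "lpar",
    text == ")" ~ "rpar",
    low == "and" | text == "&&" ~ "and",
    low == "or" | text == "||" ~ "or",
    TRUE ~ "gene"
  )
  # stray single & or | would have been dropped by the token regex; catch them
  resid <- gsub("\\(|\\)|&&|\\|\\||[^()&|[:space:]]+|[[:space:]]+", "", expr)
  if (nzchar(resid)) {
    abort(paste0("invalid character(s) in GPR expression: '", resid, "'"))
  }
  tibble(text = text, type = type, at = as.integer(m))
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

gpr_syntax_error <- function(expr, at, what) {
  abort(sprintf("GPR syntax error at position %d: %s (in \"%s\")",
                at, what, expr))
}

gpr_parse_or <- function(st, expr) {
  args <- list(gpr_parse_and(st, expr))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, expr)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st, expr) {
  args <- list(gpr_parse_atom(st, expr))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st, expr)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st, expr) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    gpr_syntax_error(expr, nchar(expr) + 1L, "dangling operator")
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(list(gene = tk$text))
  }
  if (tk$type == "lpar") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, expr)
    close <- gpr_peek(st)
    if (is.null(close) || close$type != "rpar") {
      gpr_syntax_error(expr, tk$at, "unbalanced parenthesis")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  gpr_syntax_error(expr, tk$at, paste0("unexpected '", tk$text, "'"))
}

gpr_is_leaf <- function(x) !is.null(x$gene)

#' Serialise a GPR tree back to a string
#'
#' The output re-parses to an identical tree; inner sub-expressions are
#' parenthesised.
#'
#' @param x a `gn_gpr` tree.
#' @return a single string.
#' @export
format_gpr <- function(x) {
  fmt <- function(node, top) {
    if (gpr_is_leaf(node)) return(node$gene)
    parts <- vapply(node$args, fmt, character(1), top = FALSE)
    s <- paste(parts, collapse = paste0(" ", node$op, " "))
    if (top) s else paste0("(", s, ")")
  }
  fmt(x, top = TRUE)
}

#' Gene identifiers appearing in a GPR tree
#'
#' @param x a `gn_gpr` tree.
#' @return sorted unique character vector of gene tokens.
#' @export
gpr_genes <- function(x) {
  collect <- function(node) {
    if (gpr_is_leaf(node)) return(node$gene)
    unlist(lapply(node$args, collect))
  }
  sort(unique(collect(x)))
}

#' @export
print.gn_gpr <- function(x, ...) {
  cat("<gn_gpr>", format_gpr(x), "\n")
  invisible(x)
}
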