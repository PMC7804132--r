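# Boolean rule expressions: tokenizer, recursive-descent parser, renderer,
# and an R-side evaluator used as the slow reference path in tests.
#
# Tree node shapes:
#   list(type = "var",   name = <chr>)
#   list(type = "const", value = <lgl>)
#   list(type = "not",   x = <expr>)
#   list(type = "and",   lhs = <expr>, rhs = <expr>)
#   list(type = "or",    lhs = <expr>, rhs = <expr>)

tokenize_expr <- function(text) {
  x <- gsub("([!()&|])", " \\1 ", text)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  # word operators and constants normalized to symbol form
  map <- c(AND = "&", and = "&", OR = "|", or = "|", NOT = "!", not = "!",
           TRUE. = "1", FALSE. = "0")
  up <- toupper(toks)
  toks[up == "AND"] <- "&"
  toks[up == "OR"] <- "|"
  toks[up == "NOT"] <- "!"
  toks[up == "TRUE"] <- "1"
  toks[up == "FALSE"] <- "0"
  toks
}

#' Parse a Boolean rule expression
#'
#' Accepts the BoolNet operator dialect (`!`, `&`, `|`, parentheses, the
#' constants `0`/`1`) as well as the word forms `NOT`/`AND`/`OR` and
#' `TRUE`/`FALSE`. Operator precedence is `!` over `&` over `|`.
#'
#' @param text a single expression string, e.g. `"APP & (BACE1 | !autophagy)"`.
#' @return an expression tree (nested list) used by [boolean_network()].
#' @export
parse_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_expr(text)
  if (length(toks) == 0L) stop("empty expression")
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }

  parse_or <- function() {
    e <- parse_and()
    while (identical(peek(), "|")) {
      advance()
      e <- list(type = "or", lhs = e, rhs = parse_and())
    }
    e
  }
  parse_and <- function() {
    e <- parse_factor()
    while (identical(peek(), "&")) {
      advance()
      e <- list(type = "and", lhs = e, rhs = parse_factor())
    }
    e
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression")
    if (t == "!") { advance(); return(list(type = "not", x = parse_factor())) }
    if (t == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) stop("missing closing parenthesis")
      advance()
      return(e)
    }
    if (t == "0") { advance(); return(list(type = "const", value = FALSE)) }
    if (t == "1") { advance(); return(list(type = "const", value = TRUE)) }
    if (grepl("^[A-Za-z_][A-Za-z0-9_.]*$", t)) {
      advance()
      return(list(type = "var", name = t))
    }
    stop("unexpected token '", t, "' in expression")
  }

  e <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens after expression: '", paste(toks[pos:length(toks)], collapse = " "), "'")
  e
}

#' Variables referenced by an expression
#' @param expr an expression tree from [parse_expr()].
#' @return character vector of distinct node names, in first-appearance order.
#' @export
expr_vars <- function(expr) {
  switch(expr$type,
    var = expr$name,
    const = character(0),
    not = expr_vars(expr$x),
    unique(c(expr_vars(expr$lhs), expr_vars(expr$rhs))))
}

#' Render an expression tree back to rule-file text
#' @param expr an expression tree.
#' @return a single string in `!`/`&`/`|` notation with minimal parentheses.
#' @export
render_expr <- function(expr) {
  prec <- function(e) switch(e$type, or = 1L, and = 2L, 3L)
  wrap <- function(e, min_prec) {
    s <- render_expr(e)
    if (prec(e) < min_prec) paste0("(", s, ")") else s
  }
  switch(expr$type,
    var = expr$name,
    const = if (expr$value) "1" else "0",
    not = paste0("!", wrap(expr$x, 3L)),
    and = paste(wrap(expr$lhs, 2L), "&", wrap(expr$rhs, 2L)),
    or = paste(wrap(expr$lhs, 1L), "|", wrap(expr$rhs, 1L)))
}

#' Evaluate an expression under a node-value assignment
#' @param expr expression tree.
#' @param values named logical/0-1 vector supplying every referenced variable.
#' @return logical scalar.
#' @export
eval_expr <- function(expr, values) {
  switch(expr$type,
    var = {
      v <- values[[expr$name]]
      if (is.null(v) || is.na(v)) stop("no value for variable '", expr$name, "'")
      as.logical(v)
    },
    const = expr$value,
    not = !eval_expr(expr$x, values),
    and = eval_expr(expr$lhs, values) && eval_expr(expr$rhs, values),
    or = eval_expr(expr$lhs, values) || eval_expr(expr$rhs, values))
}

# full truth table of an expression over its variables (reference oracle for
# serialization round-trips); returns logical vector of length 2^k
expr_truth_table <- function(expr, vars = expr_vars(expr)) {
  k <- length(vars)
  if (k == 0L) return(eval_expr(expr, logical(0)))
  n_rows <- 2L^k
  out <- logical(n_rows)
  for (i in seq_len(n_rows) - 1L) {
    bits <- as.logical(bitwAnd(bitwShiftR(i, seq_len(k) - 1L), 1L))
    names(bits) <- vars
    out[i + 1L] <- eval_expr(expr, bits)
  }
  out
}

# compile to postfix program for the C++ engine
# tokens: >=0 variable index (0-based), -1 NOT, -2 AND, -3 OR, -4 const0, -5 const1
compile_expr <- function(expr, index) {
  switch(expr$type,
    var = {
      i <- index[[expr$name]]
      if (is.null(i)) stop("undeclared variable '", expr$name, "'")
      i - 1L
    },
    const = if (expr$value) -5L else -4L,
    not = c(compile_expr(expr$x, index), -1L),
    and = c(compile_expr(expr$lhs, index), compile_expr(expr$rhs, index), -2L),
    or = c(compile_expr(expr$lhs, index), compile_expr(expr$rhs, index), -3L))
}
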