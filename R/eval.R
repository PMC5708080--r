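#' @title Expression evaluator
#' @description
#' A small expression language over the op registry.  Grammar (EBNF):
#'
#' ```
#' expr    = term { ("+" | "-") term } ;
#' term    = factor { ("*" | "/") factor } ;
#' factor  = "-" factor | primary ;
#' primary = number | string | ident [ "(" [ expr { "," expr } ] ")" ]
#'         | "(" expr ")" ;
#' number  = digits [ "." digits ] [ ("e"|"E") ["+"|"-"] digits ] ;
#' string  = '"' chars '"' ;
#' ident   = letter { letter | digit | "_" | "." } ;
#' ```
#'
#' Binary operators are left-associative with standard precedence.
#' Identifiers resolve against the caller-supplied bindings; calls
#' `name(args, ...)` dispatch through [resolve_op()]/[run_op()], so
#' `sub(gauss(image, 2), gauss(image, 1))` runs the same op tree as the
#' difference-of-Gaussians op.  Operators on images dispatch to the
#' `math.*` ops; on scalars they use real arithmetic (`/` is real-valued);
#' `+` on strings concatenates (numbers are rendered canonically first).
#' @name expression-eval
NULL

eval_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    if (grepl("^[0-9]$", ch) ||
        (ch == "." && grepl("^[0-9]$", substr(text, i + 1L, i + 1L)))) {
      mm <- regmatches(substr(text, i, n),
                       regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                               substr(text, i, n)))
      push("number", as.numeric(mm), i)
      i <- i + nchar(mm)
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      mm <- regmatches(substr(text, i, n),
                       regexpr("^[A-Za-z_][A-Za-z0-9_.]*", substr(text, i, n)))
      push("ident", mm, i)
      i <- i + nchar(mm)
      next
    }
    if (ch == '"') {
      j <- i + 1L
      buf <- character(0)
      while (j <= n && substr(text, j, j) != '"') {
        cj <- substr(text, j, j)
        if (cj == "\\" && j < n) { j <- j + 1L; cj <- substr(text, j, j) }
        buf <- c(buf, cj)
        j <- j + 1L
      }
      if (j > n) stop("parse error at position ", i, ": unterminated string")
      push("string", paste0(buf, collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch %in% c("+", "-", "*", "/", "(", ")", ",", "=")) {
      push(ch, ch, i)
      i <- i + 1L
      next
    }
    stop("parse error at position ", i, ": unexpected character '", ch, "'")
  }
  push("eof", "", n + 1L)
  tokens
}

# recursive-descent parser producing a nested list AST
eval_parse <- function(text) {
  tokens <- eval_tokenize(text)
  k <- 1L
  peek <- function() tokens[[k]]
  advance <- function() { t <- tokens[[k]]; k <<- k + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (t$type != type)
      stop("parse error at position ", t$pos, ": expected '", type,
           "', found '", t$type, "'")
    advance()
  }
  parse_expr <- function() {
    node <- parse_term()
    while (peek()$type %in% c("+", "-")) {
      opn <- advance()$type
      node <- list(kind = "binop", op = opn, lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (peek()$type %in% c("*", "/")) {
      opn <- advance()$type
      node <- list(kind = "binop", op = opn, lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    if (peek()$type == "-") {
      advance()
      return(list(kind = "neg", value = parse_factor()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (t$type == "number") { advance(); return(list(kind = "number", value = t$value)) }
    if (t$type == "string") { advance(); return(list(kind = "string", value = t$value)) }
    if (t$type == "ident") {
      advance()
      if (peek()$type == "(") {
        advance()
        args <- list()
        if (peek()$type != ")") {
          repeat {
            args[[length(args) + 1L]] <- parse_expr()
            if (peek()$type != ",") break
            advance()
          }
        }
        expect(")")
        return(list(kind = "call", name = t$value, args = args))
      }
      return(list(kind = "ident", name = t$value, pos = t$pos))
    }
    if (t$type == "(") {
      advance()
      node <- parse_expr()
      expect(")")
      return(node)
    }
    stop("parse error at position ", t$pos, ": unexpected '", t$type, "'")
  }
  node <- parse_expr()
  t <- peek()
  if (t$type != "eof")
    stop("parse error at position ", t$pos, ": trailing input")
  node
}

num_to_string <- function(x) {
  if (is.numeric(x)) render_value(x) else x
}

# binary operator application with image dispatch
eval_apply_binop <- function(ctx, opn, a, b) {
  img_a <- is_ndimg(a) || is_dataset(a)
  img_b <- is_ndimg(b) || is_dataset(b)
  if (img_a || img_b) {
    fam <- c("+" = "math.add", "-" = "math.sub",
             "*" = "math.mul", "/" = "math.div")[[opn]]
    return(run_op(ctx, fam, list(a, b)))
  }
  if (opn == "+" && (is.character(a) || is.character(b)))
    return(paste0(num_to_string(a), num_to_string(b)))
  if (!is.numeric(a) || !is.numeric(b))
    stop("operator '", opn, "' undefined for ", type_of(a), " and ", type_of(b))
  switch(opn, "+" = a + b, "-" = a - b, "*" = a * b, "/" = a / b)
}

eval_node <- function(ctx, node, bindings) {
  switch(node$kind,
    number = node$value,
    string = node$value,
    ident = {
      if (!node$name %in% names(bindings))
        stop("unbound identifier '", node$name, "' at position ", node$pos)
      bindings[[node$name]]
    },
    call = {
      args <- lapply(node$args, eval_node, ctx = ctx, bindings = bindings)
      run_op(ctx, node$name, args)
    },
    neg = {
      v <- eval_node(ctx, node$value, bindings)
      if (is_ndimg(v) || is_dataset(v)) run_op(ctx, "math.mul", list(v, -1))
      else -v
    },
    binop = eval_apply_binop(ctx, node$op,
                             eval_node(ctx, node$lhs, bindings),
                             eval_node(ctx, node$rhs, bindings)))
}

#' Evaluate an expression string
#'
#' @param ctx a context
#' @param expr expression text (see the grammar in the package vignette)
#' @param bindings named list giving values for free identifiers
#' @return the evaluated value (number, string or image)
#' @export
op_eval <- function(ctx, expr, bindings = list()) {
  eval_node(ctx, eval_parse(expr), bindings)
}
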