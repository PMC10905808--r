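# Tokenizer and recursive-descent parser for REDCap branching-logic and
# calculated-field expressions.
#
# Precedence, lowest to highest:
#   or < and < not < comparisons (non-associative) < + - < * / <
#   unary minus < ^ (right-associative, so -x^2 parses as -(x^2))

LOGIC_FUNCTIONS <- list(
  "if" = c(3L, 3L), datediff = c(3L, 4L), round = c(1L, 2L),
  roundup = c(1L, 2L), rounddown = c(1L, 2L), abs = c(1L, 1L),
  sqrt = c(1L, 1L), min = c(1L, NA), max = c(1L, NA),
  sum = c(1L, NA), mean = c(1L, NA)
)

new_token <- function(kind, text, pos, value = NULL) {
  list(kind = kind, text = text, pos = pos, value = value)
}

#' Tokenize a REDCap logic expression
#'
#' Splits an expression string into tokens. `[name]` is a field reference,
#' `[name(code)]` a checkbox option reference, and a bracketed name
#' containing a hyphen (e.g. `[event-name]`) a smart variable. String
#' literals accept single or double quotes. Positions are 0-based
#' character offsets into the source.
#'
#' @param source An expression string (may be empty).
#' @return A list of tokens, each `list(kind, text, pos, value)`.
#' @export
tokenize_logic <- function(source) {
  if (is.null(source) || length(source) != 1L || is.na(source)) {
    parse_error("expression must be a single string", 0L)
  }
  n <- nchar(source)
  toks <- vector("list", 0L)
  i <- 1L
  push <- function(tok) toks[[length(toks) + 1L]] <<- tok
  while (i <= n) {
    ch <- substr(source, i, i)
    pos0 <- i - 1L
    if (ch %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }

    if (ch == "[") {
      rest <- substr(source, i, n)
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0) parse_error("unterminated '['", pos0)
      text <- substr(rest, 1, close)
      content <- substr(rest, 2, close - 1L)
      if (grepl("^[A-Za-z0-9_]+\\([A-Za-z0-9_]+\\)$", content)) {
        name <- sub("\\(.*$", "", content)
        code <- sub("^.*\\(", "", sub("\\)$", "", content))
        push(new_token("checkbox_ref", text, pos0, list(name = name, code = code)))
      } else if (grepl("-", content, fixed = TRUE)) {
        push(new_token("smart_var", text, pos0, content))
      } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", content)) {
        push(new_token("field_ref", text, pos0, content))
      } else {
        parse_error(sprintf("invalid bracketed name '[%s]'", content), pos0)
      }
      i <- i + close
      next
    }

    if (ch %in% c("'", '"')) {
      rest <- substring(source, i + 1L)
      close <- regexpr(ch, rest, fixed = TRUE)
      if (close < 0) parse_error("unterminated string literal", pos0)
      inner <- substr(rest, 1, close - 1L)
      push(new_token("string", substr(source, i, i + close), pos0, inner))
      i <- i + close + 1L
      next
    }

    if (grepl("^[0-9]$", ch) ||
        (ch == "." && grepl("^[0-9]$", substr(source, i + 1L, i + 1L)))) {
      m <- regexpr("^[0-9]*\\.?[0-9]+|^[0-9]+\\.?", substring(source, i))
      len <- attr(m, "match.length")
      text <- substr(source, i, i + len - 1L)
      push(new_token("number", text, pos0, as.numeric(text)))
      i <- i + len
      next
    }

    two <- substr(source, i, i + 1L)
    if (two %in% c("<>", "<=", ">=", "!=")) {
      op <- if (two == "!=") "<>" else two
      push(new_token("operator", two, pos0, op))
      i <- i + 2L
      next
    }
    if (ch %in% c("=", "<", ">", "+", "-", "*", "/", "^")) {
      push(new_token("operator", ch, pos0, ch))
      i <- i + 1L
      next
    }
    if (ch == "(") { push(new_token("lparen", ch, pos0)); i <- i + 1L; next }
    if (ch == ")") { push(new_token("rparen", ch, pos0)); i <- i + 1L; next }
    if (ch == ",") { push(new_token("comma", ch, pos0)); i <- i + 1L; next }

    if (grepl("^[A-Za-z_]$", ch)) {
      m <- regexpr("^[A-Za-z_][A-Za-z0-9_]*", substring(source, i))
      len <- attr(m, "match.length")
      word <- substr(source, i, i + len - 1L)
      lw <- tolower(word)
      if (lw %in% c("and", "or", "not")) {
        push(new_token("operator", word, pos0, lw))
      } else {
        push(new_token("func_name", word, pos0, lw))
      }
      i <- i + len
      next
    }

    parse_error(sprintf("unexpected character '%s'", ch), pos0)
  }
  toks
}

# AST node constructors; plain lists so identical() works for round-trips.
ast_field <- function(name, code = NULL, event = NULL) {
  list(node = "field", name = name, code = code, event = event)
}
ast_lit <- function(type, value = NULL) list(node = "lit", type = type, value = value)
ast_unary <- function(op, x) list(node = "unary", op = op, x = x)
ast_binary <- function(op, left, right) {
  list(node = "binary", op = op, left = left, right = right)
}
ast_call <- function(fn, args) list(node = "call", fn = fn, args = args)
ast_smart <- function(name) list(node = "smart", name = name)

#' Parse a REDCap logic expression into an AST
#'
#' @param x Either an expression string or a token list from
#'   [tokenize_logic()].
#' @return An AST: nested lists with a `node` discriminator among
#'   `field`, `lit`, `unary`, `binary`, `call`, `smart`.
#' @export
parse_logic <- function(x) {
  toks <- if (is.character(x)) tokenize_logic(x) else x
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { t <- peek(); st$i <- st$i + 1L; t }
  expect <- function(kind, what) {
    t <- peek()
    if (is.null(t)) parse_error(paste("expected", what, "but input ended"),
                                end_pos(st$toks))
    if (t$kind != kind) parse_error(paste0("expected ", what, ", found '",
                                           t$text, "'"), t$pos)
    advance()
  }
  at_op <- function(ops) {
    t <- peek()
    !is.null(t) && t$kind == "operator" && t$value %in% ops
  }

  p_or <- function() {
    left <- p_and()
    while (at_op("or")) { advance(); left <- ast_binary("or", left, p_and()) }
    left
  }
  p_and <- function() {
    left <- p_not()
    while (at_op("and")) { advance(); left <- ast_binary("and", left, p_not()) }
    left
  }
  p_not <- function() {
    if (at_op("not")) { advance(); return(ast_unary("not", p_not())) }
    p_cmp()
  }
  p_cmp <- function() {
    left <- p_add()
    if (at_op(c("=", "<>", "<", "<=", ">", ">="))) {
      op <- advance()$value
      right <- p_add()
      if (at_op(c("=", "<>", "<", "<=", ">", ">="))) {
        t <- peek()
        parse_error("comparisons are non-associative; use parentheses", t$pos)
      }
      return(ast_binary(op, left, right))
    }
    left
  }
  p_add <- function() {
    left <- p_mul()
    while (at_op(c("+", "-"))) {
      op <- advance()$value
      left <- ast_binary(op, left, p_mul())
    }
    left
  }
  p_mul <- function() {
    left <- p_unary()
    while (at_op(c("*", "/"))) {
      op <- advance()$value
      left <- ast_binary(op, left, p_unary())
    }
    left
  }
  p_unary <- function() {
    if (at_op("-")) { advance(); return(ast_unary("neg", p_unary())) }
    p_pow()
  }
  p_pow <- function() {
    base <- p_atom()
    if (at_op("^")) {
      advance()
      return(ast_binary("^", base, p_unary()))  # right-assoc exponent
    }
    base
  }
  p_atom <- function() {
    t <- peek()
    if (is.null(t)) parse_error("unexpected end of expression", end_pos(st$toks))
    if (t$kind == "number") { advance(); return(ast_lit("number", t$value)) }
    if (t$kind == "string") {
      advance()
      if (!nzchar(t$value)) return(ast_lit("blank"))
      return(ast_lit("string", t$value))
    }
    if (t$kind %in% c("field_ref", "checkbox_ref", "smart_var")) {
      advance()
      nxt <- peek()
      # [event][field] / [smart-var][field]: event-qualified reference
      if (!is.null(nxt) && nxt$kind %in% c("field_ref", "checkbox_ref") &&
          t$kind %in% c("field_ref", "smart_var")) {
        qual <- if (t$kind == "smart_var") t$value else t$value
        advance()
        if (nxt$kind == "checkbox_ref") {
          return(ast_field(nxt$value$name, code = nxt$value$code, event = qual))
        }
        return(ast_field(nxt$value, event = qual))
      }
      if (t$kind == "field_ref") return(ast_field(t$value))
      if (t$kind == "checkbox_ref") {
        return(ast_field(t$value$name, code = t$value$code))
      }
      return(ast_smart(t$value))
    }
    if (t$kind == "func_name") {
      advance()
      nxt <- peek()
      if (is.null(nxt) || nxt$kind != "lparen") {
        parse_error(sprintf("unexpected identifier '%s'", t$text), t$pos)
      }
      if (!(t$value %in% names(LOGIC_FUNCTIONS))) {
        parse_error(sprintf("unknown function '%s'", t$text), t$pos)
      }
      advance()  # (
      args <- list()
      if (!is.null(peek()) && peek()$kind != "rparen") {
        args[[1L]] <- p_or()
        while (!is.null(peek()) && peek()$kind == "comma") {
          advance()
          args[[length(args) + 1L]] <- p_or()
        }
      }
      expect("rparen", "')'")
      sig <- LOGIC_FUNCTIONS[[t$value]]
      if (length(args) < sig[1] || (!is.na(sig[2]) && length(args) > sig[2])) {
        parse_error(sprintf("function '%s' takes %s argument(s), got %d",
                            t$value,
                            if (is.na(sig[2])) paste0(">=", sig[1])
                            else if (sig[1] == sig[2]) sig[1]
                            else paste0(sig[1], "-", sig[2]),
                            length(args)), t$pos)
      }
      return(ast_call(t$value, args))
    }
    if (t$kind == "lparen") {
      advance()
      inner <- p_or()
      expect("rparen", "')'")
      return(inner)
    }
    parse_error(sprintf("unexpected token '%s'", t$text), t$pos)
  }

  if (length(toks) == 0L) parse_error("empty expression", 0L)
  ast <- p_or()
  t <- peek()
  if (!is.null(t)) parse_error(sprintf("unexpected token '%s'", t$text), t$pos)
  ast
}

end_pos <- function(toks) {
  if (!length(toks)) return(0L)
  last <- toks[[length(toks)]]
  last$pos + nchar(last$text)
}

# Render an AST back to REDCap syntax. Children of compound nodes are
# fully parenthesized, so parse(render_logic(ast)) reproduces ast exactly.
#' Render an AST in REDCap expression syntax
#' @param ast An AST from [parse_logic()].
#' @return A single string that reparses to an identical AST.
#' @export
render_logic <- function(ast) {
  wrap <- function(node) {
    s <- render_logic(node)
    if (node$node %in% c("binary", "unary")) paste0("(", s, ")") else s
  }
  switch(ast$node,
    field = {
      ref <- if (is.null(ast$code)) paste0("[", ast$name, "]")
             else paste0("[", ast$name, "(", ast$code, ")]")
      if (is.null(ast$event)) ref else paste0("[", ast$event, "]", ref)
    },
    smart = paste0("[", ast$name, "]"),
    lit = switch(ast$type,
      number = format(ast$value, scientific = FALSE, trim = TRUE),
      string = paste0("'", ast$value, "'"),
      blank = "''"),
    unary = if (ast$op == "not") paste0("not ", wrap(ast$x))
            else paste0("-", wrap(ast$x)),
    binary = paste(wrap(ast$left), ast$op, wrap(ast$right)),
    call = paste0(ast$fn, "(",
                  paste(vapply(ast$args, render_logic, character(1)),
                        collapse = ", "), ")"),
    stop("unknown AST node: ", ast$node)
  )
}
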