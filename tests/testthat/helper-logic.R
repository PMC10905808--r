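# Independent brute-force interpreter for three-valued (Kleene) logic,
# used as the oracle against eval_logic(). It enumerates the truth tables
# directly and never calls the package's evaluator.

k_not <- function(x) {
  if (is.na(x)) NA else if (x) FALSE else TRUE
}
k_and <- function(x, y) {
  if (identical(x, FALSE) || identical(y, FALSE)) return(FALSE)
  if (isTRUE(x) && isTRUE(y)) return(TRUE)
  NA
}
k_or <- function(x, y) {
  if (isTRUE(x) || isTRUE(y)) return(TRUE)
  if (identical(x, FALSE) && identical(y, FALSE)) return(FALSE)
  NA
}

# Operand resolution for the oracle: fields come from `vals` ("" = blank),
# literals are carried as-is; the marker list(blank_lit = TRUE) is the
# syntactic '' literal.
oracle_operand <- function(node, vals) {
  if (node$node == "field") {
    v <- vals[[node$name]]
    if (is.null(v) || identical(v, "")) return(list(blank = TRUE))
    return(list(blank = FALSE, value = v, lit_blank = FALSE))
  }
  if (node$node == "lit") {
    if (node$type == "blank") return(list(blank = TRUE, lit_blank = TRUE))
    return(list(blank = FALSE, value = as.character(node$value),
                lit_blank = FALSE))
  }
  stop("oracle only handles field/literal operands")
}

oracle_cmp <- function(op, lnode, rnode, vals) {
  l <- oracle_operand(lnode, vals)
  r <- oracle_operand(rnode, vals)
  lit_blank <- isTRUE(l$lit_blank) || isTRUE(r$lit_blank)
  if (op %in% c("=", "<>") && lit_blank) {
    other_blank <- if (isTRUE(l$lit_blank)) isTRUE(r$blank) else isTRUE(l$blank)
    return(if (op == "=") other_blank else !other_blank)
  }
  if (isTRUE(l$blank) || isTRUE(r$blank)) return(NA)
  ln <- suppressWarnings(as.numeric(l$value))
  rn <- suppressWarnings(as.numeric(r$value))
  if (!is.na(ln) && !is.na(rn)) {
    return(switch(op, "=" = ln == rn, "<>" = ln != rn, "<" = ln < rn,
                  "<=" = ln <= rn, ">" = ln > rn, ">=" = ln >= rn))
  }
  switch(op, "=" = l$value == r$value, "<>" = l$value != r$value,
         "<" = l$value < r$value, "<=" = l$value <= r$value,
         ">" = l$value > r$value, ">=" = l$value >= r$value)
}

oracle_truth <- function(ast, vals) {
  if (ast$node == "unary" && ast$op == "not") {
    return(k_not(oracle_truth(ast$x, vals)))
  }
  if (ast$node == "binary" && ast$op == "and") {
    return(k_and(oracle_truth(ast$left, vals), oracle_truth(ast$right, vals)))
  }
  if (ast$node == "binary" && ast$op == "or") {
    return(k_or(oracle_truth(ast$left, vals), oracle_truth(ast$right, vals)))
  }
  if (ast$node == "binary") {
    return(oracle_cmp(ast$op, ast$left, ast$right, vals))
  }
  stop("oracle cannot interpret node ", ast$node)
}

# Random boolean expression strings over fields a, b, c.
rand_cmp_string <- function(allow_blank_lit = TRUE) {
  field <- sample(c("a", "b", "c"), 1)
  if (stats::runif(1) < 0.15) {  # field-vs-field comparison
    other <- sample(c("a", "b", "c"), 1)
    op <- sample(c("=", "<>", "<", ">"), 1)
    return(sprintf("[%s] %s [%s]", field, op, other))
  }
  op <- sample(c("=", "<>", "<", "<=", ">", ">="), 1)
  lits <- c("0", "1", "2", "'0'", "'1'", "'2'")
  if (allow_blank_lit && op %in% c("=", "<>")) lits <- c(lits, "''")
  sprintf("[%s] %s %s", field, op, sample(lits, 1))
}

rand_bool_expr <- function(depth = 3, allow_blank_lit = TRUE,
                           allow_not = TRUE) {
  if (depth <= 0 || stats::runif(1) < 0.35) {
    return(rand_cmp_string(allow_blank_lit))
  }
  kind <- sample(if (allow_not) c("and", "or", "not") else c("and", "or"), 1)
  if (kind == "not") {
    return(sprintf("not (%s)",
                   rand_bool_expr(depth - 1, allow_blank_lit, allow_not)))
  }
  sprintf("(%s) %s (%s)",
          rand_bool_expr(depth - 1, allow_blank_lit, allow_not), kind,
          rand_bool_expr(depth - 1, allow_blank_lit, allow_not))
}

rand_context_values <- function() {
  stats::setNames(as.list(sample(c("", "0", "1", "2"), 3, replace = TRUE)),
                  c("a", "b", "c"))
}

# Random value ASTs (arithmetic + calls) for the render/parse round-trip.
rand_value_ast <- function(depth = 3) {
  af <- asNamespace("redcapqc")
  if (depth <= 0 || stats::runif(1) < 0.3) {
    pick <- sample(3, 1)
    if (pick == 1) return(af$ast_field(sample(c("a", "b", "c"), 1)))
    if (pick == 2) return(af$ast_lit("number", sample(c(0, 1, 2.5, 7), 1)))
    return(af$ast_lit("string", sample(c("x", "1", "yes"), 1)))
  }
  kind <- sample(c("bin", "neg", "call", "cmp", "bool"), 1)
  if (kind == "bin") {
    return(af$ast_binary(sample(c("+", "-", "*", "/", "^"), 1),
                         rand_value_ast(depth - 1), rand_value_ast(depth - 1)))
  }
  if (kind == "neg") return(af$ast_unary("neg", rand_value_ast(depth - 1)))
  if (kind == "call") {
    fn <- sample(c("abs", "round", "min", "max", "if"), 1)
    args <- switch(fn,
      abs = list(rand_value_ast(depth - 1)),
      round = list(rand_value_ast(depth - 1), af$ast_lit("number", 2)),
      "if" = list(rand_value_ast(depth - 1), rand_value_ast(depth - 1),
                  rand_value_ast(depth - 1)),
      list(rand_value_ast(depth - 1), rand_value_ast(depth - 1)))
    return(af$ast_call(fn, args))
  }
  if (kind == "cmp") {
    return(af$ast_binary(sample(c("=", "<>", "<", "<=", ">", ">="), 1),
                         rand_value_ast(depth - 1), rand_value_ast(depth - 1)))
  }
  af$ast_binary(sample(c("and", "or"), 1),
                rand_value_ast(depth - 1), rand_value_ast(depth - 1))
}
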