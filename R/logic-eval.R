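# Three-valued evaluator for REDCap logic ASTs.
#
# Value model (tagged scalars):
#   blank            - REDCap's empty value; absorbs arithmetic
#   number / string  - data values (raw export cells are strings)
#   bool             - tri-state truth value TRUE/FALSE/NA
#
# Blank semantics: arithmetic with a blank operand yields blank;
# comparisons with a blank operand yield the missing truth value, EXCEPT
# the syntactic forms `[x] = ''` (true iff blank) and `[x] <> ''`
# (true iff non-blank). `and`/`or`/`not` follow Kleene three-valued logic.
# `=`/`<>` compare numerically when both sides parse as numbers, else as
# exact strings. A bare checkbox reference in a truth-value position means
# `= '1'` (REDCap exports checkbox options as 0/1).

v_blank <- function() list(kind = "blank")
v_num <- function(x) {
  if (is.null(x) || is.na(x)) v_blank() else list(kind = "number", v = x)
}
v_str <- function(x) list(kind = "string", v = x)
v_bool <- function(x) list(kind = "bool", v = x)

is_blankish <- function(val) {
  val$kind == "blank" || (val$kind == "string" && !nzchar(val$v))
}

to_num <- function(val) {
  switch(val$kind,
    blank = NA_real_,
    number = val$v,
    string = suppressWarnings(as.numeric(val$v)),
    bool = if (is.na(val$v)) NA_real_ else as.numeric(val$v))
}

to_chr <- function(val) {
  switch(val$kind,
    blank = "",
    number = format(val$v, scientific = FALSE, trim = TRUE),
    string = val$v,
    bool = if (is.na(val$v)) "" else if (val$v) "1" else "0")
}

to_truth <- function(val) {
  switch(val$kind,
    bool = val$v,
    blank = NA,
    number = val$v != 0,
    string = {
      n <- suppressWarnings(as.numeric(val$v))
      if (is.na(n)) NA else n != 0
    })
}

#' Build an evaluation context for one (record, event) row
#'
#' @param row Named list or character vector: field column -> raw value for
#'   the current row (checkbox options under their `field___code` keys).
#' @param cross Named list: event name -> named value vector, for
#'   event-qualified references on the same record.
#' @param today `Date` used by the `'today'` keyword in `datediff`.
#' @param dictionary Optional `redcap_dictionary` used for
#'   validation-aware date parsing.
#' @return An environment of class `rc_eval_context`; evaluation notes
#'   (division by zero, unparseable dates) accumulate in it.
#' @export
eval_context <- function(row = list(), cross = list(), today = Sys.Date(),
                         dictionary = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$row <- as.list(row)
  ctx$cross <- cross
  ctx$today <- today
  ctx$dictionary <- dictionary
  ctx$notes <- character(0)
  class(ctx) <- "rc_eval_context"
  ctx
}

#' Evaluation notes accumulated in a context
#' @param ctx An `rc_eval_context`.
#' @return Character vector of notes.
#' @export
eval_notes <- function(ctx) ctx$notes

note <- function(ctx, msg) ctx$notes <- c(ctx$notes, msg)

lookup_field <- function(ast, ctx) {
  key <- if (is.null(ast$code)) ast$name else paste0(ast$name, "___", ast$code)
  src <- ctx$row
  if (!is.null(ast$event)) {
    src <- ctx$cross[[ast$event]] %||% list()
    src <- as.list(src)
  }
  raw <- src[[key]]
  # absent fields yield blank, never an error (REDCap blank semantics)
  if (is.null(raw) || length(raw) == 0L) return(v_blank())
  raw <- as.character(raw)[1]
  if (is.na(raw) || !nzchar(raw)) v_blank() else v_str(raw)
}

DATE_FORMATS <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d",
                  "%Y/%m/%d", "%d-%m-%Y", "%d/%m/%Y", "%m/%d/%Y")

VAL_DATE_FORMATS <- list(
  date_ymd = c("%Y-%m-%d", "%Y/%m/%d"),
  date_dmy = c("%d-%m-%Y", "%d/%m/%Y"),
  date_mdy = c("%m-%d-%Y", "%m/%d/%Y"),
  datetime = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")
)

parse_date_value <- function(val, ctx, field_node = NULL) {
  if (is_blankish(val)) return(NA_real_)
  s <- trimws2(to_chr(val))
  if (tolower(s) == "today") {
    return(as.numeric(as.POSIXct(format(ctx$today), tz = "UTC")))
  }
  fmts <- DATE_FORMATS
  # validation-aware: a field's declared date format is tried first
  if (!is.null(field_node) && field_node$node == "field" &&
      !is.null(ctx$dictionary)) {
    fd <- dic_field(ctx$dictionary, field_node$name)
    if (!is.null(fd)) {
      vt <- sub("^(datetime).*$", "\\1", fd$val_type)
      pref <- VAL_DATE_FORMATS[[vt]]
      if (!is.null(pref)) fmts <- unique(c(pref, fmts))
    }
  }
  for (f in fmts) {
    t <- as.POSIXct(s, format = f, tz = "UTC")
    if (!is.na(t) && format(t, f) == s) return(as.numeric(t))
  }
  NA_real_
}

# REDCap-style rounding: half away from zero.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

eval_compare <- function(op, lnode, rnode, lval, rval) {
  lit_blank <- function(n) n$node == "lit" && n$type == "blank"
  if (op %in% c("=", "<>") && (lit_blank(lnode) || lit_blank(rnode))) {
    other <- if (lit_blank(lnode)) rval else lval
    res <- is_blankish(other)
    return(v_bool(if (op == "=") res else !res))
  }
  if (lval$kind == "blank" || rval$kind == "blank") return(v_bool(NA))
  ln <- to_num(lval); rn <- to_num(rval)
  numeric_ok <- !is.na(ln) && !is.na(rn)
  if (op %in% c("=", "<>")) {
    eq <- if (numeric_ok) ln == rn else identical(to_chr(lval), to_chr(rval))
    return(v_bool(if (op == "=") eq else !eq))
  }
  res <- if (numeric_ok) {
    switch(op, "<" = ln < rn, "<=" = ln <= rn, ">" = ln > rn, ">=" = ln >= rn)
  } else {
    lc <- to_chr(lval); rc <- to_chr(rval)
    switch(op, "<" = lc < rc, "<=" = lc <= rc, ">" = lc > rc, ">=" = lc >= rc)
  }
  v_bool(res)
}

# Truth value of a node: bare checkbox references mean `= '1'`.
eval_truth <- function(node, ctx) {
  if (node$node == "field" && !is.null(node$code)) {
    val <- eval_node(node, ctx)
    return(to_truth(eval_compare("=", node, ast_lit("string", "1"),
                                 val, v_str("1"))))
  }
  to_truth(eval_node(node, ctx))
}

eval_node <- function(ast, ctx) {
  switch(ast$node,
    lit = switch(ast$type,
      number = v_num(ast$value),
      string = v_str(ast$value),
      blank = v_blank()),
    field = lookup_field(ast, ctx),
    smart = {
      if (ast$name == "event-name") {
        ev <- ctx$row[["redcap_event_name"]] %||% ctx$event %||% ""
        if (nzchar(ev)) v_str(as.character(ev)) else v_blank()
      } else {
        note(ctx, sprintf("unsupported smart variable [%s] evaluated as blank",
                          ast$name))
        v_blank()
      }
    },
    unary = {
      if (ast$op == "not") {
        v_bool(!eval_truth(ast$x, ctx))
      } else {  # neg
        v_num(-to_num(eval_node(ast$x, ctx)))
      }
    },
    binary = eval_binary(ast, ctx),
    call = eval_call(ast, ctx),
    stop("unknown AST node: ", ast$node)
  )
}

eval_binary <- function(ast, ctx) {
  op <- ast$op
  if (op %in% c("and", "or")) {
    l <- eval_truth(ast$left, ctx)
    r <- eval_truth(ast$right, ctx)
    return(v_bool(if (op == "and") l & r else l | r))  # Kleene via R's NA
  }
  if (op %in% c("=", "<>", "<", "<=", ">", ">=")) {
    lval <- eval_node(ast$left, ctx)
    rval <- eval_node(ast$right, ctx)
    return(eval_compare(op, ast$left, ast$right, lval, rval))
  }
  ln <- to_num(eval_node(ast$left, ctx))
  rn <- to_num(eval_node(ast$right, ctx))
  if (is.na(ln) || is.na(rn)) return(v_blank())
  if (op == "/" && rn == 0) {
    note(ctx, "division by zero")
    return(v_blank())
  }
  out <- switch(op, "+" = ln + rn, "-" = ln - rn, "*" = ln * rn,
                "/" = ln / rn, "^" = ln^rn)
  if (is.nan(out) || is.infinite(out)) {
    note(ctx, sprintf("non-finite result of '%s'", op))
    return(v_blank())
  }
  v_num(out)
}

eval_call <- function(ast, ctx) {
  fn <- ast$fn
  args <- ast$args
  if (fn == "if") {
    cond <- eval_truth(args[[1]], ctx)
    if (is.na(cond)) return(v_blank())
    return(eval_node(if (cond) args[[2]] else args[[3]], ctx))
  }
  if (fn == "datediff") return(eval_datediff(args, ctx))

  vals <- lapply(args, eval_node, ctx = ctx)
  nums <- vapply(vals, to_num, numeric(1))
  if (fn %in% c("min", "max", "sum", "mean")) {
    keep <- nums[!is.na(nums)]        # blanks are ignored, REDCap-style
    if (!length(keep)) return(v_blank())
    return(v_num(switch(fn, min = min(keep), max = max(keep),
                        sum = sum(keep), mean = mean(keep))))
  }
  x <- nums[1]
  if (is.na(x)) return(v_blank())
  if (fn == "abs") return(v_num(abs(x)))
  if (fn == "sqrt") {
    if (x < 0) { note(ctx, "sqrt of a negative number"); return(v_blank()) }
    return(v_num(sqrt(x)))
  }
  digits <- if (length(nums) >= 2 && !is.na(nums[2])) nums[2] else 0
  p <- 10^digits
  switch(fn,
    round = v_num(round_half_up(x, digits)),
    roundup = v_num(ceiling(x * p) / p),
    rounddown = v_num(floor(x * p) / p))
}

# datediff(date1, date2, units, returnSigned?) — units y/M/d/h/m/s.
# Unsigned (absolute) by default; "y" uses days/365.2425 and "M"
# days/30.44, REDCap's documented approximations. Result sign (when
# signed) is date2 - date1.
eval_datediff <- function(args, ctx) {
  d1 <- parse_date_value(eval_node(args[[1]], ctx), ctx, args[[1]])
  d2 <- parse_date_value(eval_node(args[[2]], ctx), ctx, args[[2]])
  if (is.na(d1) || is.na(d2)) {
    note(ctx, "datediff: unparseable or blank date")
    return(v_blank())
  }
  unit <- to_chr(eval_node(args[[3]], ctx))
  secs <- d2 - d1
  days <- secs / 86400
  out <- switch(unit,
    y = days / 365.2425, M = days / 30.44, d = days,
    h = secs / 3600, m = secs / 60, s = secs,
    { note(ctx, sprintf("datediff: invalid unit '%s'", unit)); return(v_blank()) })
  signed <- FALSE
  if (length(args) >= 4) {
    signed <- isTRUE(to_truth(eval_node(args[[4]], ctx))) ||
      tolower(to_chr(eval_node(args[[4]], ctx))) == "true"
  }
  v_num(if (signed) out else abs(out))
}

#' Evaluate a REDCap logic expression
#'
#' @param ast An AST from [parse_logic()], or an expression string.
#' @param ctx An [eval_context()].
#' @return A scalar: numeric or character for value expressions, a
#'   tri-state logical (`TRUE`/`FALSE`/`NA`) for truth expressions, `NA`
#'   for a blank result. Division by zero and unparseable dates yield
#'   blank and record a note in the context; they never crash.
#' @export
eval_logic <- function(ast, ctx = eval_context()) {
  if (is.character(ast)) ast <- parse_logic(ast)
  val <- eval_node(ast, ctx)
  switch(val$kind,
    blank = NA,
    number = val$v,
    string = val$v,
    bool = val$v)
}

# Tri-state truth of an expression for one row (checkbox truthiness applies).
eval_logic_truth <- function(ast, ctx = eval_context()) {
  if (is.character(ast)) ast <- parse_logic(ast)
  eval_truth(ast, ctx)
}
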