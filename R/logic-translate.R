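# Translation of REDCap logic into the target (R-flavoured) convention,
# with detection of untranslatable smart variables.

# Mapping from checkbox export columns (field___code) to their
# post-transform option-named columns. Shared by the translator and the
# checkbox transformation step so both agree on names. New names are
# sanitized option labels, uniquified with numeric suffixes against both
# existing field names and one another.
checkbox_name_map <- function(dictionary) {
  taken <- dictionary$field_name[dictionary$field_type != "checkbox"]
  map <- character(0)
  for (i in which(dictionary$field_type == "checkbox")) {
    field <- dictionary$field_name[i]
    choices <- dictionary$choice_map[[i]]
    for (k in seq_along(choices)) {
      base <- sanitize_name(choices[[k]])
      name <- base
      suffix <- 2L
      while (name %in% c(taken, map)) {
        name <- paste0(base, "_", suffix)
        suffix <- suffix + 1L
      }
      map[[paste0(field, "___", names(choices)[k])]] <- name
      taken <- c(taken, name)
    }
  }
  map
}

SUPPORTED_SMART_VARS <- "event-name"

collect_smart_vars <- function(ast) {
  found <- character(0)
  walk <- function(n) {
    switch(n$node,
      smart = if (!(n$name %in% SUPPORTED_SMART_VARS)) found <<- c(found, n$name),
      field = if (!is.null(n$event) && grepl("-", n$event, fixed = TRUE) &&
                  !(n$event %in% SUPPORTED_SMART_VARS)) {
        found <<- c(found, n$event)
      },
      unary = walk(n$x),
      binary = { walk(n$left); walk(n$right) },
      call = for (a in n$args) walk(a),
      NULL)
  }
  walk(ast)
  unique(found)
}

# Rewrite checkbox references to their post-transform option columns.
rewrite_checkboxes <- function(ast, cb_map) {
  walk <- function(n) {
    switch(n$node,
      field = {
        if (!is.null(n$code)) {
          key <- paste0(n$name, "___", n$code)
          if (key %in% names(cb_map)) {
            return(ast_field(cb_map[[key]], event = n$event))
          }
        }
        n
      },
      unary = { n$x <- walk(n$x); n },
      binary = { n$left <- walk(n$left); n$right <- walk(n$right); n },
      call = { n$args <- lapply(n$args, walk); n },
      n)
  }
  walk(ast)
}

# Render an AST in the target (R) convention for the updated dictionary.
render_r_logic <- function(ast) {
  wrap <- function(node) {
    s <- render_r_logic(node)
    if (node$node %in% c("binary", "unary")) paste0("(", s, ")") else s
  }
  switch(ast$node,
    field = {
      ref <- if (is.null(ast$code)) ast$name
             else paste0(ast$name, "___", ast$code)
      if (is.null(ast$event)) ref else paste0(ast$event, "$", ref)
    },
    smart = if (ast$name == "event-name") "redcap_event_name"
            else paste0("`", ast$name, "`"),
    lit = switch(ast$type,
      number = format(ast$value, scientific = FALSE, trim = TRUE),
      string = paste0("'", ast$value, "'"),
      blank = "''"),
    unary = if (ast$op == "not") paste0("!", wrap(ast$x))
            else paste0("-", wrap(ast$x)),
    binary = {
      op <- switch(ast$op, "=" = "==", "<>" = "!=", "and" = "&",
                   "or" = "|", ast$op)
      paste(wrap(ast$left), op, wrap(ast$right))
    },
    call = paste0(if (ast$fn == "if") "ifelse" else ast$fn, "(",
                  paste(vapply(ast$args, render_r_logic, character(1)),
                        collapse = ", "), ")"),
    stop("unknown AST node: ", ast$node)
  )
}

#' Translate a REDCap logic expression
#'
#' Parses the expression, reports any smart variables the engine cannot
#' resolve (everything except `[event-name]`), rewrites checkbox
#' references to the option-named columns used after the checkbox
#' transformation, and renders the result in the target convention for
#' the updated dictionary.
#'
#' @param source Raw expression string from the dictionary.
#' @param dictionary Optional `redcap_dictionary` used to resolve checkbox
#'   option names.
#' @return A list of class `logic_translation`: `source`, `ast` (or
#'   `NULL` on parse failure), `translatable`, `offending_smart_vars`,
#'   `warning` (empty string when clean), `translated_ast`, `rendered`.
#' @export
translate_logic <- function(source, dictionary = NULL) {
  res <- list(source = source, ast = NULL, translatable = FALSE,
              offending_smart_vars = character(0), warning = "",
              translated_ast = NULL, rendered = "")
  class(res) <- "logic_translation"
  ast <- tryCatch(parse_logic(source), rcqc_parse_error = function(e) e)
  if (inherits(ast, "condition")) {
    res$warning <- paste("parse error:", conditionMessage(ast))
    return(res)
  }
  res$ast <- ast
  offending <- collect_smart_vars(ast)
  if (length(offending)) {
    res$offending_smart_vars <- offending
    res$warning <- paste("cannot translate smart variable(s):",
                         paste0("[", offending, "]", collapse = ", "))
    return(res)
  }
  res$translatable <- TRUE
  cb_map <- if (!is.null(dictionary)) checkbox_name_map(dictionary)
            else character(0)
  res$translated_ast <- rewrite_checkboxes(ast, cb_map)
  res$rendered <- render_r_logic(res$translated_ast)
  res
}

#' @export
print.logic_translation <- function(x, ...) {
  cat("Logic translation\n  source: ", x$source, "\n", sep = "")
  if (x$translatable) {
    cat("  rendered: ", x$rendered, "\n", sep = "")
  } else {
    cat("  NOT translatable: ", x$warning, "\n", sep = "")
  }
  invisible(x)
}
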