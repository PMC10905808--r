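# Discrepancy query generation, missing-event detection, summaries and
# longitudinal report diffing.
#
# A query row carries the printable Table-style columns (identifier, DAG,
# event, instrument, field, description, query text, code) plus two
# internal columns: `rule` — a value-free restatement of the rule in
# should-form, used as part of the diff match key — and `snapshot_value`,
# the offending raw value at generation time, used to tell a miscorrected
# query (value changed, rule still violated) from a pending one.

MISSING_QUERY_TEXT <- "The value is NA and it should not be missing"
MISSING_RULE_TEXT <- "The value should not be missing"
MISSING_EVENT_TEXT <- "The event is missing"

new_query_report <- function(queries) {
  structure(list(queries = queries, summary = summarize_queries(queries)),
            class = "rc_query_report")
}

empty_queries <- function() {
  data.frame(identifier = character(0), dag = character(0),
             event = character(0), instrument = character(0),
             field = character(0), description = character(0),
             query = character(0), code = character(0),
             rule = character(0), snapshot_value = character(0),
             stringsAsFactors = FALSE)
}

# When one expression is broadcast over several variables, a rule that
# references a single field follows the variable: "[copd] <> ''" applied
# to age becomes "[age] <> ''".
broadcast_expression <- function(expr, var) {
  ast <- parse_logic(expr)
  fields <- character(0)
  walk <- function(n) {
    switch(n$node,
      field = fields <<- c(fields, n$name),
      unary = walk(n$x),
      binary = { walk(n$left); walk(n$right) },
      call = for (a in n$args) walk(a),
      NULL)
  }
  walk(ast)
  fields <- unique(fields)
  if (length(fields) != 1L || fields == var) return(expr)
  expr <- gsub(paste0("[", fields, "]"), paste0("[", var, "]"), expr,
               fixed = TRUE)
  gsub(paste0("[", fields, "("), paste0("[", var, "("), expr, fixed = TRUE)
}

# Is this AST the canonical missingness rule `[var] <> ''` ?
is_missingness_rule <- function(ast) {
  ast$node == "binary" && ast$op == "<>" &&
    ast$left$node == "field" &&
    ast$right$node == "lit" && ast$right$type == "blank"
}

# Recover the value-free rule text from a printed query (used when a
# report is re-read from CSV and the internal column is gone).
rule_from_query_text <- function(query) {
  out <- sub("^The value is .* and it should be ",
             "The value should be ", query)
  out[query == MISSING_QUERY_TEXT] <- MISSING_RULE_TEXT
  out
}

# Sort queries in report order (natural identifier, event order, field
# order) and assign codes "<identifier>-<ordinal>", ordinals consecutive
# per identifier.
finalize_report <- function(queries, event_order = NULL, field_order = NULL) {
  if (!nrow(queries)) return(new_query_report(empty_queries()))
  ev_rank <- if (!is.null(event_order)) {
    match(queries$event_raw, event_order)
  } else rep(0L, nrow(queries))
  fd_rank <- if (!is.null(field_order)) {
    match(queries$field, c(field_order, ""))
  } else rep(0L, nrow(queries))
  ord <- order(natural_sortkey(queries$identifier), ev_rank, fd_rank)
  queries <- queries[ord, , drop = FALSE]
  queries$code <- stats::ave(queries$identifier, queries$identifier,
                             FUN = function(v) paste0(v, "-", seq_along(v)))
  queries$event_raw <- NULL
  rownames(queries) <- NULL
  new_query_report(queries)
}

# Resolve the records/dictionary/event_map triplet from either a raw
# project bundle or a transform result.
query_source <- function(x) {
  if (inherits(x, "redcap_project")) {
    list(records = x$records, dictionary = x$dictionary,
         event_map = x$event_map, id_field = x$id_field)
  } else if (inherits(x, "rc_transform")) {
    if (inherits(x$data, "rc_split")) {
      validation_error("query generation needs an unsplit record table (final_format = \"raw\")")
    }
    list(records = x$data, dictionary = x$dictionary,
         event_map = x$event_map, id_field = x$id_field)
  } else {
    validation_error("expected a redcap_project or rc_transform object")
  }
}

row_dag <- function(records, i) {
  if (!("redcap_data_access_group" %in% names(records))) return("")
  raw <- as.character(records$redcap_data_access_group[i])
  if (is.na(raw) || !nzchar(raw)) "" else prettify_label(raw)
}

row_event <- function(records, i) {
  if (!("redcap_event_name" %in% names(records))) return(c("", ""))
  raw <- as.character(records$redcap_event_name[i])
  if (is.na(raw)) raw <- ""
  c(raw, prettify_label(raw, strip_arm = TRUE))
}

#' Generate discrepancy queries from rule expressions
#'
#' Each expression states the VALID condition for its variable in REDCap
#' logic syntax (e.g. `"[age] >= 18 and [age] <= 100"`, or the
#' missingness rule `"[copd] <> ''"`); a query is raised for every
#' (record, event) row where the rule evaluates to false or missing.
#' `negate = TRUE` inverts the direction (the expression states the
#' invalid condition). With an event-form mapping present, each
#' variable is checked only on the events that collect its form — there
#' is no need to list events by hand.
#'
#' @param x A `redcap_project` or `rc_transform`.
#' @param variables Character vector of field names to check.
#' @param expressions One expression (recycled to every variable) or one
#'   per variable.
#' @param query_text Optional fixed query text overriding the default
#'   ("The value is NA and it should not be missing" for missingness
#'   rules, "The value is <value> and it should be <expression>"
#'   otherwise).
#' @param negate Flag rows where the expression is TRUE instead.
#' @return An `rc_query_report` with `queries` and `summary`.
#' @export
rc_query <- function(x, variables, expressions, query_text = NULL,
                     negate = FALSE) {
  src <- query_source(x)
  records <- src$records
  dictionary <- src$dictionary
  if (!length(variables)) validation_error("no variables given")
  if (!(length(expressions) %in% c(1L, length(variables)))) {
    validation_error(sprintf(
      "expressions must have length 1 or %d (one per variable), got %d",
      length(variables), length(expressions)))
  }
  broadcast <- length(expressions) == 1L && length(variables) > 1L
  expressions <- rep_len(expressions, length(variables))
  if (broadcast) {
    expressions <- vapply(seq_along(variables), function(i) {
      broadcast_expression(expressions[i], variables[i])
    }, character(1))
  }

  unknown <- setdiff(variables, names(records))
  if (length(unknown)) {
    validation_error(paste("unknown variable(s):",
                           paste(unknown, collapse = ", ")))
  }

  rows_list <- list()
  for (vi in seq_along(variables)) {
    var <- variables[vi]
    ast <- parse_logic(expressions[vi])
    fd <- dic_field(dictionary, var)
    form <- if (!is.null(fd)) fd$form_name else NA_character_
    rows <- seq_len(nrow(records))
    if (!is.null(src$event_map) && !is.na(form)) {
      evs <- events_for_form(src$event_map, form)
      if (!length(evs)) {
        validation_error(sprintf(
          "variable '%s' (form '%s') is collected in no event of the event-form mapping",
          var, form))
      }
      if ("redcap_event_name" %in% names(records)) {
        rows <- rows[as.character(records$redcap_event_name[rows]) %in% evs]
      }
    }

    missing_rule <- is_missingness_rule(ast) && !negate
    for (i in rows) {
      ctx <- eval_context(row = row_values(records, i),
                          dictionary = dictionary)
      truth <- eval_logic_truth(ast, ctx)
      flagged <- if (negate) isTRUE(truth) else !isTRUE(truth)
      if (!flagged) next
      raw_val <- as.character(records[[var]][i])
      if (is.na(raw_val)) raw_val <- ""
      ev <- row_event(records, i)
      qt <- if (!is.null(query_text)) {
        query_text
      } else if (missing_rule) {
        MISSING_QUERY_TEXT
      } else {
        sprintf("The value is %s and it should be %s",
                if (nzchar(raw_val)) raw_val else "NA", expressions[vi])
      }
      rule <- if (!is.null(query_text)) {
        query_text
      } else if (missing_rule) {
        MISSING_RULE_TEXT
      } else {
        paste("The value should be", expressions[vi])
      }
      rows_list[[length(rows_list) + 1L]] <- data.frame(
        identifier = as.character(records[[src$id_field]][i]),
        dag = row_dag(records, i),
        event = ev[2], event_raw = ev[1],
        instrument = if (!is.na(form)) prettify_label(form) else "",
        field = var,
        description = if (!is.null(fd)) fd$field_label else "",
        query = qt, code = "", rule = rule, snapshot_value = raw_val,
        stringsAsFactors = FALSE)
    }
  }

  queries <- if (length(rows_list)) do.call(rbind, rows_list)
             else cbind(empty_queries(), event_raw = character(0))
  finalize_report(queries,
                  event_order = if (!is.null(src$event_map))
                    unique(src$event_map$unique_event_name),
                  field_order = dictionary$field_name)
}

#' Detect missing events
#'
#' REDCap does not export rows for events with no collected data; this
#' builds the expected record-by-event grid from the event-form mapping
#' and raises one query per (record, expected event) pair absent from the
#' data, with query text "The event is missing".
#'
#' @param x A `redcap_project` or `rc_transform` with an event map.
#' @param events Events to check (default: all mapped events).
#' @return An `rc_query_report`; field/description/instrument columns are
#'   empty for event-level queries.
#' @export
rc_event <- function(x, events = NULL) {
  src <- query_source(x)
  if (is.null(src$event_map)) {
    validation_error("missing-event detection requires an event-form mapping")
  }
  all_events <- unique(src$event_map$unique_event_name)
  if (is.null(events)) events <- all_events
  unknown <- setdiff(events, all_events)
  if (length(unknown)) {
    validation_error(paste("unknown event(s):", paste(unknown, collapse = ", ")))
  }
  records <- src$records
  if (!("redcap_event_name" %in% names(records))) {
    validation_error("records have no redcap_event_name column")
  }
  ids <- unique(as.character(records[[src$id_field]]))
  observed <- paste(as.character(records[[src$id_field]]),
                    as.character(records$redcap_event_name), sep = "\r")
  dag_of <- vapply(ids, function(id) {
    i <- which(records[[src$id_field]] == id)[1]
    row_dag(records, i)
  }, character(1))

  rows_list <- list()
  for (id in ids) {
    for (ev in events) {
      if (paste(id, ev, sep = "\r") %in% observed) next
      rows_list[[length(rows_list) + 1L]] <- data.frame(
        identifier = id, dag = dag_of[[id]],
        event = prettify_label(ev, strip_arm = TRUE), event_raw = ev,
        instrument = "", field = "", description = "",
        query = MISSING_EVENT_TEXT, code = "",
        rule = MISSING_EVENT_TEXT, snapshot_value = "",
        stringsAsFactors = FALSE)
    }
  }
  queries <- if (length(rows_list)) do.call(rbind, rows_list)
             else cbind(empty_queries(), event_raw = character(0))
  finalize_report(queries, event_order = all_events)
}

#' Summarize a set of queries
#'
#' Groups queries by (variable, event, rule) and counts them, descending
#' by total; the rule is restated in should-form (e.g. "The value should
#' not be missing").
#'
#' @param queries An `rc_query_report` or its `queries` data.frame.
#' @return A data.frame with columns `variable`, `description`, `event`,
#'   `query`, `total`.
#' @export
summarize_queries <- function(queries) {
  if (inherits(queries, "rc_query_report")) queries <- queries$queries
  if (!nrow(queries)) {
    return(data.frame(variable = character(0), description = character(0),
                      event = character(0), query = character(0),
                      total = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(queries$field, queries$event, queries$rule, sep = "\r")
  agg <- lapply(split(seq_len(nrow(queries)), key), function(idx) {
    data.frame(variable = queries$field[idx[1]],
               description = queries$description[idx[1]],
               event = queries$event[idx[1]],
               query = queries$rule[idx[1]],
               total = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$total, natural_sortkey(out$variable)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.rc_query_report <- function(x, ...) {
  cat(sprintf("Query report: %d queries\n", nrow(x$queries)))
  if (nrow(x$summary)) {
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}

diff_key <- function(queries) {
  paste(queries$identifier, queries$event, queries$field, queries$rule,
        sep = "\r")
}

#' Compare two query reports
#'
#' Matches queries across an old and a new report on
#' (identifier, event, field, rule) and classifies each:
#' `Pending` (in both, offending value unchanged), `Miscorrected` (in
#' both, value changed but the rule is still violated), `New` (only in
#' the new report), `Solved` (only in the old one). Codes come from the
#' new report where present, else from the old.
#'
#' @param old,new `rc_query_report` objects (or ones re-read from CSV;
#'   re-read reports have no stored snapshot values, and such pairs are
#'   classified Pending rather than Miscorrected).
#' @return An `rc_query_diff`: `merged` (queries + `modification`) and
#'   `summary` (counts per category).
#' @export
rc_check <- function(old, new) {
  oq <- if (inherits(old, "rc_query_report")) old$queries else old
  nq <- if (inherits(new, "rc_query_report")) new$queries else new
  ok <- diff_key(oq)
  nk <- diff_key(nq)
  if (anyDuplicated(ok) || anyDuplicated(nk)) {
    validation_error("duplicate (identifier, event, field, rule) keys within one report")
  }

  categ <- function(key, in_old, in_new) {
    if (in_old && in_new) {
      ov <- oq$snapshot_value[match(key, ok)]
      nv <- nq$snapshot_value[match(key, nk)]
      if (!is.na(ov) && !is.na(nv) && !identical(ov, nv)) "Miscorrected"
      else "Pending"
    } else if (in_new) "New" else "Solved"
  }

  all_keys <- unique(c(nk, ok))
  pieces <- lapply(all_keys, function(key) {
    in_old <- key %in% ok
    in_new <- key %in% nk
    base <- if (in_new) nq[match(key, nk), , drop = FALSE]
            else oq[match(key, ok), , drop = FALSE]
    base$modification <- categ(key, in_old, in_new)
    base
  })
  merged <- if (length(pieces)) do.call(rbind, pieces) else {
    m <- empty_queries(); m$modification <- character(0); m
  }
  if (nrow(merged)) {
    merged <- merged[natural_order(merged$identifier), , drop = FALSE]
    rownames(merged) <- NULL
  }
  cats <- c("New", "Pending", "Miscorrected", "Solved")
  summary <- data.frame(modification = cats,
                        total = vapply(cats, function(cat) {
                          sum(merged$modification == cat)
                        }, integer(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(merged = merged, summary = summary),
            class = "rc_query_diff")
}

#' @export
print.rc_query_diff <- function(x, ...) {
  cat(sprintf("Query report comparison: %d queries\n", nrow(x$merged)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
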