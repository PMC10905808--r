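# Recalculation of auto-calculated fields and comparison with the values
# stored by the REDCap server.

# Does an AST contain event-qualified field references?
uses_cross_event <- function(ast) {
  found <- FALSE
  walk <- function(n) {
    switch(n$node,
      field = if (!is.null(n$event)) found <<- TRUE,
      unary = walk(n$x),
      binary = { walk(n$left); walk(n$right) },
      call = for (a in n$args) walk(a),
      NULL)
  }
  walk(ast)
  found
}

row_values <- function(records, i) {
  vals <- lapply(records[i, , drop = FALSE], function(col) {
    v <- col[[1]]
    if (is.factor(v)) v <- as.character(v)
    as.character(v)
  })
  vals
}

# Compare a recalculated scalar with the stored raw string.
# Numeric comparison uses |recalc - stored| <= 1e-6 after rounding the
# recalculated value to the stored value's printed decimal places
# (REDCap rounds displayed calc results). Blank vs blank matches.
compare_calc <- function(stored, recalc) {
  stored_blank <- is.na(stored) || !nzchar(stored)
  recalc_blank <- length(recalc) != 1L || is.na(recalc)
  if (stored_blank && recalc_blank) return(TRUE)
  if (stored_blank || recalc_blank) return(FALSE)
  stored_num <- suppressWarnings(as.numeric(stored))
  recalc_num <- suppressWarnings(as.numeric(recalc))
  if (!is.na(stored_num) && !is.na(recalc_num)) {
    dec <- if (grepl(".", stored, fixed = TRUE)) {
      nchar(sub("^[^.]*\\.", "", stored))
    } else 0L
    return(abs(round_half_up(recalc_num, dec) - stored_num) <= 1e-6)
  }
  identical(as.character(recalc), stored)
}

#' Recalculate calculated fields and flag discrepancies
#'
#' Re-evaluates every `calc` field's expression on each applicable row and
#' compares the result with the value stored in the export. Fields whose
#' calculation cannot be translated (unsupported smart variables, parse
#' errors) are skipped and reported. When an event-form mapping is
#' supplied, each field is recalculated only on rows of events that
#' include the field's form.
#'
#' @param records Record table (data.frame of raw values).
#' @param dictionary A `redcap_dictionary`.
#' @param event_map Optional `redcap_event_map`.
#' @param fields Calc field names to process (default: all calc fields).
#' @param today `Date` for `'today'` in expressions.
#' @return A list of class `rc_recalc`: `fields` (per-field results with
#'   `values`, `match`, `n_match`, `n_mismatch`, `status`), `skipped`
#'   (per-field translation warnings) and a `summary` data.frame with
#'   `field`, `status` ("identical"/"not identical"), `n_match`,
#'   `n_mismatch`.
#' @export
recalc_fields <- function(records, dictionary, event_map = NULL,
                          fields = NULL, today = Sys.Date()) {
  calc_fields <- dictionary$field_name[dictionary$field_type == "calc"]
  if (!is.null(fields)) {
    unknown <- setdiff(fields, calc_fields)
    if (length(unknown)) {
      validation_error(paste("Not calc fields:", paste(unknown, collapse = ", ")))
    }
    calc_fields <- fields
  }
  id_field <- dictionary$field_name[1]
  out <- list(fields = list(), skipped = list())

  for (field in calc_fields) {
    fd <- dic_field(dictionary, field)
    tr <- translate_logic(fd$calculation, dictionary)
    if (!tr$translatable) {
      out$skipped[[field]] <- tr$warning
      next
    }
    rows <- seq_len(nrow(records))
    if (!is.null(event_map) && "redcap_event_name" %in% names(records)) {
      evs <- events_for_form(event_map, fd$form_name)
      rows <- rows[records$redcap_event_name[rows] %in% evs]
    }
    needs_cross <- uses_cross_event(tr$ast)
    values <- rep(NA_real_, length(rows))
    match_flag <- logical(length(rows))
    notes <- character(0)
    for (j in seq_along(rows)) {
      i <- rows[j]
      cross <- list()
      if (needs_cross && "redcap_event_name" %in% names(records)) {
        same <- which(records[[id_field]] == records[[id_field]][i])
        cross <- stats::setNames(
          lapply(same, function(k) row_values(records, k)),
          records$redcap_event_name[same])
      }
      ctx <- eval_context(row = row_values(records, i), cross = cross,
                          today = today, dictionary = dictionary)
      recalc <- eval_logic(tr$ast, ctx)
      if (length(eval_notes(ctx))) notes <- c(notes, eval_notes(ctx))
      values[j] <- suppressWarnings(as.numeric(recalc)[1])
      if (is.character(recalc)) values[j] <- NA_real_
      stored <- as.character(records[[field]][i])
      match_flag[j] <- compare_calc(stored, recalc)
    }
    n_mismatch <- sum(!match_flag)
    out$fields[[field]] <- list(
      rows = rows, values = values, match = match_flag,
      n_match = sum(match_flag), n_mismatch = n_mismatch,
      status = if (n_mismatch == 0L) "identical" else "not identical",
      notes = unique(notes))
  }

  out$summary <- data.frame(
    field = names(out$fields),
    status = vapply(out$fields, `[[`, character(1), "status"),
    n_match = vapply(out$fields, `[[`, integer(1), "n_match"),
    n_mismatch = vapply(out$fields, `[[`, integer(1), "n_mismatch"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- "rc_recalc"
  out
}

#' @export
print.rc_recalc <- function(x, ...) {
  cat("Calculated-field recalculation\n")
  if (nrow(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf("  %s: %s (%d match, %d mismatch)\n",
                  x$summary$field[i], x$summary$status[i],
                  x$summary$n_match[i], x$summary$n_mismatch[i]))
    }
  } else cat("  no calculated fields\n")
  for (f in names(x$skipped)) {
    cat(sprintf("  %s: skipped - %s\n", f, x$skipped[[f]]))
  }
  invisible(x)
}
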