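# The default five-step transformation pipeline:
#   1. recalculate calc fields and report discrepancies
#   2. checkbox transformation (option-named columns, No/Yes labels,
#      branching-driven missing values)
#   3. factor substitution (codes -> labels)
#   4. branching-logic translation into the updated dictionary
#   5. pattern-based column deletion
# plus the optional split of the result by event or by form.

#' Checkbox transformation
#'
#' Renames each `field___code` column to a sanitized form of its option
#' label, relabels values 0/1 as No/Yes, and handles missing values: when
#' the parent field has a branching logic and that logic evaluates to
#' missing on a row, every option column of the field becomes missing on
#' that row (policy `branching_missing_only`); the stricter
#' `branching_missing_or_false` also blanks rows where the logic is false.
#' Checkbox fields with no branching logic are listed in the warnings so
#' they can be reviewed.
#'
#' @param records Record table.
#' @param dictionary A `redcap_dictionary`.
#' @param checkbox_labels Length-2 labels for unchecked/checked
#'   (default `c("No", "Yes")`).
#' @param na_policy `"branching_missing_only"` or
#'   `"branching_missing_or_false"`.
#' @return A list: `records`, `dictionary` (checkbox fields expanded to
#'   one No/Yes field per option), `warnings`.
#' @export
transform_checkboxes <- function(records, dictionary,
                                 checkbox_labels = c("No", "Yes"),
                                 na_policy = c("branching_missing_only",
                                               "branching_missing_or_false")) {
  na_policy <- match.arg(na_policy)
  if (length(checkbox_labels) != 2L) {
    config_error("checkbox_labels must have exactly two values")
  }
  cb_map <- checkbox_name_map(dictionary)
  warnings <- character(0)
  cb_idx <- which(dictionary$field_type == "checkbox")

  for (i in cb_idx) {
    field <- dictionary$field_name[i]
    choices <- dictionary$choice_map[[i]]
    cols <- paste0(field, "___", names(choices))
    cols <- cols[cols %in% names(records)]
    if (!length(cols)) next

    branching <- trimws2(dictionary$branching_logic[i])
    drop_rows <- logical(nrow(records))
    if (nzchar(branching)) {
      tr <- translate_logic(branching, dictionary)
      if (!tr$translatable) {
        warnings <- c(warnings, sprintf(
          "checkbox '%s': branching logic not translatable (%s); missing values not handled",
          field, tr$warning))
      } else {
        for (r in seq_len(nrow(records))) {
          ctx <- eval_context(row = row_values(records, r),
                              dictionary = dictionary)
          truth <- eval_logic_truth(tr$ast, ctx)
          drop_rows[r] <- is.na(truth) ||
            (na_policy == "branching_missing_or_false" && !truth)
        }
      }
    } else {
      warnings <- c(warnings, sprintf(
        "checkbox '%s' has no branching logic; check whether its zeros should be missing",
        field))
    }

    for (col in cols) {
      v <- as.character(records[[col]])
      out <- v
      out[v == "0"] <- checkbox_labels[1]
      out[v == "1"] <- checkbox_labels[2]
      out[drop_rows | is_blank(v)] <- NA_character_
      # factor here marks the column as already transformed, so the later
      # factor-substitution step leaves it untouched
      records[[col]] <- factor(out, levels = unique(c(checkbox_labels,
                                                      stats::na.omit(out))))
    }
    names(records)[match(cols, names(records))] <- unname(cb_map[cols])
  }

  # Expand checkbox dictionary rows: one No/Yes field per option.
  if (length(cb_idx)) {
    pieces <- list()
    for (i in seq_len(nrow(dictionary))) {
      if (dictionary$field_type[i] != "checkbox") {
        pieces[[length(pieces) + 1L]] <- dictionary[i, , drop = FALSE]
        next
      }
      field <- dictionary$field_name[i]
      choices <- dictionary$choice_map[[i]]
      for (k in seq_along(choices)) {
        row <- dictionary[i, , drop = FALSE]
        row$field_name <- cb_map[[paste0(field, "___", names(choices)[k])]]
        row$field_type <- "radio"
        row$field_label <- paste0(dictionary$field_label[i], ": ", choices[[k]])
        row$choices <- paste0("0, ", checkbox_labels[1], " | 1, ",
                              checkbox_labels[2])
        row$choice_map <- list(stats::setNames(checkbox_labels, c("0", "1")))
        pieces[[length(pieces) + 1L]] <- row
      }
    }
    dictionary <- do.call(rbind, pieces)
    rownames(dictionary) <- NULL
    class(dictionary) <- c("redcap_dictionary", "data.frame")
  }

  list(records = records, dictionary = dictionary, warnings = warnings)
}

#' Factor substitution
#'
#' Replaces raw category codes with their labels for radio, dropdown,
#' yesno and truefalse fields, keeping the dictionary's choice order as
#' the factor level order. `redcap_event_name` and
#' `redcap_data_access_group` retain the raw version and gain a labelled
#' companion column (`*_label`). Raw codes absent from the choices are
#' kept verbatim and reported in the `factor_warnings` attribute.
#'
#' @param records Record table.
#' @param dictionary A `redcap_dictionary`.
#' @param event_map Optional `redcap_event_map` (orders event labels).
#' @return The transformed record table, with attribute `factor_warnings`.
#' @export
apply_factors <- function(records, dictionary, event_map = NULL) {
  warnings <- character(0)
  targets <- which(dictionary$field_type %in%
                     c("radio", "dropdown", "yesno", "truefalse"))
  for (i in targets) {
    field <- dictionary$field_name[i]
    if (!(field %in% names(records))) next
    if (is.factor(records[[field]])) next  # already transformed (checkboxes)
    choices <- switch(dictionary$field_type[i],
      yesno = c("1" = "Yes", "0" = "No"),
      truefalse = c("1" = "True", "0" = "False"),
      dictionary$choice_map[[i]])
    v <- as.character(records[[field]])
    nonblank <- v[!is_blank(v)]
    if (!length(nonblank)) next
    if (!any(nonblank %in% names(choices)) && any(nonblank %in% choices)) {
      validation_error(sprintf(
        "Field '%s' already carries labels, not raw codes; factor substitution refused",
        field))
    }
    unknown <- setdiff(unique(nonblank), names(choices))
    if (length(unknown)) {
      warnings <- c(warnings, sprintf(
        "field '%s': value(s) %s not in choices; kept verbatim",
        field, paste(sQuote(unknown, q = FALSE), collapse = ", ")))
    }
    mapped <- ifelse(is_blank(v), NA_character_,
                     ifelse(v %in% names(choices), unname(choices[v]), v))
    levels <- c(unname(choices), unknown)
    records[[field]] <- factor(mapped, levels = levels)
  }

  if ("redcap_event_name" %in% names(records)) {
    raw <- records$redcap_event_name
    lv <- if (!is.null(event_map)) unique(event_map$unique_event_name)
          else unique(raw)
    records$redcap_event_name_label <-
      factor(prettify_label(raw, strip_arm = TRUE),
             levels = unique(prettify_label(lv, strip_arm = TRUE)))
  }
  if ("redcap_data_access_group" %in% names(records)) {
    raw <- records$redcap_data_access_group
    records$redcap_data_access_group_label <-
      ifelse(is_blank(raw), NA_character_, prettify_label(raw))
  }
  attr(records, "factor_warnings") <- warnings
  records
}

#' Delete columns matching name patterns
#'
#' Removes every column whose name ends with one of the patterns
#' (default suffix matching; `mode = "substring"` matches anywhere, the
#' literal REDCap-style reading).
#'
#' @param records Record table.
#' @param patterns Non-empty character vector of patterns.
#' @param mode `"suffix"` or `"substring"`.
#' @return The record table without the matching columns; the removed
#'   names are in attribute `deleted_vars`.
#' @export
delete_pattern_vars <- function(records, patterns = c("_complete", "_timestamp"),
                                mode = c("suffix", "substring")) {
  mode <- match.arg(mode)
  if (!length(patterns) || any(!nzchar(patterns))) {
    config_error("delete patterns must be a non-empty list of non-empty strings")
  }
  hit <- rep(FALSE, ncol(records))
  for (p in patterns) {
    hit <- hit | if (mode == "suffix") endsWith(names(records), p)
                 else grepl(p, names(records), fixed = TRUE)
  }
  out <- records[, !hit, drop = FALSE]
  attr(out, "deleted_vars") <- names(records)[hit]
  out
}

# Map each record column to the form it belongs to (NA for reserved and
# label companion columns).
column_forms <- function(columns, dictionary, id_field) {
  forms <- unique(dictionary$form_name)
  vapply(columns, function(col) {
    if (col %in% c(id_field, RESERVED_COLUMNS,
                   paste0(RESERVED_COLUMNS, "_label"))) return(NA_character_)
    i <- match(col, dictionary$field_name)
    if (!is.na(i)) return(dictionary$form_name[i])
    if (grepl("___", col, fixed = TRUE)) {
      parent <- sub("___.*$", "", col)
      i <- match(parent, dictionary$field_name)
      if (!is.na(i)) return(dictionary$form_name[i])
    }
    for (f in forms) {
      if (col == paste0(f, "_complete") || col == paste0(f, "_timestamp")) {
        return(f)
      }
    }
    NA_character_
  }, character(1))
}

#' Split a record table by event or by form
#'
#' `by = "event"` groups rows by event; each group keeps the reserved
#' columns plus the columns of forms mapped to that event. `by = "form"`
#' makes one group per form, keeping rows that carry at least one
#' non-missing value in that form's own columns.
#'
#' @param records Record table.
#' @param by `"event"` or `"form"`.
#' @param dictionary A `redcap_dictionary`.
#' @param event_map Required `redcap_event_map` when `by = "event"`.
#' @return An `rc_split`: list of groups `list(key, vars, data)`.
#' @export
split_records <- function(records, by = c("event", "form"), dictionary,
                          event_map = NULL) {
  by <- match.arg(by)
  id_field <- dictionary$field_name[1]
  col_form <- column_forms(names(records), dictionary, id_field)
  reserved <- names(records)[is.na(col_form)]

  groups <- list()
  if (by == "event") {
    if (is.null(event_map)) {
      config_error("splitting by event requires an event-form mapping")
    }
    if (!("redcap_event_name" %in% names(records))) {
      validation_error("records have no redcap_event_name column")
    }
    bad <- setdiff(unique(records$redcap_event_name),
                   c(event_map$unique_event_name, ""))
    if (length(bad)) {
      validation_error(paste("events absent from the event-form mapping:",
                             paste(bad, collapse = ", ")))
    }
    for (ev in unique(event_map$unique_event_name)) {
      forms <- forms_for_event(event_map, ev)
      vars <- names(records)[is.na(col_form) | col_form %in% forms]
      rows <- records$redcap_event_name == ev
      groups[[length(groups) + 1L]] <- list(
        key = ev, vars = vars,
        data = records[rows, vars, drop = FALSE])
    }
  } else {
    for (f in unique(dictionary$form_name)) {
      own <- names(records)[!is.na(col_form) & col_form == f]
      vars <- c(reserved, own)
      value_cols <- setdiff(own, c(paste0(f, "_complete"),
                                   paste0(f, "_timestamp")))
      if (length(value_cols)) {
        keep <- rowSums(!vapply(records[value_cols], function(col) {
          is_blank(as.character(col))
        }, logical(nrow(records)))) > 0
      } else {
        keep <- rep(TRUE, nrow(records))
      }
      groups[[length(groups) + 1L]] <- list(
        key = f, vars = vars,
        data = records[keep, vars, drop = FALSE])
    }
  }
  structure(list(groups = groups, by = by), class = "rc_split")
}

#' @export
print.rc_split <- function(x, ...) {
  cat(sprintf("Record table split by %s: %d groups\n", x$by, length(x$groups)))
  for (g in x$groups) {
    cat(sprintf("  %s: %d rows, %d vars\n", g$key, nrow(g$data),
                length(g$vars)))
  }
  invisible(x)
}

#' Run the full transformation pipeline
#'
#' Applies the five default steps in order — calc-field recalculation,
#' checkbox transformation, factor substitution, branching-logic
#' translation into the dictionary, pattern-based deletion — then the
#' optional split, and records a human-readable trace of each step.
#'
#' @param project A `redcap_project`.
#' @param checkbox_labels Unchecked/checked labels (default No/Yes).
#' @param delete_patterns Column-name patterns to delete (default
#'   `"_complete"`, `"_timestamp"`).
#' @param delete_mode `"suffix"` (default) or `"substring"` matching.
#' @param final_format `"raw"`, `"by_event"` (requires the event map) or
#'   `"by_form"`.
#' @param checkbox_na_policy See [transform_checkboxes()].
#' @return An `rc_transform`: `data` (record table or `rc_split`),
#'   `dictionary` (updated), `trace` (list of step records), `recalc`
#'   (the [recalc_fields()] result), `event_map`, `id_field`.
#' @export
rc_transform <- function(project,
                         checkbox_labels = c("No", "Yes"),
                         delete_patterns = c("_complete", "_timestamp"),
                         delete_mode = c("suffix", "substring"),
                         final_format = c("raw", "by_event", "by_form"),
                         checkbox_na_policy = c("branching_missing_only",
                                                "branching_missing_or_false")) {
  if (!inherits(project, "redcap_project")) {
    validation_error("project must be a redcap_project (see read_redcap_project)")
  }
  final_format <- match.arg(final_format)
  delete_mode <- match.arg(delete_mode)
  checkbox_na_policy <- match.arg(checkbox_na_policy)
  if (!length(delete_patterns) || any(!nzchar(delete_patterns))) {
    config_error("delete_patterns must be a non-empty list of non-empty strings")
  }
  if (final_format == "by_event" && is.null(project$event_map)) {
    config_error("final_format = \"by_event\" requires an event-form mapping")
  }

  records <- project$records
  dictionary <- project$dictionary
  trace <- list()
  add_step <- function(title, details, warnings = character(0)) {
    trace[[length(trace) + 1L]] <<- list(step = length(trace) + 1L,
                                         title = title, details = details,
                                         warnings = warnings)
  }

  # 1. recalculation
  recalc <- recalc_fields(records, dictionary, project$event_map)
  det <- if (nrow(recalc$summary)) {
    sprintf("%s: recalculated values %s the original ones (%d mismatch)",
            recalc$summary$field, ifelse(recalc$summary$status == "identical",
                                         "are identical to", "do NOT match"),
            recalc$summary$n_mismatch)
  } else "no calculated fields"
  add_step("Recalculation of calculated fields", det,
           warnings = unlist(recalc$skipped, use.names = FALSE) %||% character(0))

  # 2. checkboxes
  cb <- transform_checkboxes(records, dictionary,
                             checkbox_labels = checkbox_labels,
                             na_policy = checkbox_na_policy)
  records <- cb$records
  dictionary <- cb$dictionary
  n_cb <- sum(project$dictionary$field_type == "checkbox")
  add_step("Checkbox transformation",
           sprintf("%d checkbox field(s) renamed to their option names; labels set to %s/%s",
                   n_cb, checkbox_labels[1], checkbox_labels[2]),
           warnings = cb$warnings)

  # 3. factor substitution
  records <- apply_factors(records, dictionary, project$event_map)
  add_step("Factor substitution",
           "category codes replaced by their labels; event and DAG columns keep both versions",
           warnings = attr(records, "factor_warnings") %||% character(0))
  attr(records, "factor_warnings") <- NULL

  # 4. branching-logic translation
  warn4 <- character(0)
  n_tr <- 0L
  for (i in seq_len(nrow(dictionary))) {
    bl <- trimws2(dictionary$branching_logic[i])
    if (!nzchar(bl)) next
    tr <- translate_logic(bl, dictionary)
    if (tr$translatable) {
      dictionary$branching_logic[i] <- tr$rendered
      n_tr <- n_tr + 1L
    } else {
      warn4 <- c(warn4, sprintf("field '%s': %s", dictionary$field_name[i],
                                tr$warning))
    }
  }
  add_step("Branching-logic translation",
           sprintf("%d branching logic expression(s) converted to R logic in the dictionary",
                   n_tr),
           warnings = warn4)

  # 5. pattern deletion
  records <- delete_pattern_vars(records, delete_patterns, mode = delete_mode)
  deleted <- attr(records, "deleted_vars") %||% character(0)
  attr(records, "deleted_vars") <- NULL
  add_step("Deletion of pattern variables",
           sprintf("%d variable(s) removed matching pattern(s) %s%s",
                   length(deleted),
                   paste(sQuote(delete_patterns, q = FALSE), collapse = ", "),
                   if (length(deleted))
                     paste0(": ", paste(deleted, collapse = ", ")) else ""))

  data_out <- records
  if (final_format != "raw") {
    data_out <- split_records(records,
                              by = sub("^by_", "", final_format),
                              dictionary = dictionary,
                              event_map = project$event_map)
    add_step(sprintf("Split %s", gsub("_", " ", final_format)),
             sprintf("%d group(s)", length(data_out$groups)))
  }

  structure(list(data = data_out, dictionary = dictionary, trace = trace,
                 recalc = recalc, event_map = project$event_map,
                 id_field = project$id_field),
            class = "rc_transform")
}

#' @export
print.rc_transform <- function(x, ...) {
  cat("Transformation result\n")
  for (s in x$trace) {
    cat(sprintf("%d. %s\n", s$step, s$title))
    for (d in s$details) cat("   ", d, "\n", sep = "")
    for (w in s$warnings) cat("   warning: ", w, "\n", sep = "")
  }
  invisible(x)
}
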