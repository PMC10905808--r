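# Reading the three REDCap export files into a validated project bundle,
# and report/bundle persistence.

#' Read the event-form mapping ("Designate Instruments for My Events" export)
#'
#' @param event_path Path to the CSV with columns `arm_num`,
#'   `unique_event_name`, `form`.
#' @return A data.frame of class `redcap_event_map`.
#' @export
read_event_map <- function(event_path) {
  df <- read_raw_csv(event_path)
  needed <- c("arm_num", "unique_event_name", "form")
  idx <- match(norm_header(needed), norm_header(names(df)))
  if (anyNA(idx)) {
    schema_error(paste0("Event-form mapping header mismatch.\n  Expected: ",
                        paste(needed, collapse = ", "),
                        "\n  Found: ", paste(names(df), collapse = ", ")))
  }
  out <- df[, idx, drop = FALSE]
  names(out) <- needed
  key <- paste(out$arm_num, out$unique_event_name, out$form, sep = "\r")
  if (anyDuplicated(key)) {
    validation_error("Duplicate (arm, event, form) entries in event-form mapping")
  }
  class(out) <- c("redcap_event_map", "data.frame")
  out
}

# Events mapped for a given form, in mapping order.
events_for_form <- function(event_map, form) {
  unique(event_map$unique_event_name[event_map$form == form])
}

forms_for_event <- function(event_map, event) {
  unique(event_map$form[event_map$unique_event_name == event])
}

# Classify the record-table columns against the dictionary; errors on any
# column that is neither a field, a checkbox `field___code` column, a
# `<form>_complete` / `*_timestamp` column nor a reserved column.
validate_record_columns <- function(records, dictionary, id_field) {
  forms <- unique(dictionary$form_name)
  data_fields <- dictionary$field_name[dictionary$field_type != "descriptive"]
  cb_fields <- dictionary$field_name[dictionary$field_type == "checkbox"]
  for (col in names(records)) {
    if (col %in% c(id_field, RESERVED_COLUMNS)) next
    if (col %in% data_fields) next
    if (col %in% paste0(forms, "_complete")) next
    if (endsWith(col, "_timestamp")) next
    if (grepl("___", col, fixed = TRUE)) {
      parts <- strsplit(col, "___", fixed = TRUE)[[1]]
      field <- parts[1]
      code <- paste(parts[-1], collapse = "___")
      if (!(field %in% cb_fields)) {
        validation_error(sprintf(
          "Column '%s' looks like a checkbox export but the dictionary has no checkbox field '%s'",
          col, field))
      }
      if (!(code %in% names(dic_choices(dictionary, field)))) {
        validation_error(sprintf(
          "Checkbox column '%s': code '%s' is not a choice of field '%s'",
          col, code, field))
      }
      next
    }
    validation_error(sprintf("Unknown column '%s' in records file", col))
  }
  invisible(TRUE)
}

#' Read a REDCap project export into a validated bundle
#'
#' Reads the records CSV (raw coded values), the data dictionary and,
#' optionally, the event-form mapping, and cross-validates them. Raw values
#' are preserved as strings; empty cells are the internal missing marker.
#'
#' @param data_path Path to the records CSV.
#' @param dic_path Path to the data dictionary CSV.
#' @param event_path Optional path to the event-form mapping CSV.
#' @return A list of class `redcap_project` with elements `records`,
#'   `dictionary`, `event_map` (or `NULL`) and `labels` (field -> code->label).
#' @export
read_redcap_project <- function(data_path, dic_path, event_path = NULL) {
  dictionary <- read_data_dictionary(dic_path)
  records <- read_raw_csv(data_path)
  event_map <- if (!is.null(event_path)) read_event_map(event_path) else NULL

  id_field <- dictionary$field_name[1]
  if (!(id_field %in% names(records))) {
    validation_error(sprintf(
      "Record identifier column '%s' (first dictionary field) not found in records",
      id_field))
  }
  validate_record_columns(records, dictionary, id_field)

  if (!is.null(event_map)) {
    bad_forms <- setdiff(event_map$form, unique(dictionary$form_name))
    if (length(bad_forms)) {
      validation_error(paste(
        "Event-form mapping references forms absent from the dictionary:",
        paste(bad_forms, collapse = ", ")))
    }
    if ("redcap_event_name" %in% names(records)) {
      bad_ev <- setdiff(unique(records$redcap_event_name),
                        c(event_map$unique_event_name, ""))
      if (length(bad_ev)) {
        validation_error(paste(
          "Records contain events absent from the event-form mapping:",
          paste(bad_ev, collapse = ", ")))
      }
    }
  }

  # Uniqueness of (record, event [, repeat instance]) keys; rows are
  # reported 1-based counting data rows only.
  key <- records[[id_field]]
  for (col in intersect(c("redcap_event_name", "redcap_repeat_instrument",
                          "redcap_repeat_instance"), names(records))) {
    key <- paste(key, records[[col]], sep = "\r")
  }
  dup <- which(duplicated(key))
  if (length(dup)) {
    validation_error(sprintf(
      "Duplicate (record, event) rows in records file (first duplicate at data row %d)",
      dup[1]))
  }

  labels <- dictionary$choice_map
  names(labels) <- dictionary$field_name
  labels <- labels[!vapply(labels, is.null, logical(1))]

  structure(list(records = records, dictionary = dictionary,
                 event_map = event_map, labels = labels,
                 id_field = id_field),
            class = "redcap_project")
}

#' Live API import (documented stub)
#'
#' Reading a project straight from a REDCap server requires an API token —
#' effectively a back-door credential to the whole dataset — and is
#' deliberately not implemented here: the pipeline operates on the
#' exported files. Export the records, dictionary and event-form mapping
#' CSVs and use [read_redcap_project()].
#'
#' @param uri REDCap API endpoint (unused).
#' @param token API token (unused).
#' @export
read_redcap_api <- function(uri, token) {
  config_error(paste(
    "Live API import is not implemented: export the records, dictionary",
    "and event-form mapping CSVs and use read_redcap_project()."))
}

#' @export
print.redcap_project <- function(x, ...) {
  cat(sprintf("REDCap project: %d rows x %d columns, %d dictionary fields\n",
              nrow(x$records), ncol(x$records), nrow(x$dictionary)))
  if (!is.null(x$event_map)) {
    cat(sprintf("  events: %s\n",
                paste(unique(x$event_map$unique_event_name), collapse = ", ")))
  }
  invisible(x)
}

#' Write a project bundle back to disk as the three export CSVs
#'
#' Inverse of [read_redcap_project()]: writes `records.csv`,
#' `dictionary.csv` and (if present) `events.csv` under `dir`.
#'
#' @param project A `redcap_project`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_redcap_project <- function(project, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raw_csv(project$records, file.path(dir, "records.csv"))
  write_data_dictionary(project$dictionary, file.path(dir, "dictionary.csv"))
  if (!is.null(project$event_map)) {
    write_raw_csv(as.data.frame(unclass(project$event_map),
                                stringsAsFactors = FALSE),
                  file.path(dir, "events.csv"))
  }
  invisible(dir)
}

REPORT_COLUMNS <- c("Identifier", "DAG", "Event", "Instrument", "Field",
                    "Description", "Query", "Code")

#' Write a query report or report diff to disk
#'
#' Columns are exactly `Identifier, DAG, Event, Instrument, Field,
#' Description, Query, Code` (plus `Modification` for a diff), in that
#' order. The internal snapshot value used for diffing is not printed.
#'
#' @param report An `rc_query_report` or `rc_query_diff`.
#' @param path Output path.
#' @param format `"csv"` or `"xlsx"` (xlsx needs the optional `openxlsx`
#'   package).
#' @export
write_query_report <- function(report, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  df <- report_frame(report)
  cols <- REPORT_COLUMNS
  if ("Modification" %in% names(df)) cols <- c(cols, "Modification")
  df <- df[, cols, drop = FALSE]
  if (format == "csv") {
    write_raw_csv(df, path)
  } else {
    if (!requireNamespace("openxlsx", quietly = TRUE)) {
      io_error("xlsx output requires the optional 'openxlsx' package; use format = \"csv\"")
    }
    openxlsx::write.xlsx(df, path)
  }
  invisible(path)
}

# Rendered (printable) frame for a report-like object.
report_frame <- function(report) {
  if (inherits(report, "rc_query_report")) {
    q <- report$queries
    data.frame(Identifier = q$identifier, DAG = q$dag, Event = q$event,
               Instrument = q$instrument, Field = q$field,
               Description = q$description, Query = q$query, Code = q$code,
               stringsAsFactors = FALSE, check.names = FALSE)
  } else if (inherits(report, "rc_query_diff")) {
    q <- report$merged
    data.frame(Identifier = q$identifier, DAG = q$dag, Event = q$event,
               Instrument = q$instrument, Field = q$field,
               Description = q$description, Query = q$query, Code = q$code,
               Modification = q$modification,
               stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    validation_error("report must be an rc_query_report or rc_query_diff")
  }
}

#' Read a query report written by [write_query_report()]
#'
#' @param path CSV path.
#' @return An `rc_query_report` (snapshot values are not persisted and come
#'   back as `NA`; diffs against re-read reports treat them as unchanged).
#' @export
read_query_report <- function(path) {
  df <- read_raw_csv(path)
  missing <- setdiff(REPORT_COLUMNS, names(df))
  if (length(missing)) {
    schema_error(paste("Query report is missing columns:",
                       paste(missing, collapse = ", ")))
  }
  queries <- data.frame(
    identifier = df$Identifier, dag = df$DAG, event = df$Event,
    instrument = df$Instrument, field = df$Field,
    description = df$Description, query = df$Query, code = df$Code,
    rule = rule_from_query_text(df$Query),
    snapshot_value = NA_character_,
    stringsAsFactors = FALSE)
  new_query_report(queries)
}
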