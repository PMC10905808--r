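# Data dictionary (REDCap metadata) reading, validation and writing.
#
# The internal representation is a data.frame of class "redcap_dictionary"
# with one row per field and columns:
#   field_name, form_name, field_type, field_label, choices (raw string),
#   calculation, branching_logic, val_type, val_min, val_max
# plus a parsed list-column `choice_map` (named character vector code->label
# for radio/dropdown/checkbox/slider fields, NULL otherwise).

# Two dictionary dialects circulate: the web export header and the
# API-style snake_case header. Both are normalized onto one schema.
DIC_WEB_HEADER <- c(
  field_name      = "Variable / Field Name",
  form_name       = "Form Name",
  field_type      = "Field Type",
  field_label     = "Field Label",
  choices         = "Choices, Calculations, OR Slider Labels",
  val_type        = "Text Validation Type OR Show Slider Number",
  val_min         = "Text Validation Min",
  val_max         = "Text Validation Max",
  branching_logic = "Branching Logic"
)

DIC_API_HEADER <- c(
  field_name      = "field_name",
  form_name       = "form_name",
  field_type      = "field_type",
  field_label     = "field_label",
  choices         = "select_choices_or_calculations",
  val_type        = "text_validation_type_or_show_slider_number",
  val_min         = "text_validation_min",
  val_max         = "text_validation_max",
  branching_logic = "branching_logic"
)

CHOICE_FIELD_TYPES <- c("radio", "dropdown", "checkbox")
FIELD_TYPES <- c("text", "notes", "radio", "dropdown", "checkbox", "yesno",
                 "truefalse", "calc", "file", "slider", "descriptive")

# Header matching tolerates case/punctuation drift ("Choices, Calculations,
# OR Slider Labels" vs "Choices Calculations OR Slider Labels").
norm_header <- function(x) gsub("[^a-z0-9]+", "", tolower(x))

#' Parse a REDCap choices string
#'
#' Splits `"1, Yes | 0, No"` into an ordered named character vector
#' `c("1" = "Yes", "0" = "No")`. Options are separated by `|`; within an
#' option the code is everything before the first comma, so labels may
#' themselves contain commas.
#'
#' @param x A single choices string (may be empty).
#' @return A named character vector (possibly empty), codes as names.
#' @export
parse_choices <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws2(x))) {
    return(stats::setNames(character(0), character(0)))
  }
  parts <- trimws2(strsplit(x, "|", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  codes <- character(length(parts))
  labels <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]
    cut <- regexpr(",", p, fixed = TRUE)
    if (cut < 0) {       # slider-style label without a code
      codes[i] <- p
      labels[i] <- p
    } else {
      codes[i] <- trimws2(substr(p, 1, cut - 1))
      labels[i] <- trimws2(substring(p, cut + 1))
    }
  }
  if (anyDuplicated(codes)) {
    schema_error(sprintf("Duplicate choice codes in \"%s\"", x))
  }
  stats::setNames(labels, codes)
}

match_dictionary_dialect <- function(found) {
  nf <- norm_header(found)
  for (hdr in list(DIC_WEB_HEADER, DIC_API_HEADER)) {
    idx <- match(norm_header(hdr), nf)
    if (!anyNA(idx)) {
      return(stats::setNames(found[idx], names(hdr)))
    }
  }
  schema_error(paste0(
    "Dictionary header mismatch.\n  Expected (web dialect): ",
    paste(DIC_WEB_HEADER, collapse = ", "),
    "\n  or (API dialect): ", paste(DIC_API_HEADER, collapse = ", "),
    "\n  Found: ", paste(found, collapse = ", ")))
}

#' Read a REDCap data dictionary
#'
#' Reads the standard metadata CSV (either the web export header
#' "Variable / Field Name", ... or the API snake_case header) and validates
#' it: field names must be unique and must not contain `___` (reserved for
#' checkbox export columns), `calc` fields must carry a calculation, and
#' radio/dropdown/checkbox fields must carry choices.
#'
#' @param dic_path Path to the dictionary CSV.
#' @return A `redcap_dictionary` data.frame, one row per field.
#' @export
read_data_dictionary <- function(dic_path) {
  raw <- read_raw_csv(dic_path)
  sel <- match_dictionary_dialect(names(raw))
  df <- raw[, unname(sel), drop = FALSE]
  names(df) <- names(sel)
  new_dictionary(df)
}

# Internal constructor + validator over the normalized columns.
new_dictionary <- function(df) {
  needed <- names(DIC_WEB_HEADER)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    schema_error(paste("Dictionary is missing columns:",
                       paste(missing, collapse = ", ")))
  }
  df <- df[, needed, drop = FALSE]
  df$field_type <- tolower(trimws2(df$field_type))
  df$field_name <- trimws2(df$field_name)

  # descriptive fields carry no data; keep them but they never validate
  # record columns.
  dup <- df$field_name[duplicated(df$field_name)]
  if (length(dup)) {
    schema_error(paste("Duplicate field names in dictionary:",
                       paste(unique(dup), collapse = ", ")))
  }
  bad <- grepl("___", df$field_name, fixed = TRUE)
  if (any(bad)) {
    validation_error(paste(
      "Field names must not contain '___' (reserved for checkbox columns):",
      paste(df$field_name[bad], collapse = ", ")))
  }
  unknown <- setdiff(unique(df$field_type), FIELD_TYPES)
  if (length(unknown)) {
    schema_error(paste("Unknown field types:", paste(unknown, collapse = ", ")))
  }

  df$calculation <- ifelse(df$field_type == "calc", df$choices, "")
  calc_empty <- df$field_type == "calc" & !nzchar(trimws2(df$calculation))
  if (any(calc_empty)) {
    schema_error(paste("calc fields with an empty calculation:",
                       paste(df$field_name[calc_empty], collapse = ", ")))
  }

  df$choice_map <- lapply(seq_len(nrow(df)), function(i) {
    if (df$field_type[i] %in% c(CHOICE_FIELD_TYPES, "slider")) {
      parse_choices(df$choices[i])
    } else NULL
  })
  no_choices <- df$field_type %in% CHOICE_FIELD_TYPES &
    vapply(df$choice_map, length, integer(1)) == 0L
  if (any(no_choices)) {
    schema_error(paste("Choice fields without choices:",
                       paste(df$field_name[no_choices], collapse = ", ")))
  }
  rownames(df) <- NULL
  class(df) <- c("redcap_dictionary", "data.frame")
  df
}

dic_field <- function(dictionary, name) {
  i <- match(name, dictionary$field_name)
  if (is.na(i)) NULL else dictionary[i, , drop = FALSE]
}

dic_choices <- function(dictionary, name) {
  i <- match(name, dictionary$field_name)
  if (is.na(i)) return(NULL)
  dictionary$choice_map[[i]]
}

#' Write a dictionary back as a metadata CSV (web export dialect)
#'
#' @param dictionary A `redcap_dictionary`.
#' @param path Output CSV path.
#' @export
write_data_dictionary <- function(dictionary, path) {
  out <- data.frame(matrix("", nrow(dictionary), length(DIC_WEB_HEADER)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unname(DIC_WEB_HEADER)
  for (key in names(DIC_WEB_HEADER)) {
    out[[DIC_WEB_HEADER[[key]]]] <- dictionary[[key]]
  }
  # calc fields store the calculation in the choices column, REDCap-style
  is_calc <- dictionary$field_type == "calc"
  out[[DIC_WEB_HEADER[["choices"]]]][is_calc] <- dictionary$calculation[is_calc]
  write_raw_csv(out, path)
}

#' @export
print.redcap_dictionary <- function(x, ...) {
  cat(sprintf("REDCap dictionary: %d fields, %d forms\n",
              nrow(x), length(unique(x$form_name))))
  tab <- table(x$field_type)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}
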