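#' @keywords internal
"_PACKAGE"

# Condition constructors. Every error raised by the package carries a
# subclass so callers (and the CLI) can distinguish user/validation errors
# from unexpected failures.
rc_abort <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "rcqc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

io_error         <- function(msg, ...) rc_abort(msg, "rcqc_io_error", ...)
schema_error     <- function(msg, ...) rc_abort(msg, "rcqc_schema_error", ...)
validation_error <- function(msg, ...) rc_abort(msg, "rcqc_validation_error", ...)
config_error     <- function(msg, ...) rc_abort(msg, "rcqc_config_error", ...)
spec_error       <- function(msg, ...) rc_abort(msg, "rcqc_spec_error", ...)
parse_error <- function(msg, pos) {
  pos <- as.integer(pos)
  rc_abort(sprintf("%s (at offset %d)", msg, pos), "rcqc_parse_error",
           position = pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The internal missing marker is the empty string: REDCap exports blanks,
# and a literal "NA" in a raw export is a value, not a missing cell.
is_blank <- function(x) is.na(x) | x == ""

trimws2 <- function(x) trimws(x, which = "both")

# "hospital_11" -> "Hospital 11"; "baseline_visit_arm_1" -> "Baseline visit"
# (the arm suffix is stripped only when strip_arm = TRUE). Only the first
# character is capitalised, mirroring how REDCap prints event/DAG labels.
prettify_label <- function(x, strip_arm = FALSE) {
  out <- as.character(x)
  if (strip_arm) out <- sub("_arm_[0-9]+$", "", out)
  out <- gsub("_", " ", out)
  out <- trimws2(out)
  has <- !is.na(out) & nzchar(out)
  out[has] <- paste0(toupper(substr(out[has], 1, 1)), substring(out[has], 2))
  out
}

# Natural sort key: digit runs are zero-padded so "100-9" < "100-58".
natural_sortkey <- function(x) {
  x <- as.character(x)
  vapply(x, function(s) {
    if (is.na(s)) return("")
    m <- gregexpr("[0-9]+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(v) {
      if (length(v)) sprintf("%012d", as.numeric(v)) else v
    })
    s
  }, character(1), USE.NAMES = FALSE)
}

natural_order <- function(x) order(natural_sortkey(x))

# Sanitize a checkbox option label into a column name:
# lowercase, non-alphanumeric runs -> "_", trimmed; empty -> "option".
sanitize_name <- function(x) {
  out <- tolower(as.character(x))
  out <- gsub("[^a-z0-9]+", "_", out)
  out <- gsub("^_+|_+$", "", out)
  out[!nzchar(out)] <- "option"
  out
}

# Raw REDCap CSV reader: everything as character, blanks kept as "",
# the literal string "NA" preserved as a value.
read_raw_csv <- function(path) {
  if (!file.exists(path)) {
    io_error(sprintf("File not found: '%s'", path))
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = character(0),
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- ""
  df
}

write_raw_csv <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("Cannot write file: '%s'", path))
  invisible(path)
}

# Deterministic RNG scope: the generator algorithm is pinned explicitly so
# seeded output is reproducible across platforms and R versions >= 3.6.
with_fixed_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    spec_error("seed must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Columns every REDCap export may carry regardless of the dictionary.
RESERVED_COLUMNS <- c("redcap_event_name", "redcap_data_access_group",
                      "redcap_repeat_instrument", "redcap_repeat_instance")
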