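# Fixture builders: tiny dictionaries/records written as temp CSVs, and
# generated synthetic projects.

dic_row <- function(name, form, type, label, choices = "", val = "",
                    vmin = "", vmax = "", branching = "") {
  data.frame("Variable / Field Name" = name, "Form Name" = form,
             "Field Type" = type, "Field Label" = label,
             "Choices, Calculations, OR Slider Labels" = choices,
             "Text Validation Type OR Show Slider Number" = val,
             "Text Validation Min" = vmin, "Text Validation Max" = vmax,
             "Branching Logic" = branching,
             check.names = FALSE, stringsAsFactors = FALSE)
}

write_dic_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  path
}

write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

write_events_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# A minimal two-field single-form project with three records.
tiny_project <- function() {
  dic <- write_dic_csv(list(
    dic_row("record_id", "demographics", "text", "Record ID"),
    dic_row("age", "demographics", "text", "Age", val = "integer",
            vmin = "0", vmax = "120")))
  rec <- write_records_csv(data.frame(
    record_id = c("1", "2", "3"), age = c("34", "", "61"),
    stringsAsFactors = FALSE))
  read_redcap_project(rec, dic)
}

# A generated synthetic project in a self-cleaning temp directory.
local_fixture <- function(spec = fixture_spec(), env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  manifest <- generate_fixture(spec, dir)
  list(dir = dir, manifest = manifest,
       project = read_redcap_project(file.path(dir, "records.csv"),
                                     file.path(dir, "dictionary.csv"),
                                     file.path(dir, "events.csv")))
}

read_fixture_dir <- function(dir) {
  read_redcap_project(file.path(dir, "records.csv"),
                      file.path(dir, "dictionary.csv"),
                      file.path(dir, "events.csv"))
}

# The combined validity rules used in diffing tests: they flag a blank,
# an out-of-range and a "miscorrected" 999 alike, so the match key stays
# stable across snapshots.
COMBINED_RULES <- list(
  variables = c("copd", "age"),
  expressions = c("[copd] = '0' or [copd] = '1'",
                  "[age] <> '' and ([age] >= 18 and [age] <= 100)"))

combined_query <- function(project) {
  rc_query(project, COMBINED_RULES$variables, COMBINED_RULES$expressions)
}
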