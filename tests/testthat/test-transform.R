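cb_project <- function(has_comorb = c("1", "0", ""), branching = TRUE) {
  dic <- write_dic_csv(list(
    dic_row("record_id", "f1", "text", "ID"),
    dic_row("has_comorb", "f1", "yesno", "Any comorbidity"),
    dic_row("comorb", "f1", "checkbox", "Comorbidities",
            choices = "1, Hypertension | 2, Diabetes",
            branching = if (branching) "[has_comorb] = '1'" else "")))
  rec <- write_records_csv(data.frame(
    record_id = as.character(seq_along(has_comorb)),
    has_comorb = has_comorb,
    comorb___1 = rep("1", length(has_comorb)),
    comorb___2 = rep("0", length(has_comorb)),
    check.names = FALSE, stringsAsFactors = FALSE))
  read_redcap_project(rec, dic)
}

test_that("checkbox columns are renamed to option labels with No/Yes values", {
  p <- cb_project()
  out <- transform_checkboxes(p$records, p$dictionary)
  expect_true(all(c("hypertension", "diabetes") %in% names(out$records)))
  expect_false(any(grepl("comorb___", names(out$records))))
  expect_identical(as.character(out$records$hypertension[1]), "Yes")
  expect_identical(as.character(out$records$diabetes[1]), "No")
  # branching false keeps values under the default policy ...
  expect_identical(as.character(out$records$hypertension[2]), "Yes")
  # ... but a missing branching result blanks the whole field's options
  expect_true(is.na(out$records$hypertension[3]))
  expect_true(is.na(out$records$diabetes[3]))
  # the dictionary now carries one No/Yes field per option
  expect_true(all(c("hypertension", "diabetes") %in%
                    out$dictionary$field_name))
})

test_that("the stricter policy also blanks branching-false rows", {
  p <- cb_project()
  out <- transform_checkboxes(p$records, p$dictionary,
                              na_policy = "branching_missing_or_false")
  expect_true(is.na(out$records$hypertension[2]))
  expect_identical(as.character(out$records$hypertension[1]), "Yes")
})

test_that("checkboxes without branching logic are reported", {
  p <- cb_project(branching = FALSE)
  out <- transform_checkboxes(p$records, p$dictionary)
  expect_match(out$warnings, "no branching logic")
  expect_identical(as.character(out$records$hypertension[3]), "Yes")
})

test_that("factor substitution labels codes and keeps raw event/DAG versions", {
  dic <- write_dic_csv(list(
    dic_row("record_id", "f1", "text", "ID"),
    dic_row("sex", "f1", "radio", "Sex", choices = "1, Female | 2, Male"),
    dic_row("copd", "f1", "yesno", "COPD")))
  rec <- write_records_csv(data.frame(
    record_id = c("1", "2", "3"),
    redcap_event_name = "baseline_arm_1",
    redcap_data_access_group = c("hospital_11", "hospital_11", ""),
    sex = c("1", "2", "9"), copd = c("1", "0", ""),
    stringsAsFactors = FALSE))
  p <- read_redcap_project(rec, dic)
  out <- apply_factors(p$records, p$dictionary)
  expect_identical(as.character(out$sex[1:2]), c("Female", "Male"))
  expect_identical(levels(out$sex), c("Female", "Male", "9"))
  expect_identical(as.character(out$sex[3]), "9")  # unknown code verbatim
  expect_match(attr(out, "factor_warnings"), "'9'")
  expect_identical(as.character(out$copd), c("Yes", "No", NA))
  expect_identical(out$redcap_event_name, rep("baseline_arm_1", 3))
  expect_identical(as.character(out$redcap_event_name_label),
                   rep("Baseline", 3))
  expect_identical(out$redcap_data_access_group_label,
                   c("Hospital 11", "Hospital 11", NA))
})

test_that("already-labelled data is rejected, not re-factored", {
  dic <- write_dic_csv(list(
    dic_row("record_id", "f1", "text", "ID"),
    dic_row("sex", "f1", "radio", "Sex", choices = "1, Female | 2, Male")))
  rec <- write_records_csv(data.frame(
    record_id = c("1", "2"), sex = c("Female", "Male"),
    stringsAsFactors = FALSE))
  p <- read_redcap_project(rec, dic)
  expect_error(apply_factors(p$records, p$dictionary),
               class = "rcqc_validation_error")
})

test_that("pattern deletion is suffix-anchored and idempotent", {
  df <- data.frame(age = "1", comorbidities_complete = "2",
                   survey_timestamp = "t", complete_response = "x",
                   stringsAsFactors = FALSE)
  out <- delete_pattern_vars(df, c("_complete", "_timestamp"))
  expect_identical(sort(names(out)), c("age", "complete_response"))
  expect_identical(sort(attr(out, "deleted_vars")),
                   c("comorbidities_complete", "survey_timestamp"))
  again <- delete_pattern_vars(out, c("_complete", "_timestamp"))
  expect_identical(names(again), names(out))
  expect_error(delete_pattern_vars(df, character(0)),
               class = "rcqc_config_error")
  # substring mode is the documented switch for the literal reading
  out2 <- delete_pattern_vars(df, "complete", mode = "substring")
  expect_identical(names(out2), c("age", "survey_timestamp"))
})

test_that("the default pipeline runs five traced steps on the fixture", {
  fx <- local_fixture(fixture_spec(seed = 4))
  tr <- rc_transform(fx$project)
  expect_length(tr$trace, 5L)
  expect_identical(vapply(tr$trace, `[[`, integer(1), "step"), 1:5)
  # the planted age perturbation is flagged by step 1
  expect_identical(tr$recalc$summary$status[
    tr$recalc$summary$field == "age"], "not identical")
  expect_equal(tr$recalc$summary$n_mismatch[
    tr$recalc$summary$field == "age"], 1L)
  # the unbranched checkbox is reported by step 2
  expect_match(tr$trace[[2]]$warnings, "symptoms")
  # no surviving column matches a delete pattern
  expect_false(any(endsWith(names(tr$data), "_complete") |
                     endsWith(names(tr$data), "_timestamp")))
  # rows survive every step
  expect_equal(nrow(tr$data), nrow(fx$project$records))
})

test_that("configuration overrides behave and are validated", {
  fx <- local_fixture(fixture_spec(seed = 4))
  tr <- rc_transform(fx$project, delete_patterns = "_complete")
  expect_true("follow_up_timestamp" %in% names(tr$data))
  expect_error(rc_transform(fx$project, delete_patterns = character(0)),
               class = "rcqc_config_error")
  p_no_events <- read_redcap_project(file.path(fx$dir, "records.csv"),
                                     file.path(fx$dir, "dictionary.csv"))
  expect_error(rc_transform(p_no_events, final_format = "by_event"),
               class = "rcqc_config_error")
})

test_that("splitting by event groups rows and restricts variables", {
  fx <- local_fixture(fixture_spec(seed = 4, missing_events = 0))
  tr <- rc_transform(fx$project, final_format = "by_event")
  expect_length(tr$trace, 6L)
  sp <- tr$data
  expect_s3_class(sp, "rc_split")
  expect_length(sp$groups, 2L)
  keys <- vapply(sp$groups, `[[`, character(1), "key")
  expect_setequal(keys, c("baseline_visit_arm_1", "follow_up_visit_arm_1"))
  # group rows cover the source
  expect_equal(sum(vapply(sp$groups, function(g) nrow(g$data), integer(1))),
               nrow(fx$project$records))
  # baseline group holds demographics columns, not follow-up ones
  base <- sp$groups[[match("baseline_visit_arm_1", keys)]]
  expect_true("age" %in% base$vars)
  expect_false("weight" %in% base$vars)
  # split completeness: every non-reserved surviving column is in some group
  all_vars <- unique(unlist(lapply(sp$groups, `[[`, "vars")))
  flat <- rc_transform(fx$project)
  expect_true(all(names(flat$data) %in% all_vars))
})

test_that("splitting by form selects rows with any non-missing value", {
  fx <- local_fixture(fixture_spec(seed = 4, missing_events = 2))
  tr <- rc_transform(fx$project, final_format = "by_form")
  keys <- vapply(tr$data$groups, `[[`, character(1), "key")
  expect_setequal(keys, c("demographics", "comorbidities", "follow_up"))
  fu <- tr$data$groups[[match("follow_up", keys)]]
  # follow-up rows exist only for records with a follow-up event
  expect_equal(nrow(fu$data),
               sum(fx$project$records$redcap_event_name ==
                     "follow_up_visit_arm_1"))
})

test_that("recalc is self-consistent on unperturbed engine-generated values", {
  fx <- local_fixture(fixture_spec(seed = 21, missing = c(copd = 0, age = 0),
                                   calc_mismatch = 0, missing_events = 0))
  tr <- rc_transform(fx$project)
  expect_identical(unique(tr$recalc$summary$status), "identical")
})
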