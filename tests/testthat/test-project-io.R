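test_that("a minimal project reads into a validated bundle", {
  p <- tiny_project()
  expect_s3_class(p, "redcap_project")
  expect_null(p$event_map)
  expect_equal(nrow(p$records), 3L)
  expect_identical(p$records$age, c("34", "", "61"))  # blanks stay ""
  expect_identical(p$id_field, "record_id")
})

test_that("the generated fixture reads back with its full event map", {
  fx <- local_fixture(fixture_spec(seed = 3))
  expect_s3_class(fx$project$event_map, "redcap_event_map")
  expect_equal(nrow(fx$project$event_map), 3L)  # 2 forms + 1 form
  # a 2-events x 3-forms designation file has 6 entries
  ev6 <- write_events_csv(expand.grid(
    arm_num = "1", unique_event_name = c("e1_arm_1", "e2_arm_1"),
    form = c("demographics", "comorbidities", "follow_up"),
    stringsAsFactors = FALSE))
  expect_equal(nrow(read_event_map(ev6)), 6L)
})

test_that("checkbox columns must belong to a dictionary checkbox field", {
  dic <- write_dic_csv(list(
    dic_row("record_id", "f1", "text", "ID"),
    dic_row("sex", "f1", "radio", "Sex", choices = "1, Female | 2, Male")))
  rec <- write_records_csv(data.frame(record_id = "1", sex = "1",
                                      smoker___1 = "0", check.names = FALSE,
                                      stringsAsFactors = FALSE))
  expect_error(read_redcap_project(rec, dic), class = "rcqc_validation_error")
  # a checkbox column with an unknown option code is also rejected
  dic2 <- write_dic_csv(list(
    dic_row("record_id", "f1", "text", "ID"),
    dic_row("smoker", "f1", "checkbox", "Smoker", choices = "1, Yes")))
  rec2 <- write_records_csv(data.frame(record_id = "1", smoker___9 = "0",
                                       check.names = FALSE,
                                       stringsAsFactors = FALSE))
  expect_error(read_redcap_project(rec2, dic2),
               class = "rcqc_validation_error")
})

test_that("missing files and malformed dictionaries raise typed errors", {
  expect_error(read_redcap_project("no/such/records.csv", "no/such/dic.csv"),
               "no/such", class = "rcqc_io_error")
  bad_hdr <- tempfile(fileext = ".csv")
  writeLines("foo,bar\n1,2", bad_hdr)
  expect_error(read_data_dictionary(bad_hdr), "Expected",
               class = "rcqc_schema_error")
  dup <- write_dic_csv(list(dic_row("record_id", "f1", "text", "ID"),
                            dic_row("record_id", "f1", "text", "ID again")))
  expect_error(read_data_dictionary(dup), "Duplicate",
               class = "rcqc_schema_error")
  calcless <- write_dic_csv(list(dic_row("record_id", "f1", "text", "ID"),
                                 dic_row("bmi", "f1", "calc", "BMI")))
  expect_error(read_data_dictionary(calcless), class = "rcqc_schema_error")
})

test_that("both dictionary dialects normalize to the same schema", {
  web <- write_dic_csv(list(
    dic_row("record_id", "f1", "text", "ID"),
    dic_row("sex", "f1", "radio", "Sex", choices = "1, Female | 2, Male")))
  api_df <- data.frame(
    field_name = c("record_id", "sex"), form_name = "f1",
    field_type = c("text", "radio"), field_label = c("ID", "Sex"),
    select_choices_or_calculations = c("", "1, Female | 2, Male"),
    text_validation_type_or_show_slider_number = "",
    text_validation_min = "", text_validation_max = "",
    branching_logic = "", stringsAsFactors = FALSE)
  api <- tempfile(fileext = ".csv")
  utils::write.csv(api_df, api, row.names = FALSE)
  d1 <- read_data_dictionary(web)
  d2 <- read_data_dictionary(api)
  expect_identical(d1$field_name, d2$field_name)
  expect_identical(d1$choice_map, d2$choice_map)
})

test_that("choices parse with first-comma splitting and preserved order", {
  expect_identical(parse_choices("1, Yes | 0, No"),
                   c("1" = "Yes", "0" = "No"))
  expect_identical(parse_choices("1, Type A, mild | 2, Type B"),
                   c("1" = "Type A, mild", "2" = "Type B"))
  expect_identical(parse_choices(""), setNames(character(0), character(0)))
  expect_error(parse_choices("1, A | 1, B"), class = "rcqc_schema_error")
  # calc expressions pass through untouched
  dic <- read_data_dictionary(write_dic_csv(list(
    dic_row("record_id", "f1", "text", "ID"),
    dic_row("weight", "f1", "text", "Weight"),
    dic_row("height", "f1", "text", "Height"),
    dic_row("bmi", "f1", "calc", "BMI",
            choices = "[weight]/(([height]/100)^2)"))))
  expect_identical(dic$calculation[dic$field_name == "bmi"],
                   "[weight]/(([height]/100)^2)")
})

test_that("bundle write -> read is lossless and reading is deterministic", {
  fx <- local_fixture(fixture_spec(seed = 11))
  dir2 <- withr::local_tempdir()
  write_redcap_project(fx$project, dir2)
  p2 <- read_fixture_dir(dir2)
  expect_identical(fx$project$records, p2$records)
  expect_identical(fx$project$dictionary$field_name,
                   p2$dictionary$field_name)
  expect_identical(fx$project$dictionary$choice_map, p2$dictionary$choice_map)
  expect_identical(as.data.frame(fx$project$event_map),
                   as.data.frame(p2$event_map))
  p3 <- read_fixture_dir(fx$dir)
  expect_identical(fx$project$records, p3$records)
})

test_that("every checkbox field contributes one recognized column per code", {
  fx <- local_fixture(fixture_spec(seed = 2))
  dic <- fx$project$dictionary
  for (i in which(dic$field_type == "checkbox")) {
    cols <- paste0(dic$field_name[i], "___", names(dic$choice_map[[i]]))
    expect_true(all(cols %in% names(fx$project$records)))
  }
})

test_that("query reports round-trip through CSV", {
  fx <- local_fixture(fixture_spec(seed = 5))
  report <- rc_query(fx$project, c("copd", "age"), "[copd] <> ''")
  expect_gt(nrow(report$queries), 9L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_query_report(report, path)
  lines <- readLines(path)
  expect_match(lines[1],
               "^\"?Identifier\"?,\"?DAG\"?,\"?Event\"?,\"?Instrument\"?")
  back <- read_query_report(path)
  for (col in c("identifier", "dag", "event", "instrument", "field",
                "description", "query", "code", "rule")) {
    expect_identical(back$queries[[col]], report$queries[[col]])
  }
  # empty report -> header-only file
  empty <- rc_query(fx$project, "copd", "[copd] <> '' or [copd] = ''")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_query_report(empty, p2)
  expect_length(readLines(p2), 1L)
  # diff layout gains the Modification column
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_query_report(rc_check(report, report), p3)
  expect_match(readLines(p3)[1], "\"?Code\"?,\"?Modification\"?$")
})
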