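# Seeded synthetic REDCap projects with planted discrepancies.
#
# The generated project emulates a multicenter longitudinal cohort:
# hospital DAGs, a baseline visit event carrying Demographics and
# Comorbidities forms, and a follow-up visit event. It includes a
# datediff-based age calculation (its stored values computed with this
# package's own logic engine, then optionally perturbed), a
# branching-controlled comorbidity checkbox and, optionally, a checkbox
# with no branching logic, so every pipeline step and query rule has
# something to exercise.

#' Describe a synthetic REDCap project
#'
#' @param n_records Number of records (default 20).
#' @param seed Integer seed; it fully determines the generated bytes.
#' @param dags Data Access Group (site) names.
#' @param missing Named integer vector: how many records get a planted
#'   missing value per field (default `c(copd = 6, age = 5)`; a missing
#'   `age` also blanks the birth date so the stored calc stays
#'   self-consistent).
#' @param out_of_range Number of records whose stored `age` is set to 150
#'   (out of any plausible range; note this also perturbs the calc).
#' @param calc_mismatch Number of records whose stored `age` is offset by
#'   +1 against its own calculation.
#' @param missing_events Number of records whose follow-up event row is
#'   dropped (REDCap does not export empty events).
#' @param unbranched_checkbox Include a checkbox field with no branching
#'   logic (flagged by the transformation trace).
#' @return A list of class `rc_fixture_spec`.
#' @export
fixture_spec <- function(n_records = 20L, seed = 1L,
                         dags = c("hospital_5", "hospital_11", "hospital_24"),
                         missing = c(copd = 6L, age = 5L),
                         out_of_range = 0L, calc_mismatch = 1L,
                         missing_events = 3L, unbranched_checkbox = TRUE) {
  spec <- list(n_records = as.integer(n_records), seed = seed, dags = dags,
               missing = missing, out_of_range = as.integer(out_of_range),
               calc_mismatch = as.integer(calc_mismatch),
               missing_events = as.integer(missing_events),
               unbranched_checkbox = isTRUE(unbranched_checkbox))
  class(spec) <- "rc_fixture_spec"
  spec
}

FIXTURE_EVENTS <- list(
  baseline_visit_arm_1 = c("demographics", "comorbidities"),
  follow_up_visit_arm_1 = "follow_up"
)

fixture_dictionary_frame <- function(unbranched_checkbox = TRUE) {
  row <- function(name, form, type, label, choices = "", val = "",
                  vmin = "", vmax = "", branching = "") {
    data.frame(field_name = name, form_name = form, field_type = type,
               field_label = label, choices = choices, val_type = val,
               val_min = vmin, val_max = vmax, branching_logic = branching,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    row("record_id", "demographics", "text", "Record ID"),
    row("d_birth", "demographics", "text", "Date of birth", val = "date_ymd"),
    row("d_admission", "demographics", "text", "Date of hospital admission",
        val = "date_ymd"),
    row("age", "demographics", "calc", "Age",
        choices = "rounddown(datediff([d_birth],[d_admission],'y'),0)"),
    row("sex", "demographics", "radio", "Sex", choices = "1, Female | 2, Male"),
    row("has_comorb", "comorbidities", "yesno", "Any comorbidity"),
    row("comorb", "comorbidities", "checkbox", "Comorbidities",
        choices = "1, Hypertension | 2, Diabetes | 3, Chronic kidney disease",
        branching = "[has_comorb] = '1'"),
    row("copd", "comorbidities", "yesno",
        "Chronic obstructive pulmonary disease"),
    row("d_visit", "follow_up", "text", "Follow-up visit date",
        val = "date_ymd"),
    row("weight", "follow_up", "text", "Weight (kg)", val = "number",
        vmin = "30", vmax = "250"))
  if (unbranched_checkbox) {
    rows[[length(rows) + 1L]] <- row("symptoms", "follow_up", "checkbox",
                                     "Symptoms at follow-up",
                                     choices = "1, Fever | 2, Cough")
  }
  do.call(rbind, rows)
}

rand_date <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  as.Date(from + floor(stats::runif(n) * (as.numeric(to - from) + 1)),
          origin = "1970-01-01")
}

#' Generate a synthetic REDCap project on disk
#'
#' Writes `records.csv`, `dictionary.csv` and `events.csv` in the same
#' dialects the readers accept, plus `manifest.json` describing every
#' planted discrepancy. Stored calc values are computed with the
#' package's own logic engine before perturbation, so an unperturbed
#' project recalculates cleanly.
#'
#' @param spec An [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest: a data.frame (class `rc_fixture_manifest`) with
#'   one row per planted discrepancy (`kind`, `record_id`, `event`,
#'   `field`, `original`, `perturbed`, plus an auxiliary field/value pair
#'   for plantings that touch two cells), with attribute `dir`.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir) {
  n <- spec$n_records
  miss <- spec$missing
  miss_age <- if ("age" %in% names(miss)) miss[["age"]] else 0L
  if (any(miss > n) || spec$out_of_range + spec$calc_mismatch + miss_age > n ||
      spec$missing_events > n) {
    spec_error("more planted discrepancies than available cells")
  }

  dic_frame <- fixture_dictionary_frame(spec$unbranched_checkbox)
  dictionary <- new_dictionary(dic_frame)

  with_fixed_seed(spec$seed, {
    dag <- sample(spec$dags, n, replace = TRUE)
    prefix <- 100L + (match(dag, spec$dags) - 1L) * 2L
    serial <- stats::ave(seq_len(n), dag, FUN = seq_along)
    ids <- paste0(prefix, "-", serial * 7L %% 97L + serial)  # non-consecutive
    d_birth <- format(rand_date(n, "1940-01-01", "1990-12-31"))
    d_admission <- format(rand_date(n, "2020-03-01", "2020-12-31"))
    sex <- as.character(sample(1:2, n, replace = TRUE))
    has_comorb <- as.character(sample(0:1, n, replace = TRUE))
    comorb <- matrix("0", n, 3)
    for (k in 1:3) {
      comorb[, k] <- ifelse(has_comorb == "1",
                            as.character(stats::rbinom(n, 1, 0.4)), "0")
    }
    copd <- as.character(sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3)))
    d_visit <- format(as.Date(d_admission) + sample(30:90, n, replace = TRUE))
    weight <- sprintf("%.1f", stats::runif(n, 45, 110))
    symptoms <- matrix(as.character(stats::rbinom(2L * n, 1, 0.3)), n, 2)

    # stored age computed by the logic engine itself
    calc <- dic_field(dictionary, "age")$calculation
    age_ast <- parse_logic(calc)
    age <- vapply(seq_len(n), function(i) {
      ctx <- eval_context(row = list(d_birth = d_birth[i],
                                     d_admission = d_admission[i]),
                          dictionary = dictionary)
      format(eval_logic(age_ast, ctx), scientific = FALSE, trim = TRUE)
    }, character(1))

    manifest <- data.frame(kind = character(0), record_id = character(0),
                           event = character(0), field = character(0),
                           original = character(0), perturbed = character(0),
                           aux_field = character(0), aux_value = character(0),
                           stringsAsFactors = FALSE)
    add_entry <- function(kind, rec, event, field, original, perturbed,
                          aux_field = "", aux_value = "") {
      manifest[nrow(manifest) + 1L, ] <<-
        list(kind, rec, event, field, original, perturbed, aux_field, aux_value)
    }
    baseline <- "baseline_visit_arm_1"
    follow_up <- "follow_up_visit_arm_1"

    # planted missing values
    for (field in names(miss)) {
      k <- miss[[field]]
      if (k == 0L) next
      picked <- sample(n, k)
      for (i in picked) {
        if (field == "age") {
          add_entry("missing", ids[i], baseline, "age", age[i], "",
                    aux_field = "d_birth", aux_value = d_birth[i])
          age[i] <- ""; d_birth[i] <- ""
        } else if (field == "copd") {
          add_entry("missing", ids[i], baseline, "copd", copd[i], "")
          copd[i] <- ""
        } else {
          spec_error(sprintf("no planting rule for field '%s'", field))
        }
      }
    }

    # age plantings must not collide with the blanked-age records
    age_free <- which(nzchar(age))
    if (spec$calc_mismatch > 0L) {
      picked <- sample(age_free, spec$calc_mismatch)
      for (i in picked) {
        new_val <- as.character(as.numeric(age[i]) + 1)
        add_entry("calc_mismatch", ids[i], baseline, "age", age[i], new_val)
        age[i] <- new_val
      }
      age_free <- setdiff(age_free, picked)
    }
    if (spec$out_of_range > 0L) {
      picked <- sample(age_free, spec$out_of_range)
      for (i in picked) {
        add_entry("out_of_range", ids[i], baseline, "age", age[i], "150")
        age[i] <- "150"
      }
    }

    drop_fu <- integer(0)
    if (spec$missing_events > 0L) {
      drop_fu <- sample(n, spec$missing_events)
      for (i in drop_fu) {
        add_entry("missing_event", ids[i], follow_up, "", "present", "absent")
      }
    }

    # assemble rows: one per record and event
    cols <- c("record_id", "redcap_event_name", "redcap_data_access_group",
              "d_birth", "d_admission", "age", "sex", "demographics_complete",
              "has_comorb", paste0("comorb___", 1:3), "copd",
              "comorbidities_complete", "d_visit", "weight",
              if (spec$unbranched_checkbox) paste0("symptoms___", 1:2),
              "follow_up_complete", "follow_up_timestamp")
    blank_row <- stats::setNames(as.list(rep("", length(cols))), cols)
    rows <- list()
    for (i in seq_len(n)) {
      b <- blank_row
      b$record_id <- ids[i]; b$redcap_event_name <- baseline
      b$redcap_data_access_group <- dag[i]
      b$d_birth <- d_birth[i]; b$d_admission <- d_admission[i]
      b$age <- age[i]; b$sex <- sex[i]; b$demographics_complete <- "2"
      b$has_comorb <- has_comorb[i]
      for (k in 1:3) b[[paste0("comorb___", k)]] <- comorb[i, k]
      b$copd <- copd[i]; b$comorbidities_complete <- "2"
      rows[[length(rows) + 1L]] <- b
      if (!(i %in% drop_fu)) {
        f <- blank_row
        f$record_id <- ids[i]; f$redcap_event_name <- follow_up
        f$redcap_data_access_group <- dag[i]
        f$d_visit <- d_visit[i]; f$weight <- weight[i]
        if (spec$unbranched_checkbox) {
          for (k in 1:2) f[[paste0("symptoms___", k)]] <- symptoms[i, k]
        }
        f$follow_up_complete <- "2"
        f$follow_up_timestamp <- paste(d_visit[i], "09:00:00")
        rows[[length(rows) + 1L]] <- f
      }
    }
    records <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
    }))

    event_map <- do.call(rbind, lapply(names(FIXTURE_EVENTS), function(ev) {
      data.frame(arm_num = "1", unique_event_name = ev,
                 form = FIXTURE_EVENTS[[ev]], stringsAsFactors = FALSE)
    }))

    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_raw_csv(records, file.path(out_dir, "records.csv"))
    write_data_dictionary(dictionary, file.path(out_dir, "dictionary.csv"))
    write_raw_csv(event_map, file.path(out_dir, "events.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = FALSE)

    attr(manifest, "dir") <- out_dir
    class(manifest) <- c("rc_fixture_manifest", "data.frame")
    manifest
  })
}

#' Read a fixture manifest written by [generate_fixture()]
#' @param path Path to `manifest.json` (or the fixture directory).
#' @return The manifest data.frame.
#' @export
read_fixture_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) io_error(sprintf("File not found: '%s'", path))
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                      stringsAsFactors = FALSE)
  class(df) <- c("rc_fixture_manifest", "data.frame")
  df
}

#' Produce a corrected snapshot of a fixture
#'
#' Simulates a round of query resolution: `resolve` entries get their
#' original (valid) value back — or their event row re-added — while
#' `miscorrect` entries get a different but still-violating value. All
#' other cells are unchanged. The three project CSVs are written to
#' `out_dir`, so the snapshot can be read as a project of its own.
#'
#' @param fixture_dir Directory written by [generate_fixture()].
#' @param manifest The fixture's manifest.
#' @param resolve,miscorrect Disjoint integer index vectors into the
#'   manifest rows.
#' @param out_dir Output directory for the new snapshot.
#' @return Invisibly, `out_dir`.
#' @export
snapshot_fix <- function(fixture_dir, manifest, resolve = integer(0),
                         miscorrect = integer(0), out_dir) {
  resolve <- as.integer(resolve); miscorrect <- as.integer(miscorrect)
  if (length(intersect(resolve, miscorrect))) {
    spec_error("resolve and miscorrect must be disjoint")
  }
  idx <- c(resolve, miscorrect)
  if (length(idx) && (any(idx < 1L) || any(idx > nrow(manifest)))) {
    spec_error("entry not in manifest")
  }
  records <- read_raw_csv(file.path(fixture_dir, "records.csv"))

  locate <- function(entry) {
    which(records$record_id == entry$record_id &
            records$redcap_event_name == entry$event)
  }
  for (j in resolve) {
    entry <- as.list(manifest[j, ])
    if (entry$kind == "missing_event") {
      new_row <- records[1, , drop = FALSE]
      new_row[1, ] <- ""
      new_row$record_id <- entry$record_id
      new_row$redcap_event_name <- entry$event
      base <- which(records$record_id == entry$record_id)[1]
      if ("redcap_data_access_group" %in% names(records) && !is.na(base)) {
        new_row$redcap_data_access_group <-
          records$redcap_data_access_group[base]
      }
      if ("d_visit" %in% names(records)) new_row$d_visit <- "2020-10-01"
      if ("weight" %in% names(records)) new_row$weight <- "70"
      if ("follow_up_complete" %in% names(records)) {
        new_row$follow_up_complete <- "2"
      }
      records <- rbind(records, new_row)
    } else {
      i <- locate(entry)
      if (!length(i)) spec_error("entry not in manifest")
      records[[entry$field]][i] <- entry$original
      if (nzchar(entry$aux_field %||% "")) {
        records[[entry$aux_field]][i] <- entry$aux_value
      }
    }
  }
  for (j in miscorrect) {
    entry <- as.list(manifest[j, ])
    if (entry$kind == "missing_event") {
      spec_error("a missing event cannot be miscorrected, only resolved")
    }
    i <- locate(entry)
    if (!length(i)) spec_error("entry not in manifest")
    still_bad <- switch(entry$kind,
      missing = "999",
      out_of_range = if (identical(entry$perturbed, "999")) "998" else "999",
      calc_mismatch = as.character(suppressWarnings(
        as.numeric(entry$original)) + 2),
      "999")
    records[[entry$field]][i] <- still_bad
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_raw_csv(records, file.path(out_dir, "records.csv"))
  for (f in c("dictionary.csv", "events.csv")) {
    src <- file.path(fixture_dir, f)
    if (file.exists(src)) file.copy(src, file.path(out_dir, f),
                                    overwrite = TRUE)
  }
  invisible(out_dir)
}
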