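# redcapqc

Data management and quality control for REDCap exports, in R.

## The problem

REDCap is the de-facto electronic data capture system for clinical and
epidemiological studies. Its raw exports are not analysis-ready: category
codes instead of labels, one 0/1 column per checkbox option, server-stored
calculated fields that may have drifted from their formulas, branching
logic written in REDCap's own expression language, and — in longitudinal
projects — silently missing rows for events with no collected data.
Before any statistical analysis, a data manager has to turn those exports
into a clean dataset and raise *queries* (documented discrepancies:
missing values, out-of-range values, missing visits) with the collecting
sites, then track which queries get resolved between export rounds.

`redcapqc` automates that workflow for the three standard export files:
the records CSV, the data dictionary (metadata) CSV and the
"Designate Instruments for My Events" event-form mapping CSV.

## What is inside

* **Expression engine** — a tokenizer, recursive-descent parser,
  translator and evaluator for REDCap branching-logic / calculated-field
  expressions. Evaluation uses Kleene three-valued logic with REDCap's
  blank semantics: arithmetic with a blank operand is blank, comparisons
  with blank are *missing* except the blank tests `[x] = ''` / `[x] <> ''`,
  `and`/`or` propagate missingness, `datediff` uses REDCap's
  `days/365.2425` (years) and `days/30.44` (months) approximations.
  Smart variables other than `[event-name]` are detected and reported as
  untranslatable rather than guessed.
* **Transformation pipeline** (`rc_transform`) — five traced steps:
  (1) recalculate every calc field and compare against the stored values
  (tolerance 1e-6 after matching the stored printed precision);
  (2) rename checkbox columns to their option labels, relabel 0/1 as
  No/Yes, and blank option values where the parent branching logic is
  missing; (3) replace category codes with labelled factors (event and
  DAG columns keep both versions); (4) translate branching logic into R
  syntax in the updated dictionary; (5) delete `*_complete` /
  `*_timestamp` columns. Optionally split the result by event or form.
* **Query engine** — `rc_query` (rule expressions state the valid
  condition; violating rows become queries with the
  Identifier/DAG/Event/Instrument/Field/Description/Query/Code layout),
  `rc_event` (missing-visit detection from the expected record-by-event
  grid), `summarize_queries`, and `rc_check`, which diffs two report
  rounds into New / Pending / Solved / Miscorrected.
* **Synthetic project generator** (`generate_fixture`, `snapshot_fix`) —
  seeded, byte-reproducible REDCap projects with planted discrepancies
  and a manifest, for testing without any real data.
* **CLI** — `inst/cli/redcapqc` with subcommands `transform`, `query`,
  `events`, `check`, `fixture`; JSON config files, exit code 2 for
  validation errors.

## Worked example

```r
library(redcapqc)

dir <- tempfile()
manifest <- generate_fixture(fixture_spec(seed = 2024), dir)

project <- read_redcap_project(file.path(dir, "records.csv"),
                               file.path(dir, "dictionary.csv"),
                               file.path(dir, "events.csv"))
rc_transform(project)
#> Transformation result
#> 1. Recalculation of calculated fields
#>    age: recalculated values do NOT match the original ones (1 mismatch)
#> 2. Checkbox transformation
#>    2 checkbox field(s) renamed to their option names; labels set to No/Yes
#>    warning: checkbox 'symptoms' has no branching logic; check whether its zeros should be missing
#> 3. Factor substitution
#>    category codes replaced by their labels; event and DAG columns keep both versions
#> 4. Branching-logic translation
#>    3 branching logic expression(s) converted to R logic in the dictionary
#> 5. Deletion of pattern variables
#>    4 variable(s) removed matching pattern(s) '_complete', '_timestamp': ...
```

Step 1 flags the single planted calc discrepancy (a stored age offset by
one year against its own `datediff` formula); step 2 warns about the one
checkbox that has no branching logic.

```r
report <- rc_query(project, c("copd", "age"), "[copd] <> ''")
report
#> Query report: 11 queries
#>  variable                           description          event
#>      copd Chronic obstructive pulmonary disease Baseline visit
#>       age                                   Age Baseline visit
#>                            query total
#>  The value should not be missing     6
#>  The value should not be missing     5
```

The broadcast missingness rule finds exactly the 6 planted blank `copd`
values and 5 blank `age` values. The first report rows:

```
  Identifier        DAG          Event    Instrument Field ... Code
1      100-8 Hospital 5 Baseline visit  Demographics   age ... 100-8-1
2     100-40 Hospital 5 Baseline visit Comorbidities  copd ... 100-40-1
```

Missing events and a second round:

```r
rc_event(project)
#> Query report: 3 queries   (3 records lack the follow-up visit)

snapshot_fix(dir, manifest, resolve = which(manifest$kind == "missing")[1:4],
             out_dir = dir2 <- tempfile())
project2 <- read_redcap_project(file.path(dir2, "records.csv"),
                                file.path(dir2, "dictionary.csv"),
                                file.path(dir2, "events.csv"))
rc_check(report, rc_query(project2, c("copd", "age"), "[copd] <> ''"))
#> Query report comparison: 11 queries
#>  modification total
#>           New     0
#>       Pending     7
#>  Miscorrected     0
#>        Solved     4
```

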