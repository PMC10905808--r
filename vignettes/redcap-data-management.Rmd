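---
title: "From raw REDCap exports to quality-checked data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw REDCap exports to quality-checked data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redcapqc)
```

## Scope and model

`redcapqc` treats a REDCap project as the triplet a data manager can
export without server privileges: the records CSV (raw coded values, one
row per record and event), the data dictionary (field metadata, choices,
calculations, branching logic, validation), and — for longitudinal
projects — the event-form mapping. Everything downstream is a pure
function of these three files; live API import is a documented stub
(`read_redcap_api`), because a token grants back-door access to the full
dataset and the computation itself never needs it.

Missingness is modelled exactly as REDCap exports it: an empty cell is
the missing value, while the literal string `"NA"` is data. This matters
for free-text fields, where destroying a genuine "NA" answer would be a
silent data loss.

## The expression language

Branching logic and calculated fields share one expression language. The
engine implements it in three layers:

* **Tokenizer**: `[name]` (field), `[name(code)]` (checkbox option),
  bracketed hyphenated names (`[event-name]`) as smart variables, single-
  or double-quoted strings, numbers, operators. Token offsets are
  0-based; concatenating tokens reproduces the source.
* **Parser**: recursive descent with precedence
  `or < and < not < comparisons < + - < * / < unary minus < ^`.
  Comparisons are non-associative (`a = b = c` is rejected with a
  position), `^` is right-associative, and `-x^2` parses as `-(x^2)`;
  anything subtler must be parenthesized.
* **Evaluator**: three-valued (Kleene) logic over a tagged scalar model
  {blank, number, string, truth value}. The rules with teeth:
  * arithmetic with a blank operand is blank; division by zero is blank
    *plus a recorded note*, never an error — a single bad row must not
    abort a 10,000-row recalculation;
  * comparisons with a blank operand are *missing*, except the syntactic
    blank tests `[x] = ''` (true iff blank) and `[x] <> ''`. The
    exception is syntactic on purpose: `[a] = [b]` with both blank stays
    missing, matching REDCap;
  * `=`/`<>` compare numerically when both sides parse as numbers
    (`"5" = '5.0'` is true), else as exact case-sensitive strings;
  * a bare checkbox reference in a truth position means `= '1'`, because
    checkbox options export as 0/1;
  * `datediff(d1, d2, unit, signed?)` uses REDCap's documented
    approximations — years as `days / 365.2425`, months as
    `days / 30.44` — and is unsigned (absolute) by default, with the
    sign convention `d2 - d1` when signed. These constants reproduce the
    values the server stored, which is the whole point of recalculation.

The supported function set is `if`, `datediff`, `round` (half away from
zero, as REDCap rounds), `roundup`, `rounddown`, `abs`, `sqrt`, `min`,
`max`, `sum`, `mean`; aggregate functions ignore blanks. Smart
variables: only `[event-name]` is resolved (from the current row).
Everything else — `[previous-event-name]`, `[record-dag-name]`, … — is
*detected and reported* as untranslatable with a warning naming it. An
engine that guessed at context-dependent server state would produce
confidently wrong recalculations; reporting is the safer failure mode.

The evaluator is verified against an independent brute-force interpreter
that enumerates the Kleene truth tables directly, on ≥ 1000 random
(expression, context) pairs per test run, and the renderer satisfies
`parse(render(ast)) = ast` on generated ASTs.

## The transformation pipeline

`rc_transform` runs five steps in a fixed order, each appended to a
machine-readable trace:

1. **Recalculation** of every calc field, restricted (when the event map
   is present) to events whose forms include the field. A field is
   "identical" or "not identical"; comparison rounds the recalculated
   number to the stored value's printed decimal places and allows 1e-6 —
   REDCap displays rounded results, so bit-exact comparison would cry
   wolf. Blank-vs-blank matches.
2. **Checkbox transformation**: `field___code` columns are renamed to
   sanitized option labels (lowercase, non-alphanumerics to `_`,
   collisions uniquified with `_2`, `_3`, …), values relabelled No/Yes.
   When the parent field has branching logic, rows where that logic
   evaluates to *missing* get missing option values (REDCap exports 0
   there, which overstates knowledge). The stricter "missing-or-false"
   policy is available behind `checkbox_na_policy`; the default follows
   the narrower missing-only behaviour. Checkboxes *without* branching
   logic are listed in the trace for review. The dictionary is updated
   by expanding each checkbox into one No/Yes field per option.
3. **Factor substitution** for radio/dropdown/yesno/truefalse fields,
   preserving choice order as level order. Unknown codes are kept
   verbatim with a warning, never dropped. `redcap_event_name` and
   `redcap_data_access_group` keep the raw column and gain a `_label`
   companion. Already-labelled input (no raw codes present, labels
   present) is rejected rather than re-mapped — re-running the pipeline
   on its own output should fail loudly, not corrupt.
4. **Branching-logic translation**: every translatable expression in the
   dictionary is rewritten in R syntax (`=`→`==`, `and`→`&`,
   `[x(2)]`→ the renamed option column); untranslatable ones are traced.
5. **Pattern deletion** of `*_complete` / `*_timestamp` columns. Matching
   is *suffix-anchored* by default — the literal "contains" reading would
   delete a legitimate field called `complete_response` — with
   `delete_mode = "substring"` as the documented switch.

The order is deliberate: recalculation runs before checkbox renaming so
calc expressions referencing `[field(code)]` still resolve against the
raw `field___code` columns. Steps 1–4 never change the row count; step 5
only drops columns.

`final_format = "by_event"` nests the result into one table per mapped
event, each restricted to the columns of that event's forms plus
reserved columns; `"by_form"` makes one table per form, keeping rows with
at least one non-missing value in the form's own columns (the row rule
for the by-form case is not pinned down by the upstream description;
any-non-missing is this package's documented choice).

## Queries and their lifecycle

A rule states the **valid** condition (`"[age] >= 18 and [age] <= 100"`,
missingness as `"[copd] <> ''"`); rows where it evaluates to false *or
missing* raise queries. `negate = TRUE` inverts the direction. One
expression may be broadcast over several variables; in that case a rule
referencing a single field follows each variable (`"[copd] <> ''"`
applied to `age` checks `[age]`). Variables are checked only on the
events that collect their form, resolved from the event map, so users
never list events by hand.

Report rows follow the standard layout — Identifier, DAG, Event,
Instrument, Field, Description, Query, Code — with codes
`<identifier>-<ordinal>`, ordinals consecutive per identifier in
(event, dictionary field) order. `rc_event` raises "The event is
missing" queries from the expected record × event grid; since the export
carries no arm column, every record is expected at every requested
event, and a legitimate absence (death before follow-up) is a query to
raise and resolve, not to suppress.

`rc_check` matches queries across rounds on
**(identifier, event, field, rule)**, where *rule* is a value-free
should-form restatement ("The value should not be missing"). Using the
printed query text — which embeds the offending value — would make the
Miscorrected category unreachable, and using the code's ordinal would
break as earlier queries resolve and later ordinals shift. Categories:
both rounds + unchanged snapshot value → `Pending`; both + changed value
→ `Miscorrected`; only new → `New`; only old → `Solved`. The four
categories partition the key-union by construction, and the partition
law is property-tested over random snapshot pairs. Snapshot values are
internal (not printed); reports re-read from CSV lose them, and such
pairs degrade gracefully to Pending.

## The synthetic world

`generate_fixture` emulates the structure of a multicenter longitudinal
cohort: 20 records across three hospital DAGs; a baseline event carrying
a Demographics form (birth/admission dates, an age calc defined as
`rounddown(datediff([d_birth],[d_admission],'y'),0)`, sex) and a
Comorbidities form (a yes/no gate, a branching-controlled comorbidity
checkbox, a COPD field); and a follow-up event (visit date, weight, and
a checkbox deliberately lacking branching logic). Stored calc values are
computed by the package's own engine and then perturbed, so an
unperturbed project recalculates cleanly by construction.

Default plantings — 6 missing COPD values, 5 missing ages (the birth
date is blanked with the age so the stored calc stays self-consistent),
1 calc mismatch (+1 year), 3 dropped follow-up events — mirror the
worked-example scale of the upstream description. The RNG is pinned
(Mersenne-Twister, inversion, rejection sampling), so a seed determines
the output bytes on any platform. What the generator does **not**
emulate: realistic clinical distributions, survey timestamps, repeating
instruments, multi-arm designs. A green test therefore establishes the
pipeline's logic on well-formed exports with known defects, not
robustness to every REDCap project shape in the wild.

## Numerical and degenerate-input choices

* Recalculation tolerance: 1e-6 after rounding to stored precision (see
  above); stored non-numeric calc values compare as strings.
* Ordered comparisons between non-numeric strings are lexicographic;
  ISO (`Y-M-D`) dates therefore order correctly, other date formats do
  not — range rules on non-ISO dates should use `datediff`.
* Date parsing is validation-aware (a field's declared `date_dmy` format
  is tried first), then falls back through common formats; an
  unparseable date in `datediff` yields blank plus a note.
* Empty expression, unterminated bracket/string, unknown function,
  dangling operator: parse errors with 0-based offsets.
* Checkbox fields whose own names contain `___` are rejected at read
  time; the three-underscore separator must stay unambiguous.
* Row numbers in reader error messages are 1-based over data rows
  (header excluded).

## Known limitations

Only `[event-name]` among smart variables; no `stdev`, action tags or
`@CALCTEXT`; repeating instruments are read and preserved but each
(record, event, instance) row is treated independently; DAGs do not
filter query generation; xlsx report output needs the optional
`openxlsx` package (CSV is the tested path). These are deliberate
boundaries, each surfaced as an explicit warning or error rather than a
silent approximation.
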