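---
title: "Field-book sessions: the data model, traversal engine and exchange formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-book sessions: the data model, traversal engine and exchange formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocapture)
```

## The problem

Manual phenotyping of field and greenhouse trials — still the workhorse
of genebank characterization and breeding research — produces one value
per (plant, trait) cell, collected while walking the trial. The
bottleneck is rarely the scoring itself but the bookkeeping around it:
keeping position in the field, skipping traits that are not scored on a
given date, finding the cells still missing after repeated passes, and
getting the records into a spreadsheet or LIMS without transcription
errors. `phenocapture` models this workflow as an explicit, scriptable
session object (a *field book*) with a small, fully specified exchange
format on either side.

## The data model

A field book couples four pieces of state:

* an ordered table of **locations**, each either grid-keyed
  (`plot`, `row`, `plant` all non-empty after trimming) or
  accession-keyed (`accession name` non-empty). These are the only
  obligatory columns; eight further passport columns are carried for
  orientation and copied verbatim to the output, including the
  `database-key` column that is hidden from all listings but preserved
  for database synchronization. Grid triples must be unique.
* a table of **descriptors** with the five sheet fields
  (shortcut, description, type, values, remark) and a partial-selection
  flag. Type-1 descriptors own a parsed rating scale; type-2 remarks
  conventionally hold the unit.
* a sparse **observation matrix** keyed by (location index, descriptor
  shortcut), with typed payloads per trait type.
* a **cursor** (location, descriptor, row walking direction) plus the
  session options (`zigzag`, `multiple_selection`, `bbch_question`,
  `zigzag_carry`, `strict_rating`).

### The five trait types and their value language

`validate_value()` is total: every input yields either a typed
observation or a classed validation error, never a crash, and a failed
`record()` leaves the book untouched.

| type | meaning | accepted input |
|------|---------|----------------|
| 1 | rating | a scale code; several codes joined with `","` when multiple selection is active |
| 2 | measured value | decimal, `"."` separator only |
| 3 | date | ISO-8601 `YYYY-MM-DD` (or a `Date`) |
| 4 | text | anything |
| 5 | BBCH | `species:code`, or a bare two-digit code resolved through the sticky entry context |

The rating-scale grammar splits the values column on `";"`, each entry
on its *first* `":"`, and trims — exactly the shape of the conventional
`1: none; 3: little; 5: medium; 7: strong; 9: very strong` severity
scale. Codes are arbitrary tokens (letter-coded morphological scales
are common), with two deliberate restrictions: codes are unique within
a scale and may not contain `","`, which is reserved as the
multi-value separator in output files. For the same reason the decimal
separator of measured values is `"."` only — `"12,5"` would be
ambiguous with a value list.

Two contract points were genuinely open and decided here:

* A type-1 value outside the descriptor's scale is **rejected** by
  default. Silent acceptance would defeat the purpose of a declared
  scale; the `strict_rating = FALSE` option stores such codes as-is for
  salvage work on legacy files.
* The values column of type-2/3/4 descriptors is ignored rather than
  validated; files in the wild often leave stray content there.

## BBCH scales

A BBCH scale is a strict three-level hierarchy: species → principal
growth stage (one digit 0–9) → specific growth stage (two digits whose
first digit names the parent). Codes are stored as zero-padded
two-digit text, never integers (`"07"`, not `7`), and anything that is
not exactly two digits — including three-digit mezzo stages — is
rejected. Scales live in a registry; validation of a type-5 value is
simply membership of the code in the species' scale.

Template workbooks follow the layout of the established import path:
the first sheet is named after the species and lists the principal
stages (code, title, optional image name); every further sheet holds
the specific stages of one principal stage. Sheets bind to principal
stages in order, except that a sheet named with a single digit binds to
that stage explicitly — this makes templates robust to sheet
reordering, and the exporter always writes digit-named sheets, which is
why `import_bbch_template()` ∘ `export_bbch_template()` is the
identity. Principal stages without an image entry are associated with
sibling files whose stem matches the stage title case-insensitively.
Imported template files are moved to a `processed/` subfolder rather
than deleted: a library should not destroy its inputs.

During phenology scoring, `bbch_sticky_context()` copies species and
principal stage forward from the previous entry so only the specific
stage needs selecting at each plant; recording a BBCH value updates the
context. With the `bbch_question` option, opening a session offers to
append a dated type-5 descriptor `BBCH_<date>` — one column per
calendar date, so a season of repeated phenology passes accumulates one
column per scoring day.

The bundled registry ships scales for the seven crops a field scorer
expects to find (apple, cereals, grapevine, maize, potato, rapeseed,
rice). These are *synthetic structural fixtures* — ten principal
stages with nine specific stages each — not transcriptions of the
official BBCH monograph; they exercise the three-level structure and
are replaced by importing real templates.

## Traversal

Canonical order sorts by plot, then row, then plant. Label comparison
is numeric-aware: labels that are pure digit strings compare
numerically among themselves (plant `"2"` walks before `"10"`) and sort
before non-numeric labels, which compare lexicographically. This
matters because plot/row/plant are usually, but not reliably, numbers.
Accession-keyed records have no grid position; they are appended after
all grid records in input order and treated as one pseudo-row.

**Zigzag (serpentine) mode** keeps the row order but alternates the
plant direction of consecutive rows, so the scorer enters each new row
from the near end and counts backwards. Three boundary decisions:

* The alternation **resets to forward at each plot's first row**. The
  walking geometry within a plot is what serpentine traversal
  optimizes; across plots the scorer relocates anyway. The
  `zigzag_carry` option carries the alternation over for trials where
  plots are physically contiguous.
* Ragged rows are traversed by actual membership, not a padded
  rectangle — real trials lose plants.
* Directional jumps (`up`/`down` within a row, `left`/`right` to the
  adjacent row at the same plant position) **clamp** at boundaries
  rather than wrapping, mirroring physical walking; a jump into a
  shorter row lands on the nearest existing plant.

`advance()` moves descriptor-first: the next *selected* descriptor at
the current location, then the first selected descriptor of the next
location in the active plan, ending in an explicit absorbing end state.
`first_empty()` scans selected descriptors only, forward from the
current cursor in plan order, wrapping once — the feature exists for
repeated scoring over time, which is exactly when partial selection is
active, so unselected descriptors are not "missing". Both properties
are enforced by tests against independently coded oracles (a
brute-force serpentine enumeration; a linear scan over the rotated cell
list).

## Exchange formats and numerical choices

The input workbook has the locations sheet first and the traits sheet
second; sheets named `Locations`/`Traits` override position. The first
row of each sheet is a header and is never parsed as data; unexpected
header strings produce a warning, not an error, because the canonical
header wording is conventional rather than normative. A merged
"accession name and number" column is accepted on read (the value is
kept as the name). Fully empty rows are skipped silently. Invalid
location rows are excluded and reported with their sheet row numbers;
unknown trait-type codes and duplicate shortcuts abort the import —
silently dropping a descriptor column would corrupt downstream LIMS
ingestion.

The output table is one row per location in field-book order: the
eleven location columns verbatim, two remarks columns (`location info`,
`plant note` — two distinct columns, never concatenated), then one
column per descriptor. Excel output stores dates as native date cells
and measured values as number cells; CSV stores ISO-8601 dates, with
the common dialect (comma, double-quote quoting, UTF-8). BBCH cells
are written fully qualified as `species:code`: mixed-species books are
legal, and the lossless round-trip guarantee requires the species to
survive the export. `read_output()` re-validates every non-empty cell;
failures are reported with their raw values, never silently dropped.

Because no spreadsheet *writer* is among the package's dependencies,
the package includes a minimal OOXML writer (`write_xlsx_minimal()`):
inline strings, number cells, and date-styled cells, zipped with fixed
member timestamps so identical content yields identical bytes. Dates
use the 1900 date system (serial days since 1899-12-30). The writer is
deliberately narrow — no shared strings, styling or formulas — and its
output is verified through an independent reader (readxl) in the test
suite.

## Sessions, the CLI, and replayability

Session state persists as a versioned JSON file: locations,
descriptors (with raw scale definitions, re-parsed on load),
serialized observations, remarks, cursor, options, the BBCH registry
and the audit log. A schema-version mismatch refuses to load. The CLI
is a thin layer over the engine; every state-changing command appends
its argv (one JSON array per line) to a log next to the session file,
and `cli_replay()` rebuilds a byte-identical session from that log —
all engine operations are deterministic, and commands with hidden time
dependence (`init --bbch-question`) accept an explicit date for exactly
this reason. Exit codes separate validation failures (2) from I/O
failures (3).

## The fixture generator, and what passing tests do not show

`make_input_workbook()`, `make_bbch_template()` and `make_session()`
produce synthetic trials: a full plot/row/plant grid with passport
fields drawn from a small accession-name pool, one descriptor set
covering the requested trait types (type-1 descriptors carry the
standard 1/3/5/7/9 severity scale), and sessions with exactly
`round(fill_fraction × cells)` valid observations. All content derives
from the spec's seed, so identical specs yield byte-identical files.

The generator emulates the *structure* of real trial data, not its
statistics: trait values are uniform draws, there is no genetic or
spatial structure, no measurement error model, and accession names are
decorative. Passing the round-trip and traversal suites therefore
demonstrates format and engine correctness — that no value, key or
passport field is altered or lost between entry and export, and that
traversal follows the declared geometry — but says nothing about the
biological plausibility of recorded values. That is by design: the
package's contract is faithful capture and exchange, not simulation.

## Problem sizes used in the checks

The shipped verification suites use: 200 fuzzed field books for the
round-trip property (mostly 1–3 plots × 1–3 rows × 1–4 plants with up
to ten descriptors, plus three 5×5×5 books and one 10×10×10 book with
20 descriptors — the contract's upper bound); 500 fuzzed, possibly
ragged grids up to 5×6×10 for the serpentine oracle; 100 single-hole
placements for first-empty; 25 fuzzed scales with all 100 two-digit
codes enumerated for BBCH validation; and a 51-command scripted CLI
session for replay determinism. These sizes exercise every boundary
(single-cell books, single-row plots, ragged rows, empty and full
matrices) while keeping the full suite fast enough to run on every
change.

## Known limitations

* No streaming: workbooks are read whole; very large trials (tens of
  thousands of plants) will be slow through the xlsx path (CSV is
  considerably faster).
* The bundled BBCH scales are structural fixtures, not the official
  code lists; real scales must be imported from templates.
* No ontology mapping (Crop Ontology / AGROVOC), no multi-user
  conflict resolution, no GPS or route optimization, and no camera
  integration — photo *names* are generated, files are not.
* Formula cells, styling and shared strings in input workbooks are
  ignored; only cell values are read.
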