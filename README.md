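# phenocapture

Scriptable field-book sessions for manual plant phenotyping.

Genebank characterization and breeding-research trials are still scored
largely by hand: a scorer walks a field plot by plot and row by row,
recording one value per plant and trait. `phenocapture` models that
workflow as a *field book* you can create, drive and export from R or
the shell, without a GUI:

* **Locations** — an ordered list of plant positions keyed by
  `plot / row / plant` (or, alternatively, by accession name), carrying
  genebank passport metadata (accession number, pedigree, a hidden
  `database-key` passed through verbatim for LIMS synchronization).
* **Trait descriptors** in five formats, keyed by a `type` code 1–5:
  **1 rating** (categorical, with a scale defined as
  `1: none; 3: little; 5: medium; 7: strong; 9: very strong`),
  **2 measured value** (decimal, unit in the remark),
  **3 date**, **4 free text**, and **5 BBCH** phenology codes.
* **BBCH growth-stage scales** — the standard two-digit phenology
  coding: species → principal stage (digit 0–9) → specific stage
  (two digits whose first digit is the parent). Scales live in a
  registry and can be added from Excel template workbooks; during
  scoring, species and principal stage stick from entry to entry so
  only the specific stage changes.
* **Navigation** the way a scorer walks: auto-advance through the
  selected descriptors of a location and on to the next location;
  optional serpentine ("zigzag") row order that enters every second row
  from the far end; a first-empty search for tracking missing data
  points over repeated scoring dates; arrow-key jumps within and
  between rows; partial descriptor selection.
* **Exchange formats** — the two-sheet input workbook
  (`Locations` + `Traits`, `.xlsx`/`.xls` or a CSV pair) and the flat
  output table (all location columns verbatim, two remarks columns, one
  column per descriptor), written as `.xlsx` (native date cells) or CSV
  (ISO-8601 dates). Exports round-trip losslessly back into a session.
* A **deterministic fixture generator** for synthetic layouts,
  descriptor sets, BBCH templates and partially filled sessions.

## Worked example

```r
library(phenocapture)

# a synthetic trial: 2 plots x 1 row x 3 plants, one descriptor per type
make_input_workbook(fixture_spec(plots = 2, rows_per_plot = 1,
                                 plants_per_row = 3), "vineyard.xlsx")
book <- read_input("vineyard.xlsx")
book$cursor          # 1 1 1 | RAT1  -- plot 1, row 1, plant 1, first trait

book <- record(book, "7")      # rating "strong"; cursor auto-advances
book <- record(book, "12.5")   # measured value at the same plant
write_output(book, "results.csv", format = "csv")
```

The same session from the shell (the `phenocapture` script under
`inst/cli/`, or `cli_main()` directly):

```
$ phenocapture init vineyard.xlsx --session s.json
session: 6 locations, 5 descriptors (0 invalid row(s) skipped)
cursor: 1 1 1 | RAT1
$ phenocapture record --value 7 --session s.json
recorded
cursor: 1 1 1 | MV1
$ phenocapture record --value 12.5 --session s.json
recorded
cursor: 1 1 1 | DT1
$ phenocapture status --session s.json
6 locations, 5 descriptors (5 selected), 2 / 30 cells recorded
cursor: 1 1 1 | DT1
$ phenocapture export --format csv --out results.csv --session s.json
exported results.csv
```

The cursor line reads `plot row plant | descriptor`: after recording the
rating the session asks for the next descriptor (`MV1`) at the same
plant; `2 / 30 cells` means two of 6 locations × 5 descriptors are
scored. The first rows of `results.csv`:

```
plot,row,plant,accession name,accession number,variety number,genotype,mother,father,information,database-key,location info,plant note,RAT1,MV1,DT1,TXT1,BBCH1
1,1,1,Riesling,ACC18753,V5273,G-074,Regent,Kerner,border plant,DBK046208,,,7,12.5,,,
```

Every CLI command appends to a plain-text audit log next to the session
file; `cli_replay()` rebuilds an identical session from it.

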