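# bidsforge

Rule-based, headless conversion of source neuroimaging data into a
[BIDS](https://bids.neuroimaging.io/) (Brain Imaging Data Structure) tree.

Neuroimaging researchers who want to share or standardize their data must
reorganize scanner exports — subject folders full of acquisition series —
into the BIDS layout of prescribed folder names, file names
(`sub-001_task-Reward_acq-mb8_run-1_bold.nii.gz`), and JSON sidecar
metadata. bidsforge automates this for anyone who can recognize their own
scans but does not want to write conversion code: the mapping from source
data types to BIDS output is *data*, not a program.

## How it works

All rules live in a **bidsmap**, a YAML document. One **run-item** maps one
source data type to one output:

* input filters — regular expressions over four file **properties**
  (`filepath`, `filename`, `filesize`, `nrfiles`) and any header
  **attributes** (`ProtocolName`, `EchoNumber`, ...). A pattern must match
  the *entire* extracted value; an empty pattern imposes no constraint. A
  file matches a run-item only if every non-empty filter matches.
* output naming — a **bids** dictionary of entity labels plus a suffix,
  composed in schema order and validated against an embedded BIDS schema
  snapshot, and a **meta** dictionary merged into the JSON sidecar.

The workflow has two stages:

1. **Mapping** (`run_bidsmapper()`): a generic *template* bidsmap with
   broad filters (e.g. `ProtocolName: (?i).*(mprage|t1w).*` → anatomical
   T1w) is matched, in document order with first-match precedence, against
   one representative file per acquisition series. Each template match is
   *narrowed*: its patterns are replaced by the literal header values of
   the matched file, and the narrowed rule is appended to the *study*
   bidsmap unless an equivalent one is already there. The study map is the
   de-duplicated shortlist of everything acquired in the study; you edit
   it (programmatically, `edit_run_items()`) once, however many subjects
   arrive later.
2. **Coining** (`run_bidscoiner()`): every session is converted per the
   study map — ignored types (localizers) are dropped, names are composed
   and validated, sidecars merged, the participants table and dataset
   scaffolding written.

Values in a bidsmap may be **dynamic**: `<key>` resolves at mapping time,
`<<key>>` at coining time, and `<<key:regex>>` extracts a substring — e.g.
`<<filepath:/sub-(.*?)/>>` pulls subject label `003` out of
`/data/raw/sub-003/ses-01`. A dynamic run index `run-<<1>>` auto-increments
past existing output, and fieldmap `IntendedFor` lists resolve shell-style
wildcards (`<<Stop*Go><Reward>>`) against the files already coined.

Source formats are accessed through a five-function plugin contract
(`test`, `is_sourcefile`, `get_attribute`, `bidsmapper_plugin`,
`bidscoiner_plugin`). The built-in plugin reads a plain-text "toy scan"
format, and `generate_raw_dataset()` emits a deterministic synthetic study
in it — eleven series per subject including localizers, an MPRAGE T1w,
single-band-reference + bold pairs (one multi-echo), and two fieldmap
pairs — so the entire workflow is testable without imaging data.

## Worked example

```r
library(bidsforge)

raw  <- file.path(tempdir(), "raw")
bids <- file.path(tempdir(), "bids")
generate_raw_dataset(raw, n_subjects = 1, seed = 0)

study <- run_bidsmapper(raw, bids, quiet = TRUE)
study
#> <bidsmap> version 0.1.0
#>   Toy: 11 run-item(s) [exclude 2, anat 1, func 4, fmap 4, dwi 0, extra_data 0]

study <- example_study_edits(study)   # task/acq labels, IntendedFor, no session
save_bidsmap(study, study_bidsmap_path(bids))

run_bidscoiner(raw, bids, quiet = TRUE)
#> <conversion_report> 1 subject(s): 1 processed, 0 skipped, 0 failed; 11 file(s) written
```

The 11 run-items are the study's unique data types: the two localizers
(excluded), the T1w, a single-band-reference + bold rule per functional
resolution, and magnitude/phasediff rules per fieldmap pair. Coining the
13 sample groups (the multi-echo bold contributes three) writes 11 imaging
files — localizers are dropped, the three echoes become
`..._run-1_echo-1..3_bold` — each with a JSON sidecar; the fieldmap
sidecars carry `IntendedFor` lists that name the functional files on disk.
Re-running converts nothing (subjects with output are skipped) until new
data arrives or `force = TRUE`.

The same workflow is available from a shell via the bundled executable
(`inst/exec/bidsforge`): `bidsforge map raw bids`, `bidsforge coin raw
bids`, plus `validate`, `inspect`, and `fixture` subcommands.

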