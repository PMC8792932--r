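---
title: "Rule-based source-to-BIDS conversion: the model behind bidsforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based source-to-BIDS conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidsforge)
```

## The mapping model

bidsforge converts source neuroimaging data to BIDS with a *mapping*
strategy rather than programmatic logic: every decision — which files
belong to which data type, what the output is called, what goes into the
sidecar — is held in a YAML rule document, the *bidsmap*. The engine makes
three assumptions:

1. The source tree is minimally organized as `subject[/session]` folders
   (configurable prefixes). Within a session, files may sit in per-series
   subfolders or flat in one folder; series membership comes from header
   attributes, not folder structure.
2. One representative file per acquisition group is sufficient to identify
   the group's data type. Groups are keyed by
   `(SeriesNumber, EchoNumber-or-empty)` — multi-echo series split into
   per-echo groups, mirroring converters that write per-echo outputs — and
   the representative is the lexicographically first file, which makes
   discovery deterministic and order-independent.
3. Data types are separable by regular expressions over file properties
   (`filepath`, `filename`, `filesize`, `nrfiles`) and header attributes.
   If a study's types are not separable this way, the rule list degenerates
   toward one rule per acquisition, which still works but is labor to edit.

### Matching semantics

A pattern must match the **entire** extracted value (`match_value()`
anchors as `^(?:pattern)$`), not merely occur in it. This is what makes
narrowing sound: when a template rule like
`ProtocolName: (?i).*(mprage|t1w).*` matches a file, the study map stores
the *literal* header value (`t1_mprage_sag_ipat2_1p0iso`) in its place, and
under full-match semantics that literal behaves as an exact matcher.
Narrowed literals are stored raw, not regex-escaped — faithful to how the
rule files read — with the documented caveat that a literal metacharacter
such as `.` still acts as regex when re-matched; for scanner-style protocol
names this is benign (a `.` matches itself).

Within a data-format section, rules are tried in strict document order
across datatypes and the first match wins. Templates therefore place
`exclude` rules first and the all-empty catch-all (`extra_data`) last.
The engine's scan is property-tested against an independent brute-force
first-match oracle on randomized trees and rule documents.

Run-item *identity* — what "already present in the study map" means —
covers the input side only: format, datatype, properties, attributes.
Provenance and the user-editable output dictionaries are excluded, so
editing a task label can never cause the same acquisition to be re-learned
as a new type. Whether property patterns should join the identity was an
open design point; they are included, since two rules differing only in a
filename filter do describe different source types. Empty patterns carry
no constraint and are excluded from identity.

### Dynamic values

Bidsmap values may embed `<key>` (resolved at mapping time, while
narrowing) or `<<key>>` (kept verbatim until coining). A `:regex` appended
to the key extracts a substring: the first match anywhere in the value;
with capture groups, the concatenation of the groups (multi-group
concatenation is this package's choice; a single group is the common
case). Keys are looked up among the four file properties first, then the
header attributes — properties shadow attributes on a (rare) name
collision, a rule that must simply be fixed one way. Results used as BIDS
entity or subject/session labels are sanitized to alphanumerics
(`t1_mprage_sag_p2_iso_1.0` → `t1mpragesagp2iso10`); sidecar (meta) values
keep raw text, since free-text fields like patient comments must survive
verbatim. An appended pattern that matches with an empty capture yields
empty text plus a logged warning.

Two cases are not key lookups. A pure-number seed `run-<<1>>` is the run
index: at coining time it increments from the seed until no output file
with that index exists in the target folder. And an `IntendedFor` meta
value holds `><`-separated shell wildcards, each wrapped as `*pattern*`
and glob-matched against the imaging files already written under the
subject (or subject/session) folder; matches are recorded relative to the
subject folder. Fieldmaps are coined after the other datatypes of a
session precisely so these lookups see final names — the ordering is this
package's choice, as is the subject-relative base (the classic sidecar
convention).

### Validation

Output names are validated against an embedded schema snapshot (BIDS 1.6
imaging subset: anat, func, fmap, dwi — entity order, allowed suffixes and
entities, required entities such as func's `task`, default `.nii.gz`
extension). The snapshot is a shipped YAML table users can extend; no
network fetch, so builds are hermetic. `validate_run()` returns the list
of problems that would render a previewed name "red": a missing required
entity, an entity or suffix foreign to the datatype, non-alphanumeric
label text, unbalanced brackets, or an unresolved mapping-time dynamic.
One nuance: a *template* legitimately contains mapping-time dynamics (they
resolve during narrowing), so validation takes a `template` flag under
which those are not flagged; study maps are validated strictly, and the
coiner refuses to start while any non-ignored run-item is red. Rules under
`exclude` (never converted) and `extra_data` (converted BIDS-like and
listed in `.bidsignore`) are always green — there is nothing BIDS requires
of them.

A candidate-list bids value (used where BIDS restricts a label to a fixed
set, e.g. `part`) serializes as a YAML list whose final element is the
1-based index of the active candidate, with an empty first candidate
meaning "omitted"; this keeps drop-down semantics editable in a plain
file. The 1-based base is the R convention.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `subprefix`, `sesprefix` | Options | `sub-`, `ses-` | how subject/session folders are recognized in the raw tree; `""` matches any folder |
| `datatypes` | Options | anat, func, fmap, dwi | converted to BIDS proper |
| `unknowntypes` | Options | extra_data | converted BIDS-like, added to `.bidsignore` |
| `ignoretypes` | Options | exclude | not converted at all (localizers, scouts) |
| `bidsignore` | Options | `extra_data/` | semicolon-separated extra `.bidsignore` lines |
| plugin `anon` | Options/plugins | `'y'` | rounds age down to whole years and discards the acquisition date in sidecars and the participants table |
| plugin `command`, `args` | Options/plugins | `''` | for plugins wrapping an external converter binary; `test_plugin()` checks the command resolves |

The three datatype classes must be pairwise disjoint, and every
unknowntype folder appears in `.bidsignore`.

## What the synthetic data emulates — and what it does not

`generate_raw_dataset()` writes, per subject, the eleven series of a
typical task-fMRI session: two localizer/scout series, an MPRAGE T1w, a
multiband single-band-reference + bold pair, a multi-echo pair (three
echoes), and two fieldmap magnitude/phasediff pairs, one per functional
resolution (series numbers 1, 2, 7, 47–50, 59–62, gaps as a scanner would
leave them). Headers carry the attributes the engine reads (protocol,
series/echo numbers, echo times, patient name/comments, sex, age,
acquisition date); payloads are seeded random text, so the same seed
reproduces a byte-identical tree. Subject 2 (when present) is written
flat — all series' files in one folder — to exercise discovery without
series subfolders. File counts per series are kept small (1–9) for test
speed; the grouping logic is count-independent.

The toy format is a plain-text stand-in with a `TOYSCAN/1` magic line,
`Key: value` header lines, and a `---`-separated payload. What passing
tests on it do **not** show: real DICOM quirks (multi-valued tags, missing
or vendor-specific attributes, transfer syntaxes), real image conversion
(outputs are payload copies under `.nii.gz` stub names, not NIfTI), DICOMDIR
or PAR/XML organizations, and scanner-induced attribute drift within a
series. Those live behind the plugin contract: a real-format plugin
supplies `is_sourcefile`/`get_attribute` and the conversion step, while the
mapping, narrowing, naming, and sidecar logic tested here is shared.

## Numerical and degenerate-input choices

* Regex dialect is the host's PCRE; templates should stay within the
  common core (alternation, classes, lazy quantifiers, inline `(?i)`).
  Invalid patterns are errors naming the pattern; empty patterns always
  match.
* Unreadable, empty, or malformed source files are skipped with logged
  warnings — discovery over a large archive must not abort.
* An absent attribute is empty text: it fails any non-empty filter, and a
  dynamic lookup of an unknown key yields empty text plus a warning.
* File sizes and counts are decimal text, paths POSIX-style with `/`,
  also on Windows.
* Logs append (full console mirror in `.log`, warnings/errors in
  `.errors`, timestamped) — so re-runs keep history; the coiner's
  skip-idempotence is therefore a property of the *data* tree, logs
  excluded.
* A forced re-run never overwrites: with a dynamic run index the new
  output lands at the next free index. Deleting stale output is left to
  the user, keeping the engine strictly additive.

## Problem sizes used in the tests

The suite runs the full workflow on the one-subject generated study
(13 sample groups → 11 run-items → 11 imaging outputs), a two-subject
variant for skip/force behavior, 200 randomized tree/rule instances for
the first-match oracle equivalence, and 20–50-instance property loops for
round-trips and invariants — chosen to exercise every code path in
seconds on one CPU while keeping the acceptance counts at their derived
values.

## Known limitations

* Not a bids-validator replacement: no NIfTI header checks, no TSV content
  rules, schema snapshot limited to the tutorial-relevant imaging subset.
* No echo combination, defacing, stimulus-logfile conversion, or
  physiological data support.
* Irregular studies (hand-typed protocol names) inflate the rule list; a
  custom plugin is the escape hatch the architecture provides.
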