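---
title: "Detecting multi-disorder basket trials in a registry export"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multi-disorder basket trials in a registry export}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialbasket)
```

## The problem

A basket trial evaluates one investigational drug (or combination) in
several disease populations inside a single protocol. In neurodegeneration,
shared pathobiology (alpha-synuclein in PD/DLB/MSA, tau in PSP/CBD/FTLD/AD)
and shared clinical syndromes (parkinsonism, orthostatic hypotension,
dementia-related psychosis) make baskets a natural design, yet they are
uncommon, and the registry gives no "basket" flag: the design has to be
inferred from free text. `trialbasket` operationalizes that inference as a
deterministic, fully testable filter cascade over registry exports.

## The procedure and its assumptions

A trial is a basket entry when, and only when:

1. its last posted update lies in the analysis window (default 2010-01-01
   to 2021-06-06, inclusive on both ends; records with no update date
   cannot be placed and are dropped, with the count logged in the
   FilterTrace);
2. it is interventional (any registry status; any phase, including none —
   registries commonly omit the phase, and absence of a label is not
   evidence of ineligibility);
3. its canonical NDD set, after stage folding, has at least two distinct
   disorders; and
4. it has at least one intervention classified as a non-placebo drug.

The output unit is the **trial–agent pair**: one trial testing carbidopa,
droxidopa and entacapone contributes three entries. This is the unit under
which per-agent trial counts are additive, and it is the unit used
consistently by the aggregation tables (the sponsor distribution counts
entries; the phase distribution counts agent–phase pairs, so an agent
spanning phases 2 and 3 appears in both buckets).

### Disease-name normalization

The vocabulary maps variant strings — full names, possessives,
abbreviations, alternate names — to ten reporting labels: AD, PD, DLB,
FTLD, PSP, CBD, CTE, HD, ALS, MSA. Matching applies one shared
normalization (lower-case, possessive-apostrophe removal, punctuation to
whitespace) and then:

- **exact** variant lookup first;
- failing that, **bounded edit distance** (Levenshtein, default threshold
  1 edit), applied only to strings of at least 8 characters. The length
  floor exists because one edit turns one short abbreviation into another
  (AD/HD/PD are pairwise distance 1); abbreviations therefore match only
  exactly, and only as standalone word tokens, never inside ordinary words
  ("advanced" must not fire AD).

**Stage folding** happens inside the vocabulary: PDD and its spellings are
variants of PD, LBD of DLB, FTD of FTLD. MCI and "PD MCI" are stage tokens
that map to nothing. Folding-before-counting is what guarantees that
AD+MCI or PD+PDD+PD-MCI trials — one disease at several severities — can
never reach set size 2 and be mistaken for baskets. The bare word
"dementia" is deliberately absent from the vocabulary: an unqualified
dementia population is not attributable to a disorder, so such trials are
excluded rather than guessed at.

### Eligibility-criteria scanning

Conditions are scanned string-by-string; eligibility text is scanned as a
sliding token n-gram window (n up to the longest variant length) over the
**inclusion portion only** — everything before an "Exclusion Criteria"
heading. Stripping the exclusion block is the minimal reproducible rule for
avoiding the obvious false positives ("Exclusion: Parkinson's disease")
without attempting clinical negation detection, which is out of scope. The
cost of the rule is that a disease mentioned only in free-form exclusion
prose without the heading would still match; the synthetic generator plants
exactly the heading-based pattern, so the tests certify the rule as stated,
not general clinical NLP.

### Intervention classification

The classifier is lexicon-based by construction, not a trained model:
curated plain-text phrase lists, one file per class (drug, behavioral,
biomarker, device, stem cell, supplement, placebo, other), matched as
whole-token subsequences of the normalized name. When several classes
match, a fixed priority resolves the tie — placebo > device > stem_cell >
biomarker > behavioral > supplement > other > drug — so that removal
classes always beat the permissive drug default ("Placebo oral tablet"
must be placebo even though "oral tablet" is a drug-form phrase, and even
when the registry declares the arm's type as "drug", as registries commonly
do). Unmatched names fall back on the registry's declared type: drug if
declared drug, otherwise other. Cross-class duplicate phrases are a
load-time error, which keeps the priority order the only source of
ambiguity resolution.

Agent names are canonicalized through a curated annotation table
(synonym codes: RVT-101 → intepirdine, TRx0237/LMT-X → LMTM, dimebon →
latrepirdine); unknown drugs pass through normalized, making
canonicalization idempotent. The same table carries each agent's dominant
MOA class (symptomatic vs disease-modifying — agents with several
mechanisms get exactly one dominant class; a tie is a load error that
forces curation) and CADRO target category from the closed 20-category
vocabulary. Symptomatic agents default to *neurotransmitter receptors*
(symptomatic treatment in these disorders acts on transmitter or receptor
function); protein-aggregation agents outside amyloid map to
*proteostasis/proteinopathies*. Agents absent from the table are reported
as **unclassified**, never silently defaulted — the bundle carries them as
a separate list.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| update window | 2010-01-01 … 2021-06-06 | dates | the retrospective analysis window; both ends inclusive |
| `fuzzy_threshold` | 1 | edits | registry misspellings are overwhelmingly single-character; 2 starts to cross disease names |
| fuzzy length floor | 8 | characters | below it, edits cross abbreviations |
| exclusion policy for trimmed means | explicit id list | ids | "extreme" trials are named, not inferred; `n_retained` and the excluded ids are reported so the choice is auditable. A percentile-band alternative exists for when no curated list is available |
| recency cutoff | 2016-06-06 | date | "last five years" relative to the window end |

## The synthetic generator

`generate_registry()` plants ground-truth baskets (agents drawn from the
annotation table; NDD sets of size 2–5) among distractors of every species
the cascade must reject: single-NDD trials, non-NDD trials (half of which
mention an NDD only inside an exclusion block), stage-variant-only trials
(AD+MCI, PD+PDD), multi-NDD trials with device/behavioral/biomarker arms
only, and trials updated before the window. Rates control placebo
co-arms (default 0.3 — declared as drugs, as registries do), NDDs visible
only in inclusion text (0.2), and misspelling injection (single-character
edits, never on strings under 8 characters). Default sizes (20 planted
baskets among ~95 distractors) keep a full cascade run well under a second
while exercising every rejection path; all randomness in the package lives
in this module, keyed to an explicit seed.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real exports: registry-scale volume (hundreds of
thousands of records), free-form eligibility prose without the standard
headings, multi-arm dose-level naming ("Drug X 10 mg"), non-English
condition names, and agents whose drug-ness is only recognizable from
pharmacological knowledge rather than declared type or lexicon. On a real
snapshot the cascade's recall depends on the curated vocabulary and
lexicons, which are packaged as replaceable resource files for exactly that
reason.

## Fixtures and what is (not) reproducible

The packaged fixture tables transcribe the curated per-agent
characteristics of the known multi-NDD basket-trial landscape: agent,
number of trials, treatment goal, and NDD list, for 25 symptomatic and 14
disease-modifying agents. `expand_fixture_tables()` emits one per-trial
record per fixture trial, each carrying the agent's **full** NDD list as
conditions, because per-trial NDD subsets are not published. Every count
that depends only on per-agent information — entry totals (41 + 18 = 59),
agent totals (25 + 14 = 39), per-NDD distinct-agent counts, the maximum
per-agent trial count — is exactly conserved under this expansion and is
asserted at face value in the tests and recomputed by
`scripts/acceptance.R`. Pairwise disease co-occurrence counts are **not**
recoverable from per-agent unions (an agent's union over-counts pairs its
individual trials never combined), so the pairwise table is validated
property-wise (symmetry; equality with a brute-force double loop on random
inputs) rather than against published values; the same applies to
per-trial dates, so recency fractions are oracle-tested on synthetic dates
only.

## Numerical and degenerate-input choices

- Dates parse as ISO-8601, then MM/DD/YYYY, then "Month D, YYYY" (the
  registry XML dialect); anything else raises rather than guesses, and
  records failing date parsing are excluded and counted, not imputed.
- Unrecognized registry statuses map to "unknown" with a warning;
  unrecognized study types to "other" (and are then excluded by the
  interventional filter).
- All outputs are sorted (entries by agent then NCT id; tables by fixed
  column order) and written with fixed quoting, so identical inputs give
  byte-identical output directories; the pipeline writes to a staging
  directory and renames only on success, so failed runs leave nothing
  partial.
- Empty inputs are first-class: an empty dataset yields an all-zero trace
  and header-only tables.
- `robust_mean()` with an empty exclusion list is exactly the arithmetic
  mean; excluding every value is an error, not NaN.

## Known limitations

- The multi-NDD decision is only as good as the vocabulary; a disorder
  spelled beyond one edit of every variant is missed. The vocabulary file
  is user-replaceable.
- Eligibility scanning has no negation or hypothetical-context handling
  beyond exclusion-block stripping.
- The lexicon classifier cannot recognize a novel drug name with no
  declared type; such interventions land in "other" and the trial may be
  missed. Conversely the annotation table decides MOA/CADRO — the package
  encodes curation, it does not re-derive it from literature.
- One curiosity of the curated landscape is preserved deliberately:
  ampreloxetine and TD-9855 appear as distinct agents (as curated), even
  though the code name refers to the same molecule; merging them would
  change the agent totals away from the curated tables.
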