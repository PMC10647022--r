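---
title: "Argument-role extraction for synthesis procedures: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Argument-role extraction for synthesis procedures: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnroles)
```

## The representation

A synthesis procedure is modelled as a set of *actions* over a text,
each action carrying a PropBank-style roleset: a verb lemma with up to
three described slots (ARG0–ARG2) plus the unnumbered modifier role
ARGM. The corpus-level assumptions baked into the schema are:

* **Synthesis part only.** Actions that transform reactants toward the
  product are `REACTION_STEP`; workup operations (washing for
  separation, purification) and instrument preparation are out of
  scope and left unannotated.
* **ARG1 everywhere, ARG2 sometimes, ARG0 almost never.** Every frame
  in the registry defines ARG1 (the patient); ARG2 exists where a
  secondary participant is systematic (destination, solvent, gas).
  ARG0 denotes the agent and is annotated only for the container frame
  `contain.01` — for every other action the agent is the experimenter
  and carries no information. `validate_document()` therefore treats
  ARG0 on any other roleset as an error.
* **One roleset per verb.** No verb in this domain needs several
  senses, so every roleset id is `<lemma>.01` and the registry loader
  rejects duplicate lemmas.
* **Parameters at first mention.** A repeated identical parameter
  ("… stirred 12 h. After 12 h, …") is annotated only once; the
  package normalizes surfaces by case and whitespace when applying
  this policy.
* **One span per entity.** Coreference labels and amounts are part of
  the entity span.

A relation label that is *absent from the head's frame* (ARG2 on
`mix.01`, whose frame is ARG1-only) is a warning, not an error: such a
link is still interpretable by consulting the roleset, and demanding
hard failure would discard recoverable annotations. The same applies to
action surfaces whose verb is not in the registry (`unresolved-lemma`):
unknown verbs never auto-create frames.

## The registry

The registry ships as a TSV
(`lemma<TAB>sense<TAB>origin_type<TAB>arg0<TAB>arg1<TAB>arg2`) so
chemists can extend it without code changes; its size is a data
property, not a constant. The packaged file carries the frames
attested in the package's own templates and tests (21 rolesets). Each
frame records an origin type: `A` (adopted from PropBank, possibly
with surface edits), `B` (slot definitions changed — `mix.01` collapses
PropBank's two ingredient slots into one ARG1, since which ingredient
is "first" is syntax, not chemistry), `C` (new frame, verb known to
PropBank) and `D` (new frame, new verb). `type_distribution()` reports
integer percentage shares of these types.

One slot assignment needed a decision the frame inventory does not
dictate: for `charge.01` the package defines ARG1 as the vessel being
charged and ARG2 as the material. In the pervasive passive pattern
*"The flask was charged with X"* the vessel is the grammatical subject,
which keeps the subject→ARG1 convention uniform across all frames.

Lemmatization is dictionary-first (noun forms like *addition*,
irregulars like *held*, *kept*), then rule-based suffix stripping
(`-ed`, `-ing`, `-(e)s`) with candidate stems (bare, undoubled final
consonant, `+e`, `i→y`) disambiguated against a lexicon of known
lemmas — by default the registry itself, so "charged" resolves to
*charge*, not *charg*. The function is idempotent and total: unknown
tokens return lowercased and are flagged downstream.

## Text processing

All offsets are 0-based and half-open (brat convention). Three
deterministic components are pinned as part of the package contract:

* **Cross-reference stripping.** `strip_note_refs()` removes
  parenthesized `(Note n)` / `(Figure n)` groups (including `and`/range
  lists) plus one preceding space, and returns a strictly increasing
  offset map from cleaned to original positions. All other parentheses
  — amounts, coreference labels — are untouched. The exact patterns
  used by the original curation are not published; the package's
  pattern covers the attested forms and is regression-tested.
* **Sentence splitting** is rule-based with a fixed abbreviation list
  (`equiv.`, `aq.`, `Fig.` …), never splitting inside decimals; a
  boundary requires a terminator, whitespace, and an upper-case/digit
  continuation. A rule-based splitter was chosen over a statistical
  one so IOB2 exports are bit-stable.
* **Tokenization** is a single documented regex keeping decimal
  numbers, ranges (`14–15`), hyphenated/slashed chemical names and
  `°C` as single tokens; every other non-space character stands alone.

## The pipeline

`run_pipeline()` mirrors a three-track NER + pairwise RE architecture:
separate taggers for actions, entities and parameters (labels may
overlap *across* tracks, never within one), whose decoded mentions are
merged by union, followed by classification of every
(action, other-mention) pair within a sentence. The tagger and
classifier are *contracts* — any model mapping sentences to IOB2 tags,
or marked instances to relation labels, can be plugged in; the package
provides a deterministic rule/lexicon baseline, and training of learned
models is deliberately outside the package.

Baseline rules worth knowing:

* The action track requires a verb context: sentence-initial
  (imperative), after an auxiliary/infinitive marker, or visibly
  inflected and not preceded by a determiner/preposition — so
  "the addition" and "with stirring" are not actions.
* The entity track is lexicon-driven (longest match first, ties to the
  leftmost start) and absorbs following parenthesized amount or
  coreference groups into the span.
* The relation rules: a parameter attaches as ARGM iff the marked
  action is the *nearest* action in the sentence; an entity preceding
  its action is ARG1 (ARG0 for the subject of *contain*); an entity
  after the action governed by to/into/in/onto/with is ARG2 when the
  frame has that slot, falling back to ARG1; a bare object is ARG1.
  The nearest-action gate is also applied to entity pairs — a baseline
  locality heuristic that matches how arguments distribute in
  single-clause procedure sentences.
* No synthesis/workup boundary detection is attempted. Sentences mixing
  both parts therefore yield spurious workup predictions (e.g.
  "washed" in a workup tail) — a known failure mode that the package
  reproduces intentionally and tests for.

## Evaluation

Precision, recall and F-score use the 0/0 → 0 convention (relevant for
empty label rows). Exact match requires identical span sets and label.
Relaxed match requires at least one character of overlap and the same
label. Published definitions of "partial match" do not specify the
assignment discipline, so the package pins **one-to-one greedy
matching in order of predicted start offset**, each prediction taking
the earliest-starting unmatched overlapping gold mention; a
many-to-one reading is available behind `one_to_one = FALSE`. For
disjoint span sets (which per-track mentions always are) the greedy
assignment attains the maximum bipartite matching; the test suite
verifies this against a brute-force augmenting-path oracle on all
small instances.

Relation scoring requires both endpoints to match a gold mention and
the relation label to agree. Whether endpoint matching should be exact
or relaxed when entities are themselves predicted is genuinely open;
the package defaults to the stricter exact-span reading and exposes
`endpoint_match = "relaxed"` as a switch.

`counts_from_prn()` inverts printed (precision, recall, support)
triples into the integer TP/FP/FN counts behind them — possible
exactly because the counts are integers — and refuses inputs that no
integer triple reproduces at 4 decimal places. This is how the package
re-derives benchmark tables without access to the underlying corpus,
and reports are rendered at 4 decimal places to match that convention.

## The synthetic generator

The corpus the schema was developed on is not redistributable, so the
package generates its own: seeded, template-based procedures that
satisfy every schema invariant by construction (validated in tests).
The generator emulates the *structural* properties that matter to the
toolchain:

* passive single-clause synthesis sentences, usually opening with a
  vessel-charging step;
* a skewed verb distribution — the default weights are the published
  per-verb occurrence counts (add and stir dominant), so the Zipf-like
  shape is empirical, not invented;
* amounts and coreference labels absorbed into entity spans, including
  the canonical exemplars ("(9.00 g, 45.6 mmol, 1.00 equiv)",
  "between 0 °C and 5 °C", "ice/water", "overnight",
  "internal temperature");
* parameters annotated at first mention only;
* optional noise, on by default because raw journal text has all
  three: `(Note n)`/`(Figure n)` cross-references (inserted after a
  sentence's annotations so gold offsets remain valid on the noisy
  text), unannotated workup tails (which use verbs such as *washed*
  to reproduce the boundary failure mode), and repeated parameters.

It does **not** emulate lexical variety, chemical validity, anaphora,
multi-clause syntax or annotation disagreement. Consequently, the rule
baseline's F = 1.0 on a noise-free generated corpus demonstrates the
*internal consistency* of generator, pipeline and scorer — the
templates sit inside the baseline's pattern coverage by construction —
and says nothing about performance on real journal text. Generated
relations always respect the head's frame; the `adversarial` flag
exists solely to produce off-frame relations for validator tests.

Splits are procedure-level: shuffle with the seed, slice contiguously,
dev and test each `floor(n/10)` at the default 8:1:1 ratio (112
documents give 90/11/11). Which procedures land in which split is a
seed property; only the sizes are meaningful.

## Numerical and degenerate-input choices

* Offsets 0-based half-open everywhere; discontinuous mentions are
  supported in I/O and validation (fragments sorted, disjoint) though
  the generator emits only contiguous spans.
* Within-track span conflicts resolve longest-first, ties leftmost.
* Empty inputs: empty text → zero sentences, empty document; empty
  registry file → empty registry; evaluation of empty corpora → empty
  report with a zero micro row.
* `type_distribution()` rounds shares to integer percent; the shares
  sum to 100 ± 1 by rounding.
* Serialization renumbers mentions by (start, end, label) and
  relations by head then tail order, making brat output canonical and
  the parse/serialize pair mutually inverse.

## Problem sizes

The test suite and the acceptance script exercise: 200 generated
documents for the brat round-trip property, 50 perturbed prediction
sets for the relaxed-vs-exact dominance property, 80 random small
instances for the matching oracle, and a 50-document noise-free corpus
for the full-recovery check — sizes chosen to cover every template and
noise path many times over while keeping the whole suite fast on a
single CPU.

## Limitations

Anaphora between entities (compound ↔ "the mixture") is not resolved;
amounts are not parsed into quantities; parameters are carried
verbatim (no "reflux → solvent boiling point" inference); nested
actions inside modifier spans are not re-extracted; and the rule
baseline is a reference implementation, not a competitive extractor —
its coverage is exactly its lexicons and patterns.
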