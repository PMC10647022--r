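# rxnroles

Argument-role annotation and extraction for organic-synthesis procedures.

## The problem

Reproducing a reaction from a published procedure requires more than the
list of chemicals: *"A is added to B"* and *"B is added to A"* involve the
same species but different operations. `rxnroles` represents procedure
text as a sequence of **actions with argument roles**, PropBank-style.
Each action verb carries a *roleset* — a small frame of numbered slots.
For `add.01`:

```
ARG1: thing being added
ARG2: thing being added to
```

so in *"A is added to B"*, A is ARG1 and B is ARG2. Slots stop at ARG2;
ARG0 (the agent) is annotated only for the container frame `contain.01`,
because the agent of every other action is simply the experimenter.
Time, temperature, temperature-target and modifier phrases attach to
actions through the modifier role ARGM.

The annotation schema uses six mention labels — `REACTION_STEP`,
`ENTITY`, `TIME`, `TEMPERATURE`, `TEMP_TARGET`, `MODIFIER` — and four
relation labels — `ARG0`, `ARG1`, `ARG2`, `ARGM`. Two corpus policies
matter for tooling: a repeated parameter is annotated only at its first
mention, and coreference labels/amounts are absorbed into one span
(`"12-aminododecanolactam (1) (9.00 g, 45.6 mmol, 1.00 equiv)"` is a
single `ENTITY`).

The package provides, for this representation:

* **schema types and validation** (`rxn_document()`, `validate_document()`),
* a **roleset registry** with verb lemmatization (`load_registry()`,
  `resolve_roleset()`, `has_arg()`) shipped as an extensible TSV,
* **brat standoff I/O** and journal-text preprocessing
  (`parse_standoff()`, `serialize_standoff()`, `strip_note_refs()`),
* **training views**: per-track IOB2 export and `[E1]`/`[E2]`
  entity-marker relation instances (`export_iob2()`,
  `export_relation_instances()`),
* a **deterministic rule-based extraction pipeline** with pluggable
  tagger/classifier contracts (`run_pipeline()`),
* **evaluation** with exact and relaxed span matching
  (`evaluate_ner()`, `evaluate_re()`, `counts_from_prn()`),
* **action sequencing** aligned to the source text
  (`build_sequence()`, `render_text()`, `render_json()`),
* a **seeded synthetic-corpus generator** (`generate_corpus()`,
  `split_corpus()`, `corpus_stats()`), and
* a **CLI** (`inst/cli/rxnroles`, `rxn_main()`).

Scores use precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)` and
`F = 2PR/(P+R)` (0/0 → 0). *Exact* match requires identical span and
label; *relaxed* match requires at least one character of overlap with
the same label, assigned one-to-one.

## Worked example

```r
library(rxnroles)

txt <- paste(
  "A 500-mL three-necked round-bottomed flask was charged with",
  "12-aminododecanolactam (1) (9.00 g, 45.6 mmol, 1.00 equiv) (Note 2).",
  "Anhydrous THF (150 mL) was added dropwise to the flask over 10 min.",
  "The mixture was stirred at 0 °C for 2 h.")

doc <- run_pipeline(txt, doc_id = "example")
doc$mentions[, c("id", "label", "surface")]
```

```
   id    label         surface
 1 T1    ENTITY        A 500-mL three-necked round-bottomed flask
 2 T2    REACTION_STEP charged
 3 T3    ENTITY        12-aminododecanolactam (1) (9.00 g, 45.6 mmo…
 4 T4    ENTITY        Anhydrous THF (150 mL)
 5 T5    REACTION_STEP added
 6 T6    MODIFIER      dropwise
 7 T7    ENTITY        the flask
 8 T8    TIME          10 min
 9 T9    ENTITY        The mixture
10 T10   REACTION_STEP stirred
11 T11   TEMPERATURE   0 °C
12 T12   TIME          2 h
```

The `(Note 2)` cross-reference has been stripped before extraction; the
coreference label `(1)` and the amount are part of the entity span. The
relation table links each action to its arguments (`charged`:
ARG1 = the flask being charged, ARG2 = the material; `added`: ARG1/ARG2
plus ARGM for `dropwise` and `10 min`). Converting to an action
sequence aligned with the text:

```r
cat(render_text(build_sequence(doc)))
```

```
1. Charge A 500-mL three-necked round-bottomed flask → 12-aminododecanolactam (1) (9.00 g, 45.6 mmol, 1.00 equiv)
2. Add Anhydrous THF (150 mL) → the flask (dropwise, 10 min)
3. Stir The mixture (0 °C, 2 h)
```

One numbered step per `REACTION_STEP` mention, ARG1 before `→` ARG2,
parameters in parentheses; a step whose relation labels fall outside the
verb's roleset (e.g. ARG2 on `mix.01`, which has only ARG1) keeps the
argument and is suffixed `[!]`.

Synthetic corpora for development come from the seeded generator, whose
noise flags control `(Note n)` cross-references, unannotated workup
tails and repeated parameters:

```r
docs  <- generate_corpus(generator_config(seed = 7, n_procedures = 20))
stats <- corpus_stats(split_corpus(docs, ratio = c(8, 1, 1), seed = 7))
preds <- lapply(docs, function(d) run_pipeline(d$text, doc_id = d$doc_id))
golds <- lapply(docs, preprocess_document)
evaluate_ner(golds, preds, criterion = "relaxed")
```

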