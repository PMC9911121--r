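---
title: "Core lexicon scoring: method, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core lexicon scoring: method, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corelexr)
```

## The measure

Core lexicon (CoreLex) analysis scores a structured monologic discourse
sample against a task-specific checklist of key lexical items. Each item
scores 1 if produced at least once and 0 otherwise; the sample score is
the sum. The scoring equivalences are lexical, not contextual:

* every inflection of an item's lemma counts (plurals, verb conjugations,
  irregular forms — *went* credits *go*, *feet* credits *foot*);
* contracted forms count the same as uncontracted forms (*isn't* credits
  both *be* and *not*);
* dialect variants count as their standard equivalents (*gonna* credits
  *go* and *to*);
* homographs count regardless of part of speech or sense (*hand* the verb
  credits the item *hand*);
* synonyms do not count (*lad* never credits *boy*), with the conventional
  exception of the *mother*/*mom*/*mama*/*mommy*/*ma* and
  *father*/*dad*/*daddy*/*pa*/*papa* groups, which each behave as one item;
* semantic paraphasias credit only the word actually produced, never the
  intended target; phonemic paraphasias credit the intended target, on the
  assumption that the transcriber only codes a target (`tick [: kick]
  [* p:n]`) when the production was recognizably that word.

The last rule reflects a division of labour the package inherits from
transcription practice: judgments that require hearing the speech (e.g.
whether enough of a distorted word's phonemes were produced for it to
count) are made by the transcriber and encoded as CHAT codes; the scorer —
human or automated — trusts the codes. corelexr therefore never computes
phoneme overlap.

## The pipeline and its assumptions

Scoring a transcript composes five steps
(`score_transcript()` / `score_file()`):

1. **Parse** the CHAT subset: headers, speaker tiers with inline codes
   (`[: target]`, `[:: target]`, `[* class]`, `[/]`, `[//]`, `&`-fillers,
   `xxx`/`yyy`/`www`), `%mor` tiers, gem markers. Anything else is
   preserved opaquely (`raw_line`, `unknown_codes`, verbatim dependent
   tiers) and never silently dropped. The parser assumes one utterance per
   main tier and treats speaker codes and task labels case-insensitively.
2. **Unhide revisions**: retrace scopes (`<...> [//]`) are removed so
   revised material becomes scoreable. The `%mor` tier does not cover
   revision material, so items produced only there would otherwise be
   missed. Verbatim repetitions (`[/]`) remain excluded from scoring; the
   package follows the convention that repetition-scoped material is never
   credited (its head word is scored from the plain copy anyway).
3. **Demote semantic replacements**: single-colon target replacements
   carrying a semantic error class (`[* s:...]`) become double-colon, so
   morphological analysis processes the produced surface rather than the
   unproduced target. Phonological classes (`[* p:...]`) keep the single
   colon and credit the target. A replacement with *no* error class is kept
   single-colon (target credited) and recorded as a notice: in transcription
   practice untyped replacements are typically not semantic substitutions,
   but since the convention is ambiguous the package surfaces every such
   token rather than deciding silently.
4. **Derive lemma events** (`effective_lemmas()`): for each scoreable token
   the lemma comes from the aligned `%mor` entry when present, otherwise
   from the fallback analyzer (below). Contractions and dialect forms
   expand to one event per component.
5. **Match and tabulate** (`score_lemmas()`): an item is credited when any
   event's lemma falls in its accepted-lemma group, or its surface form is
   one of the item's user-added extended forms (e.g. *kittycat* for *cat*,
   if the user opts in). Matching is case-insensitive and POS-blind by
   construction.

Checklists are editable TSV files with one accepted-lemma group per item.
Validation enforces the invariants binary scoring relies on: unique
labels, lowercase entries, the label inside its own group, and group
disjointness across items — without disjointness a single production could
credit two items and per-item scores would be ill-defined. Every scoring
output carries an MD5 stamp of the checklist, and reliability comparisons
refuse to mix scores produced against different list versions. The five
packaged lists are synthetic reconstructions (24, 34, 94, 35, and 29 items
for Broken Window, Cat Rescue, Cinderella, Refused Umbrella, and Sandwich)
labeled as such in their provenance headers; they exercise the machinery
but are not normative instruments.

## The fallback analyzer

A bounded inflection lexicon stands behind `analyze_surface()`. It is not
a morphological grammar: it resolves, in order, a dialect table, a
contraction table (suffixes `n't`, `'ll`, `'re`, `'ve`, `'m`, `'s`, `'d`,
plus irregular full forms like *won't*), an inflection index, and regular
suffix heuristics, falling back to the identity lemma with a notice. The
index is generated over the package vocabulary (checklist lemmas,
distractors, irregular bases) by forward inflection rules, so every listed
lemma's paradigm is inverted exactly; unknown words rely on the suffix
heuristics, which are deliberately conservative.

Three resolution choices are worth stating because they are genuine
ambiguities:

* `'s` is mapped to *be* (*she's* → *she be*). Possessives therefore also
  emit a spurious *be* event; since *be* is produced near-universally in
  connected speech, the practical effect on binary scores is nil.
* `'d` and the irregulars *would*/*could*/*should* map to their base
  modals (*will*/*can*/*shall*): checklists list the base modal, and
  omission audits of hand scoring show *would* must credit *will*.
* Form collisions in the index are resolved deterministically with
  irregular verbs taking precedence (*leaves* → *leave*, not *leaf*;
  *lives* → *live*). The alternative reading loses only noun plurals of
  words that are rarely checklist items, while the verb reading protects
  items that are.

All tables are plain TSV under `inst/extdata/morphology/` so researchers
can extend them, mirroring how the automated scoring command is meant to
be tweakable for irregular-but-acceptable productions.

## Reliability statistics

`icc_agreement()` implements the intraclass correlation for the two-way
random-effects model with absolute agreement, the standard statistic for
validating a new scoring modality against an existing one. From the
two-way ANOVA mean squares (rows = samples, columns = methods):

$$ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

Absolute agreement retains the method (column) variance term, so a scorer
that is systematically one point low is penalized even if perfectly
correlated — the right behaviour when the claim is "the methods give the
same score", not "the methods rank samples identically". The 95% CI uses
the F-distribution method with Satterthwaite degrees of freedom;
average-measures values ($ICC(A,k)$) and their limits are the
Spearman–Brown step-up, available behind `type = "average"`. Single
measures is the default because in the validation design each transcript
is scored once per modality. Interpretation bands are left-closed at .5,
.75, and .9 (poor / moderate / good / excellent).

Degenerate inputs are defined rather than left to produce NaN: an
all-equal matrix (zero total variance) returns ICC 1 with a collapsed CI
and a `degenerate` flag, and noise-free agreement on varying data returns
exactly 1 with CI [1, 1]. The closed form is unit-tested against an
independent ANOVA-based computation to 1e-10 on randomized matrices, and
against an external implementation on a classic 6×4 worked example
(ICC(A,1) = 0.290, CI [0.019, 0.761]).

`compare_modalities()` produces the item-level discrepancy audit (every
disagreeing sample × item cell with direction), and `error_proportion()`
the errors-over-opportunities summary
$\#errors / (\#items \times \#samples)$.

## What the synthetic generator emulates — and what it does not

`generate_transcript()` builds CHAT transcripts whose exact checklist
score is known by construction, which is what makes end-to-end testing
possible without gated corpora. Per transcript it draws a coverage
probability, realises each covered item in a random invertible inflection,
and mixes in distractor words, fillers, retraces (revised material drawn
from distractors), verbatim repetitions, coded semantic paraphasias
(target = an unproduced item, never credited), coded phonemic paraphasias
(target credited), and dialect forms, then segments the stream into
utterances of 4–9 tokens and emits a consistent `%mor` tier. Exactness
rests on two design rules: the distractor vocabulary is packaged disjoint
from every built-in checklist's accepted lemmas (test-enforced), and every
noise construct tracks its effect into the ground truth.

Generator defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `coverage` | range 0.35–0.95 | aphasia cohorts span latent to severe presentations, producing a wide spread of totals; per-sample coverage drawn from a range reproduces that large between-sample variance, which is what carries a realistic ICC |
| `filler_rate` | 0.08 | fillers are frequent but not dominant in monologue |
| `retrace_rate` | 0.04 | revisions occur a few times per narrative |
| `repetition_rate` | 0.05 | verbatim repetitions slightly more common |
| `semantic_paraphasia_rate` | 0.02 | coded paraphasias are rare per token |
| `phonemic_paraphasia_rate` | 0.02 | likewise |
| `dialect_rate` | 0.03 | occasional *gonna*/*wanna* style forms |
| `distractor_vocab_size` | 40 | enough lexical variety without diluting items |

What the generator does **not** model: realistic syntax or discourse
structure, utterance-level error codes, agrammatism, perseveration,
severity-correlated paraphasia rates, or transcriber inconsistency.
Passing tests therefore show that the engine implements the scoring rules
exactly on well-formed coded input; they do not show robustness to
transcription idiosyncrasies beyond the supported CHAT subset, and scores
on real corpora remain contingent on transcript quality and on using the
published normative checklists.

`simulate_manual_scorer()` models the documented profile of hand-scoring
error — omissions of items that were produced — by flipping credited cells
to 0 at a configurable rate, never inventing credits.

## Validation problem sizes

The shipped test suite and `scripts/acceptance.R` rehearse the validation
design at desk scale, sizes chosen to exercise the statistics while
keeping a full run in minutes: a 200-transcript corpus for cell-for-cell
engine-vs-truth equivalence; 1,000 randomized matrices (5–20 samples × 2–3
methods) for the ICC closed form against the ANOVA oracle; and 20
replicates of 48 transcripts — the cohort size typical of discourse
validation studies — scored by engine and simulated manual scorer with a
1–5% omission rate. Across replicates the engine-vs-manual ICC stays in
the excellent band (≥ .9), reproducing the qualitative finding that
omission-dominated manual error leaves inter-method reliability excellent.

## Other design notes

* Utterance and token positions are 1-based and gem ranges inclusive,
  following R indexing conventions throughout the package.
* Gem labels resolve through a user-extensible alias table
  (`register_gem_alias()`), since corpora spell task markers
  inconsistently; unknown labels pass through as custom task ids.
* After `unhide_revisions()` a stored `%mor` tier no longer aligns (the
  unhidden tokens were never tagged); `write_chat()` drops such stale
  tiers, and scoring covers the gap with the fallback analyzer. This
  mirrors the reformat-then-retag structure of the original workflow while
  keeping the package free of a full morphological tagger.
* Batch scoring skips unreadable files with a logged report instead of
  failing the run; per-file results are identical to `score_file()`.

## Limitations

The parser covers the CHAT subset relevant to checklist scoring, not the
full standard. The fallback analyzer is bounded: out-of-vocabulary
irregulars and genuinely ambiguous forms can mis-lemmatize, which is why
transcripts carrying a real `%mor` tier are preferred input. The packaged
checklists are placeholders for the normative lists. And CoreLex itself is
a microlinguistic measure — it says nothing about discourse organisation,
informativeness, or syntax, and is best read alongside complementary
discourse measures.
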