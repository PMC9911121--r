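# corelexr

Automated core lexicon (CoreLex) scoring for discourse transcripts in CHAT
format, with the validation machinery for comparing scoring modalities.

## The problem

Core lexicon analysis is a checklist measure of lexical typicality in
structured monologic discourse, widely used in aphasia research: for a
given elicitation task (e.g. telling the Cinderella story, describing the
Broken Window picture sequence), a normed list of key lexical items exists,
and a speaker's score is the number of checklist items they produce at
least once. An item counts in any inflected form (*went*, *going*, *goes*
all credit *go*), in contractions (*isn't* credits *be* and *not*), and in
dialect forms (*gonna* credits *go* and *to*); synonyms do not count
(*lad* never credits *boy*), with the conventional exception of the
*mother*/*mom*/*mama* and *father*/*dad*/*pa* groups. Semantic paraphasias
(saying *brother* for the target *sister*) credit only the word actually
produced, while recognizable phonemic paraphasias (*tick* for *kick*)
credit the intended target.

Scoring this by hand is slow and error-prone. corelexr automates it for
transcripts in CHAT format (the TalkBank transcription standard), including
the two reformatting steps that make automation match hand scoring:

1. **Unhide revisions** — retraced material (`<the boy> [//] the girl`)
   is not covered by the `%mor` morphology tier, so items produced only in
   a revision would be missed; the retrace scoping is removed so revised
   words become scoreable. Verbatim repetitions (`the [/] the`) stay
   unscored.
2. **Demote semantic replacements** — `brother [: sister] [* s:r]` becomes
   `brother [:: sister] [* s:r]`, which blocks the morphology from crediting
   the unproduced target and credits the produced word instead.

Reliability between two scoring modalities (e.g. automated vs manual) is
assessed with the two-way random-effects, absolute-agreement intraclass
correlation

```
ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))
```

with the F-based 95% confidence interval, interpreted on the standard
bands (poor < .5 ≤ moderate < .75 ≤ good < .9 ≤ excellent), plus an
item-level discrepancy audit and the error proportion
`#errors / (#items × #samples)`.

Because real aphasia corpora are membership-gated, the package also ships a
synthetic transcript generator that emulates the relevant phenomena
(inflections, fillers, retraces, repetitions, coded paraphasias, dialect
forms) with **exact** ground-truth scores, so the whole pipeline is
testable end to end.

## Worked example

```r
library(corelexr)

t <- parse_chat(c(
  "*PAR:\tknocks it off the table.",
  "%mor:\tv|knock-3S pro:per|it prep|off det:art|the n|table."
))
effective_lemmas(t)$lemma
#> [1] "knock" "it"    "off"   "the"   "table"

lex <- builtin_lexicon("BrokenWindow")
score_transcript(t, lex)
#> <CoreLex score> sample: NA  task: BrokenWindow
#>   total: 2 of 24 items
#>   credited: it, the
```

The five scoreable words lemmatize through the `%mor` tier; of the 24-item
Broken Window checklist, only *it* and *the* appear in this utterance, so
the sample scores 2.

A full study-style run — generate a corpus, score it, and compare the
engine against a simulated manual scorer:

```r
cfg <- generation_config(task_id = "BrokenWindow", seed = 1)
corpus <- generate_corpus(48, cfg, dir = "corpus")
engine <- batch_score("corpus", builtin_lexicon("BrokenWindow"),
                      task = "BrokenWindow")
manual <- simulate_manual_scorer(corpus$truth, omission_rate = 0.03, seed = 2)
icc_agreement(totals_matrix(engine, manual))
#> ICC (two-way random, absolute agreement, single measures)
#>   ICC = 0.9699, 95% CI [0.7549, 0.9904] — excellent
#>   MS rows 31.1560, MS cols 12.0417, MS error 0.2332 (n=48, k=2)
```

The same workflow is available from a shell via `exec/corelex`
(subcommands `reformat`, `score`, `reliability`, `synth`).

Note on the built-in checklists: the packaged task lists under
`inst/extdata/lexicons/` are synthetic reconstructions for testing and
demonstration (their provenance headers say so). For real analyses supply
the published normative lists as your own checklist files via
`load_lexicon()`.

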