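Package: corelexr
Title: Automated Core Lexicon Scoring for CHAT Discourse Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores structured monologic discourse samples transcribed in
    CHAT format against task-specific core lexicon (CoreLex) checklists.
    Parses the CHAT subset used in aphasia discourse analysis (speaker
    tiers, %mor morphology tiers, target-replacement, paraphasia, retrace
    and repetition codes, gem markers), applies the reformatting steps that
    make revision material and semantic paraphasias scoreable, matches
    produced lemmas against editable per-task checklists, and provides the
    validation machinery for comparing scoring modalities: two-way random
    absolute-agreement intraclass correlation with confidence intervals,
    item-level discrepancy audits, and error-proportion summaries. Includes
    a synthetic transcript generator with exact ground-truth scores for
    end-to-end testing without access to gated corpora.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
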