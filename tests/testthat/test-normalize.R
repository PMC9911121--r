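test_that("unhide_revisions makes retraced material scoreable, leaves repetitions excluded", {
  t <- parse_chat("*PAR:\t<the boy> [//] the girl ran .")
  u <- unhide_revisions(t)$utterances[[1]]
  expect_identical(u$tokens$scope_role, rep("plain", 5))
  expect_identical(effective_lemmas(unhide_revisions(t))$lemma,
                   c("the", "boy", "the", "girl", "run"))

  t2 <- parse_chat("*PAR:\tthe [/] the dog .")
  u2 <- unhide_revisions(t2)$utterances[[1]]
  expect_identical(u2$tokens$scope_role,
                   c("repetition_material", "plain", "plain"))

  plain <- parse_chat("*PAR:\tthe dog ran .")
  expect_identical(transcript_essence(unhide_revisions(plain)),
                   transcript_essence(plain))
})

test_that("demote_semantic_replacements targets semantic but not phonemic codes", {
  t <- parse_chat("*PAR:\tbrother [: sister] [* s:r] tick [: kick] [* p:n] dog [: log] .")
  d <- demote_semantic_replacements(t)
  tk <- d$utterances[[1]]$tokens
  expect_identical(tk$replacement_style, c("double", "single", "single"))
  # untyped replacement stays single-colon but is noticed
  ev <- effective_lemmas(d)
  expect_true(any(grepl("untyped", attr(ev, "notes"))))
})

test_that("reformatting transformations are idempotent", {
  t <- parse_chat(c(
    "*PAR:\t<the boy> [//] brother [: sister] [* s:r] went .",
    "*PAR:\tthe [/] the tick [: kick] [* p:n] ."
  ))
  once <- demote_semantic_replacements(unhide_revisions(t))
  twice <- demote_semantic_replacements(unhide_revisions(once))
  expect_identical(transcript_essence(twice), transcript_essence(once))
})

test_that("effective lemma stream follows replacement semantics", {
  # double colon: surface analyzed, target never credited
  t <- parse_chat("*PAR:\tbrother [:: sister] .")
  expect_identical(effective_lemmas(t)$lemma, "brother")
  # single colon: target credited (phonemic paraphasia semantics)
  t <- parse_chat("*PAR:\ttick [: kick] [* p:n] .")
  ev <- effective_lemmas(t)
  expect_identical(ev$lemma, "kick")
  expect_identical(ev$source, "replacement_target")
  # with an aligned %mor tier the tier wins
  t <- parse_chat(c("*PAR:\tknocks it off the table.",
                    "%mor:\tv|knock-3S pro:per|it prep|off det:art|the n|table."))
  ev <- effective_lemmas(t)
  expect_identical(ev$lemma, c("knock", "it", "off", "the", "table"))
  expect_identical(unique(ev$source), "mor_tier")
})

test_that("contractions and dialect forms expand to multiple lemma events", {
  t <- parse_chat("*PAR:\tgonna go but isn't here .")
  lem <- effective_lemmas(t)$lemma
  expect_identical(lem, c("go", "to", "go", "but", "be", "not", "here"))
})

test_that("fillers, unintelligibles and repetition material yield nothing", {
  t <- parse_chat("*PAR:\t&-um xxx the [/] the dog .")
  ev <- effective_lemmas(t)
  expect_identical(ev$lemma, c("the", "dog"))
  all_rep <- parse_chat("*PAR:\t<the dog ran> [/] .")
  expect_identical(nrow(effective_lemmas(all_rep)), 0L)
})

test_that("lemma events keep nondecreasing utterance order", {
  cfg <- generation_config(task_id = "Cinderella", seed = 5)
  g <- generate_transcript(cfg)
  ev <- effective_lemmas(unhide_revisions(g$transcript))
  expect_true(all(diff(ev$utterance_index) >= 0))
})

test_that("fallback analyzer implements the scoring equivalences", {
  cases <- list(
    list("went", "go"), list("going", "go"), list("goes", "go"),
    list("table", "table"), list("dishes", "dish"), list("stopped", "stop"),
    list("tries", "try"), list("carried", "carry"), list("children", "child"),
    list("knocks", "knock"), list("would", "will"), list("feet", "foot")
  )
  for (cs in cases) {
    expect_identical(analyze_surface(cs[[1]])$lemma, cs[[2]],
                     label = paste("lemma of", cs[[1]]))
  }
  expect_identical(analyze_surface("isn't")$parts$lemma, c("be", "not"))
  expect_identical(analyze_surface("won't")$parts$lemma, c("will", "not"))
  expect_identical(analyze_surface("she'd")$parts$lemma, c("she", "will"))
  expect_identical(analyze_surface("gonna")$parts$lemma, c("go", "to"))
  expect_identical(analyze_surface("wanna")$parts$lemma, c("want", "to"))
  # unanalyzable forms pass through as identity, flagged
  an <- analyze_surface("flurble")
  expect_identical(an$lemma, "flurble")
  expect_false(an$analyzed)
})

test_that("fallback analyzer reproduces %mor lemmas when the tier is removed", {
  for (seed in 1:4) {
    cfg <- generation_config(task_id = "RefusedUmbrella", seed = seed)
    g <- generate_transcript(cfg)
    with_mor <- g$lines
    without <- with_mor[!startsWith(with_mor, "%")]
    pipe <- function(lines) {
      t <- demote_semantic_replacements(unhide_revisions(parse_chat(lines)))
      sort(effective_lemmas(t)$lemma)
    }
    expect_identical(pipe(without), pipe(with_mor))
  }
})
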