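test_that("item scores are binary and frequency-invariant", {
  lex <- make_lexicon(c("mother", "go"),
                      accepted = list(mother = c("mother", "mom", "mama")))
  ev <- data.frame(lemma = c("mother", "mother", "mother"),
                   surface = c("mother", "mother", "mother"))
  s <- score_lemmas(ev, lex)
  expect_identical(unname(s$per_item), c(1L, 0L))
  expect_identical(s$total, 1L)
  none <- score_lemmas(data.frame(lemma = character(0),
                                  surface = character(0)), lex)
  expect_identical(none$total, 0L)
  expect_identical(unname(none$per_item), c(0L, 0L))
})

test_that("scoring the worked utterance credits exactly the produced items", {
  lex <- make_lexicon(c("knock", "table", "dog"))
  ev <- effective_lemmas(parse_chat("*PAR:\tknocks it off the table."))
  s <- score_lemmas(ev, lex)
  expect_identical(s$per_item, c(knock = 1L, table = 1L, dog = 0L))
  expect_identical(s$total, 2L)
  # agrees with the brute-force surface-expansion oracle
  expect_identical(unname(s$per_item),
                   oracle_score(c("knocks", "it", "off", "the", "table"), lex))
})

test_that("engine equals the surface-expansion oracle on inflected input", {
  lex <- make_lexicon(c("go", "mother", "kick", "window", "be"),
                      accepted = list(mother = c("mother", "mom", "mama")))
  words_sets <- list(
    c("went", "the", "window"),
    c("mama", "kicked", "goes"),
    c("kicking", "windows", "was", "tables"),
    c("dog", "lad", "running")
  )
  for (words in words_sets) {
    t <- parse_chat(paste0("*PAR:\t", paste(words, collapse = " "), " ."))
    s <- score_transcript(t, lex)
    expect_identical(unname(s$per_item), oracle_score(words, lex),
                     label = paste("oracle match on:",
                                   paste(words, collapse = " ")))
  }
})

test_that("score_file composes the full pipeline deterministically", {
  lex <- make_lexicon(c("knock", "table", "sister", "brother", "kick"))
  path <- withr::local_tempfile(fileext = ".cha")
  writeLines(c("@Begin", "@G:\tTestTask",
               "*INV:\twhat happened ?",
               "*PAR:\tknocks it off the table.",
               "*PAR:\tbrother [: sister] [* s:r] tick [: kick] [* p:n] .",
               "@End"), path)
  s <- score_file(path, lex, task = "TestTask")
  # semantic paraphasia target not credited; produced brother credited;
  # phonemic paraphasia target credited
  expect_identical(s$per_item,
                   c(knock = 1L, table = 1L, sister = 0L, brother = 1L,
                     kick = 1L))
  expect_identical(s$sample_id, sub("\\.cha$", "", basename(path)))
  expect_identical(score_file(path, lex, task = "TestTask"), s)
  expect_error(score_file(path, lex, task = "Cinderella"), "absent")
})

test_that("batch scoring walks a folder, skips corrupt files, keeps order", {
  lex <- builtin_lexicon("BrokenWindow")
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    cfg <- generation_config(task_id = "BrokenWindow", seed = 100 + i)
    writeLines(generate_transcript(cfg)$lines,
               file.path(dir, sprintf("s%02d.cha", i)))
  }
  writeLines("garbage not a tier", file.path(dir, "bad.cha"))
  msgs <- capture_messages(
    tab <- batch_score(dir, lex, task = "BrokenWindow")
  )
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$sample_id, sprintf("s%02d", 1:3))
  expect_match(paste(msgs, collapse = "\n"), "skipping bad.cha")
  expect_match(paste(msgs, collapse = "\n"), "3 scored, 1 skipped")
  # per-file equivalence
  s1 <- score_file(file.path(dir, "s01.cha"), lex, task = "BrokenWindow")
  expect_identical(tab$total[1], s1$total)
  expect_error(batch_score(dir, lex, pattern = "\\.nope$"), "no files")
})

test_that("scores are monotone under appended speech and invariant to duplication and case", {
  lex <- builtin_lexicon("RefusedUmbrella")
  base_lines <- c("*PAR:\tthe boy went to school .",
                  "*PAR:\tit was raining .")
  extra <- "*PAR:\tmom said take the umbrella ."
  s_base <- score_transcript(parse_chat(base_lines), lex)
  s_more <- score_transcript(parse_chat(c(base_lines, extra)), lex)
  expect_true(all(s_more$per_item >= s_base$per_item))
  expect_gte(s_more$total, s_base$total)
  # duplication invariance
  s_dup <- score_transcript(parse_chat(c(base_lines, base_lines)), lex)
  expect_identical(s_dup$per_item, s_base$per_item)
  # case invariance
  s_up <- score_transcript(parse_chat(toupper(base_lines)), lex)
  expect_identical(s_up$per_item, s_base$per_item)
})

test_that("score tables round-trip through CSV with checklist stamp", {
  cfg <- generation_config(task_id = "Sandwich", seed = 9)
  res <- generate_corpus(4, cfg, dir = withr::local_tempdir())
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(res$truth, path)
  back <- read_scores(path)
  expect_identical(back$sample_id, res$truth$sample_id)
  expect_identical(back$total, res$truth$total)
  expect_identical(attr(back, "lexicon_hash"),
                   attr(res$truth, "lexicon_hash"))
  expect_identical(attr(back, "task_id"), "Sandwich")
  expect_identical(attr(back, "item_labels"),
                   attr(res$truth, "item_labels"))
})
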