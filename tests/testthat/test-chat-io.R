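test_that("a main tier with %mor parses into aligned tokens and lemmas", {
  t <- parse_chat(c(
    "*PAR:\tknocks it off the table.",
    "%mor:\tv|knock-3S pro:per|it prep|off det:art|the n|table."
  ))
  expect_length(t$utterances, 1)
  u <- t$utterances[[1]]
  expect_identical(u$speaker, "PAR")
  expect_identical(u$tokens$surface,
                   c("knocks", "it", "off", "the", "table"))
  expect_identical(sum(!is.na(u$tokens$mor_index)), 5L)
  expect_identical(vapply(u$mor, function(e) e$parts$lemma[1], ""),
                   c("knock", "it", "off", "the", "table"))
})

test_that("empty input yields an empty transcript", {
  t <- parse_chat("")
  expect_length(t$utterances, 0)
  expect_identical(nrow(t$gems), 0L)
})

test_that("replacement, error, retrace, repetition, and filler codes are captured", {
  t <- parse_chat("*PAR:\tbrother [:: sister] went .")
  tk <- t$utterances[[1]]$tokens
  expect_identical(tk$surface[1], "brother")
  expect_identical(tk$replacement_target[1], "sister")
  expect_identical(tk$replacement_style[1], "double")

  t <- parse_chat("*PAR:\ttick [: kick] [* p:n] it .")
  tk <- t$utterances[[1]]$tokens
  expect_identical(tk$replacement_style[1], "single")
  expect_identical(tk$error_codes[1], "p:n")

  t <- parse_chat("*PAR:\t&-um <the boy> [//] the [/] the girl xxx ran .")
  tk <- t$utterances[[1]]$tokens
  expect_true(tk$is_filler[1])
  expect_identical(tk$scope_role[2:3], rep("retrace_material", 2))
  expect_identical(tk$scope_role[4], "repetition_material")
  expect_true(tk$is_unintelligible[7])
  # repetition- and retrace-scoped material and fillers get no %mor slot
  expect_identical(which(!is.na(tk$mor_index)), c(5L, 6L, 8L))
})

test_that("unknown codes are flagged, never silently dropped", {
  t <- parse_chat("*PAR:\tthe dog [% comment] ran .")
  u <- t$utterances[[1]]
  expect_identical(u$unknown_codes, "[% comment]")
  expect_match(u$raw_line, "% comment", fixed = TRUE)
  expect_identical(u$tokens$surface, c("the", "dog", "ran"))
})

test_that("malformed lines and unbalanced scopes raise parse errors", {
  expect_error(parse_chat("not a tier line"), "line 1")
  expect_error(parse_chat("%mor:\tv|go ."), "line 1")
  expect_error(parse_chat("*PAR:\t<the boy [//] ran ."), "unbalanced")
})

test_that("%mor misalignment is recorded as a warning flag, tier kept raw", {
  t <- parse_chat(c("*PAR:\tthe dog ran .", "%mor:\tdet|the n|dog ."))
  u <- t$utterances[[1]]
  expect_true(u$mor_warning)
  expect_null(u$mor)
  expect_identical(u$deps$mor, "det|the n|dog .")
})

test_that("speaker selection is case-insensitive and partitions utterances", {
  t <- parse_chat(c("*INV:\ttell me more .", "*PAR:\tthe dog ran .",
                    "*PAR:\tit was big .", "*inv:\tokay ."))
  par <- select_speaker(t, "par")
  expect_length(par, 2)
  expect_identical(par[[1]]$tokens$surface[1], "the")
  expect_length(select_speaker(t, "MOT"), 0)
  codes <- unique(vapply(t$utterances, `[[`, "", "speaker"))
  pooled <- sort(unlist(lapply(codes, function(cd) {
    attr(select_speaker(t, cd), "indices")
  })))
  expect_identical(pooled, seq_along(t$utterances))
})

test_that("gem segments extract by task id and alias; absent tasks error", {
  t <- parse_chat(c(
    "@Begin", "@G:\tWindow", "*PAR:\tthe boy kicked .",
    "@G:\tCat", "*PAR:\tthe cat was stuck .", "*PAR:\tin a tree .",
    "@Bg:\tSandwich", "*PAR:\tget the bread .", "@Eg:\tSandwich", "@End"
  ))
  expect_identical(nrow(t$gems), 3L)
  cat_seg <- extract_task_segment(t, "CatRescue")
  expect_length(cat_seg$utterances, 2)
  expect_identical(cat_seg$utterances[[1]]$tokens$surface[2], "cat")
  bw <- extract_task_segment(t, "BrokenWindow")
  expect_length(bw$utterances, 1)
  sw <- extract_task_segment(t, "Sandwich")
  expect_length(sw$utterances, 1)
  err <- tryCatch(extract_task_segment(t, "Cinderella"),
                  error = conditionMessage)
  expect_match(err, "absent")
  expect_match(err, "Window")
  only <- extract_task_segment(parse_chat(c("@G:\tCat", "*PAR:\tthe cat .")),
                               "CatRescue")
  expect_length(only$utterances, 1)
})

test_that("user-registered gem aliases resolve", {
  register_gem_alias("fenster", "BrokenWindow")
  t <- parse_chat(c("@G:\tfenster", "*PAR:\tthe window broke ."))
  expect_length(extract_task_segment(t, "BrokenWindow")$utterances, 1)
})

test_that("write/parse round-trips hand-written and generated transcripts", {
  t <- parse_chat(c(
    "@Begin", "@Languages:\teng", "@G:\tWindow",
    "*PAR:\t&-um <the boy> [//] the girl tick [: kick] [* p:n] it .",
    "*INV:\tbrother [:: sister] [/] ok ?",
    "@End"
  ))
  expect_roundtrip(t)
  expect_match(paste(write_chat(t), collapse = "\n"), "[:: sister]",
               fixed = TRUE)
  for (task in c("BrokenWindow", "Cinderella")) {
    cfg <- generation_config(task_id = task, seed = 11)
    expect_roundtrip(generate_transcript(cfg)$transcript)
  }
  empty <- parse_chat("")
  lines <- write_chat(empty)
  expect_identical(lines, c("@Begin", "@End"))
})

test_that("stripping dependent tiers never changes main-tier token counts", {
  cfg <- generation_config(task_id = "CatRescue", seed = 3)
  with_mor <- generate_transcript(cfg)$lines
  without <- with_mor[!startsWith(with_mor, "%")]
  ta <- parse_chat(with_mor)
  tb <- parse_chat(without)
  expect_identical(
    vapply(ta$utterances, function(u) nrow(u$tokens), integer(1)),
    vapply(tb$utterances, function(u) nrow(u$tokens), integer(1))
  )
})
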