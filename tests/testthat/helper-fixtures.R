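# Shared fixtures: in-code checklist construction and transcript comparison.

# write a checklist TSV and load it; accepted/extended are named lists
# keyed by label ("label=a;b" groups), defaults to {label}
make_lexicon <- function(labels, accepted = list(), extended = list(),
                         task_id = "TestTask") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  rows <- vapply(labels, function(l) {
    acc <- if (!is.null(accepted[[l]])) paste(accepted[[l]], collapse = ";")
           else l
    ext <- if (!is.null(extended[[l]])) paste(extended[[l]], collapse = ";")
           else ""
    paste(l, acc, ext, sep = "\t")
  }, "")
  writeLines(c(paste0("# task_id: ", task_id),
               "# provenance: test fixture",
               "label\taccepted_lemmas\textended_forms",
               rows), path)
  load_lexicon(path)
}

# write checklist rows verbatim (for validation-failure cases)
write_raw_lexicon <- function(rows, task_id = "TestTask",
                              env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(c(paste0("# task_id: ", task_id),
               "label\taccepted_lemmas\textended_forms",
               rows), path)
  path
}

# comparable view of a transcript: content fields only, raw lines ignored
transcript_essence <- function(t) {
  list(
    utterances = lapply(t$utterances, function(u) {
      tk <- u$tokens
      list(speaker = u$speaker,
           tokens = tk[, c("surface", "replacement_target",
                           "replacement_style", "error_codes", "scope_role",
                           "is_filler", "is_unintelligible")],
           terminator = u$terminator,
           mor = if (!is.null(u$mor)) {
             lapply(u$mor, function(e) e$parts$lemma)
           })
    }),
    gems = t$gems[, c("label", "start", "end", "style")]
  )
}

expect_roundtrip <- function(t) {
  t2 <- parse_chat(write_chat(t))
  expect_equal(transcript_essence(t2), transcript_essence(t))
}

# brute-force scoring oracle: expand each item into the full surface-form
# set the package's inflection lexicon can invert, then test membership of
# the produced word list (independent of the parsing/scoring pipeline)
oracle_score <- function(words, lex) {
  words <- tolower(words)
  vapply(seq_len(nrow(lex$items)), function(i) {
    forms <- unlist(lapply(lex$items$accepted[[i]],
                           corelexr:::invertible_forms))
    forms <- c(forms, lex$items$extended[[i]])
    as.integer(any(words %in% forms))
  }, integer(1))
}

# two-way ANOVA mean squares via stats::aov (independent of the package's
# own sums-of-squares arithmetic)
aov_icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   row = factor(rep(seq_len(n), k)),
                   col = factor(rep(seq_len(k), each = n)))
  # zero-residual fits make aov warn about its F tests; only the mean
  # squares are used here
  a <- suppressWarnings(stats::anova(stats::aov(y ~ row + col, data = df)))
  msr <- a["row", "Mean Sq"]
  msc <- a["col", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  list(
    agreement = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    consistency = (msr - mse) / (msr + (k - 1) * mse)
  )
}
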