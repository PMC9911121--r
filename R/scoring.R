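# The scoring engine: lemma events x checklist -> binary item scores,
# single-file scoring, and batch scoring into a results table.

new_checklist_score <- function(sample_id, task_id, per_item, lexicon_hash) {
  structure(list(sample_id = sample_id, task_id = task_id,
                 per_item = per_item, total = sum(per_item),
                 lexicon_hash = lexicon_hash),
            class = "clx_score")
}

#' Score a lemma event stream against a checklist
#'
#' An item scores 1 when at least one event credits it and 0 otherwise;
#' production frequency never changes the score (saying *mother* three
#' times still scores 1).
#'
#' @param events Lemma events from [effective_lemmas()] (data frame with
#'   `lemma` and `surface` columns).
#' @param lex A `clx_lexicon`.
#' @param sample_id Identifier recorded on the score.
#' @return A `clx_score`: `per_item` named 0/1 vector in checklist order,
#'   `total`, `task_id`, and the checklist `lexicon_hash`.
#' @examples
#' lex <- builtin_lexicon("BrokenWindow")
#' ev <- data.frame(lemma = c("knock", "it", "off", "the", "table"),
#'                  surface = c("knocks", "it", "off", "the", "table"))
#' score_lemmas(ev, lex)$total
#' @export
score_lemmas <- function(events, lex, sample_id = NA_character_) {
  stopifnot(inherits(lex, "clx_lexicon"))
  labels <- lex$items$label
  per_item <- setNames(integer(length(labels)), labels)
  if (nrow(events)) {
    lemma_map <- setNames(
      rep(labels, lengths(lex$items$accepted)),
      unlist(lex$items$accepted)
    )
    hit <- lemma_map[tolower(events$lemma)]
    per_item[hit[!is.na(hit)]] <- 1L
    ext_n <- lengths(lex$items$extended)
    if (any(ext_n > 0) && !is.null(events$surface)) {
      ext_map <- setNames(rep(labels, ext_n), unlist(lex$items$extended))
      hit <- ext_map[tolower(events$surface)]
      per_item[hit[!is.na(hit)]] <- 1L
    }
  }
  new_checklist_score(sample_id, lex$task_id, per_item, lex$hash)
}

#' Score a parsed transcript
#'
#' Composes the full pipeline on an in-memory transcript:
#' [unhide_revisions()], [demote_semantic_replacements()], task segment
#' extraction, speaker selection, [effective_lemmas()], [score_lemmas()].
#'
#' @param t A `clx_transcript`.
#' @param lex A `clx_lexicon`.
#' @param task Task id; `NULL` scores the whole transcript.
#' @param speaker Speaker code (default `"PAR"`).
#' @param sample_id Identifier recorded on the score.
#' @return A `clx_score`.
#' @export
score_transcript <- function(t, lex, task = NULL, speaker = "PAR",
                             sample_id = NA_character_) {
  t <- demote_semantic_replacements(unhide_revisions(t))
  ev <- effective_lemmas(t, speaker = speaker, task = task)
  score_lemmas(ev, lex, sample_id = sample_id)
}

#' Score one CHAT file
#'
#' @param path A `.cha` file.
#' @inheritParams score_transcript
#' @return A `clx_score`; the sample id is the file name without extension.
#' @export
score_file <- function(path, lex, task = NULL, speaker = "PAR") {
  t <- read_chat(path)
  sid <- sub("\\.[^.]*$", "", basename(path))
  tryCatch(
    score_transcript(t, lex, task = task, speaker = speaker, sample_id = sid),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE)
  )
}

#' Batch-score a folder of CHAT files into a results table
#'
#' Files are processed in sorted name order. A file that fails to parse or
#' score is reported on standard error and skipped; a summary of processed
#' and skipped counts is logged.
#'
#' @param folder Directory containing transcript files.
#' @inheritParams score_transcript
#' @param pattern Regular expression selecting files (default `.cha`).
#' @return A score table: tibble with `sample_id`, `task`, one 0/1 column
#'   per checklist item, and `total`; checklist metadata in attributes
#'   `task_id`, `item_labels`, `lexicon_hash`.
#' @export
batch_score <- function(folder, lex, task = NULL, speaker = "PAR",
                        pattern = "\\.cha$") {
  files <- sort(list.files(folder, pattern = pattern, full.names = TRUE))
  if (!length(files)) {
    stop("no files matching \"", pattern, "\" in ", folder, call. = FALSE)
  }
  scores <- list()
  skipped <- 0L
  for (f in files) {
    s <- tryCatch(score_file(f, lex, task = task, speaker = speaker),
                  error = function(e) {
                    message("skipping ", basename(f), ": ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(s)) skipped <- skipped + 1L else {
      scores[[length(scores) + 1L]] <- s
    }
  }
  message("batch_score: ", length(scores), " scored, ", skipped, " skipped")
  if (!length(scores)) {
    stop("all ", length(files), " files failed to score", call. = FALSE)
  }
  score_table(scores)
}

#' Assemble scores into a score table
#'
#' @param scores List of `clx_score` objects over the same checklist.
#' @return Score table tibble; see [batch_score()].
#' @export
score_table <- function(scores) {
  stopifnot(length(scores) > 0)
  labels <- names(scores[[1]]$per_item)
  hashes <- unique(vapply(scores, `[[`, "", "lexicon_hash"))
  if (length(hashes) > 1L) {
    stop("scores come from different checklist versions", call. = FALSE)
  }
  ids <- vapply(scores, `[[`, "", "sample_id")
  task <- scores[[1]]$task_id
  mat <- do.call(rbind, lapply(scores, function(s) s$per_item[labels]))
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- tibble::add_column(out, sample_id = ids,
                            task = rep(task, length(ids)), .before = 1)
  out$total <- vapply(scores, `[[`, integer(1), "total")
  attr(out, "task_id") <- task
  attr(out, "item_labels") <- labels
  attr(out, "lexicon_hash") <- hashes
  out
}

#' Read and write score tables as CSV
#'
#' The CSV carries the task id and checklist hash in a leading `#` comment
#' line so downstream reliability analyses can refuse to compare scores
#' produced against different checklist versions.
#'
#' @param tab Score table from [batch_score()] / [score_table()].
#' @param path CSV file path.
#' @return `write_scores()`: `path`, invisibly. `read_scores()`: the score
#'   table.
#' @export
write_scores <- function(tab, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# corelex scores task=", attr(tab, "task_id"),
                    " lexicon_hash=", attr(tab, "lexicon_hash")), con)
  utils::write.csv(as.data.frame(tab, check.names = FALSE), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "#")]
  task <- NA_character_
  hash <- NA_character_
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("task=([^ ]+) lexicon_hash=([^ ]+)",
                                    hdr[1]))[[1]]
    if (length(m) == 3L) {
      task <- m[2]
      hash <- m[3]
    }
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        check.names = FALSE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "task_id") <- task
  attr(out, "item_labels") <- setdiff(names(out),
                                      c("sample_id", "task", "total"))
  attr(out, "lexicon_hash") <- hash
  out
}

#' @export
print.clx_score <- function(x, ...) {
  cat("<CoreLex score> sample:", x$sample_id, " task:", x$task_id, "\n")
  cat("  total:", x$total, "of", length(x$per_item), "items\n")
  hits <- names(x$per_item)[x$per_item == 1L]
  if (length(hits)) cat("  credited:", paste(hits, collapse = ", "), "\n")
  invisible(x)
}
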