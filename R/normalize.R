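# Preprocessing transformations applied before scoring, equivalent to the
# reformatting step of the command-line workflow, plus derivation of the
# effective lemma stream the scoring engine consumes.

#' Make retraced (revised) material scoreable
#'
#' Revision material — words inside `<...> [//]` retrace scopes — is not
#' covered by the `%mor` morphology tier, so a checklist item produced only
#' in a revision would be missed. This transformation removes the retrace
#' scoping so the revised words become plain, scoreable tokens. Verbatim
#' repetitions (`[/]`) are left excluded from scoring.
#'
#' Idempotent; the input transcript is not modified.
#'
#' @param t A `clx_transcript`.
#' @return A new `clx_transcript` with retrace material unhidden. Unhidden
#'   tokens carry no `%mor` alignment, so their lemmas later come from the
#'   fallback analyzer.
#' @examples
#' t <- parse_chat("*PAR:\t<the boy> [//] the girl ran .")
#' u <- unhide_revisions(t)$utterances[[1]]
#' u$tokens$scope_role
#' @export
unhide_revisions <- function(t) {
  stopifnot(inherits(t, "clx_transcript"))
  t$utterances <- lapply(t$utterances, function(u) {
    hit <- u$tokens$scope_role == "retrace_material"
    if (any(hit)) {
      u$tokens$scope_role[hit] <- "plain"
      u$tokens$scope_group[hit] <- NA_integer_
      u$tokens$mor_index[hit] <- NA_integer_
    }
    u
  })
  t
}

#' Demote semantic-paraphasia target replacements to double colons
#'
#' A single-colon replacement `brother [: sister]` credits the intended
#' target (*sister*) because morphological analysis processes the target.
#' For semantic paraphasias that is wrong — the speaker did not produce the
#' target — so replacements carrying a semantic error class (`[* s:...]`)
#' are rewritten to double colons, which blocks target processing and
#' credits the produced surface instead. Phonological error classes
#' (`[* p:...]`) keep the single colon: a recognizable sound-level
#' distortion still credits the intended word.
#'
#' Idempotent; the input transcript is not modified.
#'
#' @param t A `clx_transcript`.
#' @return A new `clx_transcript`.
#' @examples
#' t <- parse_chat("*PAR:\tbrother [: sister] [* s:r] .")
#' demote_semantic_replacements(t)$utterances[[1]]$tokens$replacement_style
#' @export
demote_semantic_replacements <- function(t) {
  stopifnot(inherits(t, "clx_transcript"))
  t$utterances <- lapply(t$utterances, function(u) {
    tk <- u$tokens
    for (i in seq_len(nrow(tk))) {
      if (tk$replacement_style[i] == "single" && nzchar(tk$error_codes[i])) {
        classes <- strsplit(tk$error_codes[i], ";", fixed = TRUE)[[1]]
        if (any(startsWith(classes, "s"))) {
          tk$replacement_style[i] <- "double"
        }
      }
    }
    u$tokens <- tk
    u
  })
  t
}

empty_lemma_events <- function() {
  data.frame(lemma = character(0), surface = character(0),
             source = character(0), utterance_index = integer(0),
             stringsAsFactors = FALSE)
}

#' Derive the effective lemma stream for scoring
#'
#' Walks a speaker's scoreable tokens (plain tokens; fillers, unintelligible
#' material, and repetition-scoped material yield nothing) and emits one
#' lemma event per morphological component:
#' \itemize{
#'   \item double-colon replacement: the produced surface is analyzed
#'     (the unproduced target is never credited);
#'   \item single-colon replacement: the intended target is credited, from
#'     the `%mor` tier when aligned, else by analyzing the target;
#'   \item plain token: `%mor` lemma when available, else the fallback
#'     analyzer on the surface.
#' }
#' Contractions and dialect forms expand to multiple events. The transcript
#' should already have passed through [unhide_revisions()] and
#' [demote_semantic_replacements()]; [score_transcript()] composes the full
#' pipeline.
#'
#' @param t A `clx_transcript`.
#' @param speaker Speaker code to score (default `"PAR"`).
#' @param task Optional task id; when given, the gem segment is extracted
#'   first via [extract_task_segment()].
#' @return Data frame with columns `lemma` (lowercase), `surface`, `source`
#'   (`mor_tier`, `fallback_analyzer`, or `replacement_target`), and
#'   `utterance_index` (position in `t`). Scoring notices (untyped
#'   replacements, unanalyzable forms) are in attribute `"notes"`.
#' @examples
#' t <- parse_chat("*PAR:\tgonna go .")
#' effective_lemmas(t)$lemma
#' @export
effective_lemmas <- function(t, speaker = "PAR", task = NULL) {
  stopifnot(inherits(t, "clx_transcript"))
  if (!is.null(task)) t <- extract_task_segment(t, task)
  notes <- character(0)
  rows <- list()
  for (ui in seq_along(t$utterances)) {
    u <- t$utterances[[ui]]
    if (!identical(toupper(u$speaker), toupper(speaker))) next
    tk <- u$tokens
    mor_ok <- !is.null(u$mor)
    for (i in seq_len(nrow(tk))) {
      if (tk$scope_role[i] != "plain" || tk$is_filler[i] ||
          tk$is_unintelligible[i]) next
      style <- tk$replacement_style[i]
      if (style == "single" && !nzchar(tk$error_codes[i])) {
        notes <- c(notes, paste0("untyped [: ", tk$replacement_target[i],
                                 "] replacement for \"", tk$surface[i],
                                 "\"; target credited"))
      }
      if (style == "double") {
        an <- analyze_surface(tk$surface[i])
        if (!an$analyzed) {
          notes <- c(notes, paste0("unanalyzed form \"", an$surface,
                                   "\"; identity lemma used"))
        }
        parts <- an$parts
        src <- "fallback_analyzer"
      } else if (style == "single") {
        if (mor_ok && !is.na(tk$mor_index[i])) {
          parts <- u$mor[[tk$mor_index[i]]]$parts
          src <- "mor_tier"
        } else {
          words <- strsplit(trimws(tk$replacement_target[i]),
                            "[[:space:]]+")[[1]]
          parts <- do.call(rbind, lapply(words,
                                         function(w) analyze_surface(w)$parts))
          src <- "replacement_target"
        }
      } else {
        if (mor_ok && !is.na(tk$mor_index[i])) {
          parts <- u$mor[[tk$mor_index[i]]]$parts
          src <- "mor_tier"
        } else {
          an <- analyze_surface(tk$surface[i])
          if (!an$analyzed) {
            notes <- c(notes, paste0("unanalyzed form \"", an$surface,
                                     "\"; identity lemma used"))
          }
          parts <- an$parts
          src <- "fallback_analyzer"
        }
      }
      if (is.null(parts) || !nrow(parts)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lemma = tolower(parts$lemma), surface = tk$surface[i],
        source = src, utterance_index = ui, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_lemma_events()
  rownames(out) <- NULL
  attr(out, "notes") <- notes
  out
}
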