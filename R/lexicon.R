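# Core-lexicon checklists: loading, validation, matching semantics.
#
# Checklist file format (UTF-8 TSV):
#   # task_id: BrokenWindow
#   # provenance: <where the list comes from>
#   label	accepted_lemmas	extended_forms
#   mother	mother;mom;mama
# accepted_lemmas defaults to {label} when empty; extended_forms are
# user-added surface forms matched verbatim (e.g. "kittycat").

new_core_lexicon <- function(task_id, items, provenance = NA_character_,
                             path = NA_character_) {
  lx <- structure(list(task_id = task_id, items = items,
                       provenance = provenance, path = path),
                  class = "clx_lexicon")
  lx$hash <- lexicon_hash(lx)
  lx
}

#' Checklist version stamp
#'
#' MD5 digest of the checklist's canonical serialization (task id, item
#' labels, accepted lemma groups, extended forms). Every scoring output
#' carries this stamp so results are traceable to a specific list version.
#'
#' @param lex A `clx_lexicon`.
#' @return Hex digest string.
#' @export
lexicon_hash <- function(lex) {
  canon <- c(lex$task_id, vapply(seq_len(nrow(lex$items)), function(i) {
    paste(lex$items$label[i],
          paste(sort(lex$items$accepted[[i]]), collapse = ";"),
          paste(sort(lex$items$extended[[i]]), collapse = ";"),
          sep = "|")
  }, ""))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

split_field <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' Load and validate a core-lexicon checklist file
#'
#' Validation enforces the invariants binary per-item scoring relies on:
#' unique labels, non-empty lowercase entries, the label contained in its
#' own accepted-lemma group, and accepted-lemma groups disjoint across
#' items (one production must not credit two items).
#'
#' @param path Checklist TSV file (format documented above).
#' @return A `clx_lexicon`: list with `task_id`, `items` (tibble with
#'   columns `label`, `accepted` (list), `extended` (list)), `provenance`,
#'   and `hash`.
#' @seealso [builtin_tasks()], [lexicon_matches()]
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- lines[grepl("^#", lines)]
  get_hdr <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(hit)) trimws(sub("^[^:]*:", "", hit[1])) else NA_character_
  }
  task_id <- get_hdr("task_id")
  provenance <- get_hdr("provenance")
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  if (!all(c("label", "accepted_lemmas") %in% names(df))) {
    stop(path, ": expected columns label, accepted_lemmas", call. = FALSE)
  }
  if (!nrow(df)) stop(path, ": checklist has no items", call. = FALSE)
  if (is.null(df$extended_forms)) df$extended_forms <- ""
  labels <- trimws(df$label)
  if (anyDuplicated(labels)) {
    stop(path, ": duplicate label at row ",
         which(duplicated(labels))[1], ": ",
         labels[which(duplicated(labels))[1]], call. = FALSE)
  }
  accepted <- vector("list", nrow(df))
  extended <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!nzchar(labels[i])) stop(path, ": empty label at row ", i,
                                 call. = FALSE)
    acc <- split_field(df$accepted_lemmas[i])
    if (!length(acc)) acc <- labels[i]
    ext <- split_field(df$extended_forms[i])
    bad <- c(labels[i], acc, ext)[c(labels[i], acc, ext) !=
                                    tolower(c(labels[i], acc, ext))]
    if (length(bad)) {
      stop(path, ": non-lowercase entry at row ", i, ": ", bad[1],
           call. = FALSE)
    }
    if (!labels[i] %in% acc) {
      stop(path, ": row ", i, ": label \"", labels[i],
           "\" missing from its accepted_lemmas group", call. = FALSE)
    }
    accepted[[i]] <- unique(acc)
    extended[[i]] <- unique(ext)
  }
  all_acc <- unlist(accepted)
  if (anyDuplicated(all_acc)) {
    dup <- all_acc[duplicated(all_acc)][1]
    stop(path, ": accepted lemma \"", dup,
         "\" appears under more than one item", call. = FALSE)
  }
  items <- tibble::tibble(label = labels, accepted = accepted,
                          extended = extended)
  new_core_lexicon(task_id %||% NA_character_, items, provenance, path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Does a lemma event credit a checklist item?
#'
#' True when the event's lemma belongs to the item's accepted-lemma group,
#' or its surface form is one of the item's user-added extended forms.
#' Matching is case-insensitive and deliberately blind to part of speech
#' and word sense: *hand* is credited whether used as noun or verb.
#'
#' @param item One checklist item: a row of `lex$items` (or a list with
#'   `label`, `accepted`, `extended`).
#' @param lemma Lemma to test (e.g. from [effective_lemmas()]).
#' @param surface Optional originating surface form, tested against the
#'   item's extended forms.
#' @return Logical flag.
#' @examples
#' lex <- builtin_lexicon("Cinderella")
#' item <- lex$items[lex$items$label == "mother", ]
#' lexicon_matches(item, "mama")   # TRUE
#' @export
lexicon_matches <- function(item, lemma, surface = NULL) {
  acc <- if (is.list(item$accepted) && !is.character(item$accepted)) {
    item$accepted[[1]]
  } else {
    item$accepted
  }
  ext <- if (is.list(item$extended) && !is.character(item$extended)) {
    item$extended[[1]]
  } else {
    item$extended
  }
  tolower(lemma) %in% acc ||
    (!is.null(surface) && length(ext) && tolower(surface) %in% ext)
}

#' Built-in task checklists
#'
#' Packaged checklist fixtures for the five standard monologic discourse
#' tasks (Broken Window, Cat Rescue, Cinderella, Refused Umbrella,
#' Sandwich). These are synthetic reconstructions assembled for testing and
#' demonstration — the normative lists live in the cited norming
#' publications recorded in each file's provenance header — and users can
#' (and for real studies should) supply their own list files via
#' [load_lexicon()].
#'
#' @return `builtin_tasks()`: named list of `clx_lexicon`, one per task.
#'   `builtin_lexicon(task)`: the single requested lexicon.
#' @export
builtin_tasks <- function() {
  if (is.null(.clx$builtin)) {
    dir <- clx_extdata("lexicons")
    files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
    out <- lapply(files, load_lexicon)
    names(out) <- vapply(out, `[[`, "", "task_id")
    .clx$builtin <- out[.clx_builtin_tasks]
  }
  .clx$builtin
}

#' @rdname builtin_tasks
#' @param task Task id (alias-tolerant, see [register_gem_alias()]).
#' @export
builtin_lexicon <- function(task) {
  tasks <- builtin_tasks()
  id <- resolve_task(task)
  if (!id %in% names(tasks)) {
    stop("no built-in checklist for task \"", task, "\"; available: ",
         paste(names(tasks), collapse = ", "), call. = FALSE)
  }
  tasks[[id]]
}

#' @export
print.clx_lexicon <- function(x, ...) {
  cat("<core lexicon> task:", x$task_id, "—", nrow(x$items), "items\n")
  cat("  hash:", x$hash, "\n")
  if (!is.na(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
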