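# CHAT (.cha) reading and writing for the supported subset.

.clx_builtin_tasks <- c("BrokenWindow", "CatRescue", "Cinderella",
                        "RefusedUmbrella", "Sandwich")

# canonical form used for task / gem-label matching: lowercase, alphanumerics
canon_label <- function(x) gsub("[^a-z0-9]", "", tolower(x))

default_gem_aliases <- function() {
  list(
    BrokenWindow    = c("brokenwindow", "window", "broken"),
    CatRescue       = c("catrescue", "cat", "catinthetree", "catstory"),
    Cinderella      = c("cinderella", "cinderellastory"),
    RefusedUmbrella = c("refusedumbrella", "umbrella", "refused"),
    Sandwich        = c("sandwich", "sandwichother", "pbj",
                        "peanutbutterandjelly")
  )
}

gem_alias_table <- function() {
  if (is.null(.clx$aliases)) .clx$aliases <- default_gem_aliases()
  .clx$aliases
}

#' Register an additional gem-label alias for a task
#'
#' Corpora differ in how gem markers spell task names. The built-in alias
#' table covers common spellings for the five standard tasks; use this to
#' map further labels (or labels for custom tasks) onto a canonical task id.
#'
#' @param alias Gem label as it appears in transcripts.
#' @param task Canonical task id the label should resolve to.
#' @return The updated alias table, invisibly.
#' @examples
#' register_gem_alias("fenetre", "BrokenWindow")
#' @export
register_gem_alias <- function(alias, task) {
  tab <- gem_alias_table()
  task <- resolve_task(task, tab, strict = FALSE)
  tab[[task]] <- unique(c(tab[[task]], canon_label(alias)))
  .clx$aliases <- tab
  invisible(tab)
}

# resolve a user-supplied task name or gem label to a canonical task id;
# unknown labels pass through canonically (custom tasks) unless strict
resolve_task <- function(x, tab = gem_alias_table(), strict = FALSE) {
  cx <- canon_label(x)
  for (task in names(tab)) {
    if (cx == canon_label(task) || cx %in% tab[[task]]) return(task)
  }
  if (strict) stop("unknown task: ", x, call. = FALSE)
  x
}

new_utterance <- function(speaker, tokens, terminator = ".", mor = NULL,
                          deps = list(), unknown_codes = character(0),
                          raw_line = NA_character_, mor_warning = FALSE) {
  structure(
    list(speaker = toupper(speaker), tokens = tokens, terminator = terminator,
         mor = mor, deps = deps, unknown_codes = unknown_codes,
         raw_line = raw_line, mor_warning = mor_warning),
    class = "clx_utterance"
  )
}

new_transcript <- function(metadata, utterances, gems) {
  structure(list(metadata = metadata, utterances = utterances, gems = gems),
            class = "clx_transcript")
}

empty_gems <- function() {
  data.frame(label = character(0), start = integer(0), end = integer(0),
             style = character(0), stringsAsFactors = FALSE)
}

#' Parse CHAT transcript text
#'
#' Parses the CHAT subset used for core lexicon scoring: `@` header lines,
#' `*` speaker tiers with inline codes (`[: target]`, `[:: target]`,
#' `[* class]`, `[/]`, `[//]`, `&`-fillers, `xxx`/`yyy`/`www`), `%mor`
#' dependent tiers, and gem markers (`@G`, `@Bg`/`@Eg`). Unknown inline
#' codes are kept on the utterance (`unknown_codes`) and in `raw_line`;
#' other dependent tiers are preserved verbatim.
#'
#' `%mor` entries are aligned to the tokens CHAT morphology parses (plain
#' tokens that are not fillers, unintelligible material, or inside retrace /
#' repetition scopes). On an alignment mismatch the utterance is flagged
#' (`mor_warning`) and the tier is kept only as raw text.
#'
#' @param text CHAT file content: a single string or a character vector of
#'   lines.
#' @return A `clx_transcript`: list with `metadata` (data frame of header
#'   key/value pairs), `utterances` (list of utterances, each holding a
#'   token table and optional morphology), and `gems` (task segment table,
#'   1-based inclusive utterance ranges).
#' @examples
#' t <- parse_chat(c("*PAR:\tknocks it off the table.",
#'                   "%mor:\tv|knock-3S pro:per|it prep|off det:art|the n|table."))
#' t$utterances[[1]]$tokens$surface
#' @seealso [write_chat()], [read_chat()]
#' @export
parse_chat <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  # fold continuation lines (leading tab/space) into the preceding tier
  merged <- character(0)
  for (ln in lines) {
    if (grepl("^[ \t]", ln) && length(merged)) {
      merged[length(merged)] <- paste(merged[length(merged)], trimws(ln))
    } else {
      merged <- c(merged, ln)
    }
  }

  metadata <- data.frame(key = character(0), value = character(0),
                         stringsAsFactors = FALSE)
  utterances <- list()
  gems <- empty_gems()
  open_lazy <- NULL   # list(label, start)
  open_bg <- list()   # stack of list(label, start)

  close_lazy <- function() {
    if (!is.null(open_lazy) && open_lazy$start <= length(utterances)) {
      gems[nrow(gems) + 1L, ] <<- list(open_lazy$label, open_lazy$start,
                                       length(utterances), "lazy")
    }
    open_lazy <<- NULL
  }

  for (li in seq_along(merged)) {
    ln <- merged[li]
    if (!nzchar(trimws(ln))) next
    first <- substr(ln, 1L, 1L)
    if (first == "@") {
      if (grepl("^@Bg\\b", ln)) {
        close_lazy()
        label <- trimws(sub("^@Bg:?", "", ln))
        open_bg[[length(open_bg) + 1L]] <- list(label = label,
                                                start = length(utterances) + 1L)
      } else if (grepl("^@Eg\\b", ln)) {
        label <- trimws(sub("^@Eg:?", "", ln))
        if (length(open_bg)) {
          hit <- length(open_bg)
          if (nzchar(label)) {
            for (j in rev(seq_along(open_bg))) {
              if (canon_label(open_bg[[j]]$label) == canon_label(label)) {
                hit <- j; break
              }
            }
          }
          g <- open_bg[[hit]]
          open_bg[[hit]] <- NULL
          gems[nrow(gems) + 1L, ] <- list(g$label, g$start,
                                          length(utterances), "bounded")
        }
      } else if (grepl("^@G\\b", ln)) {
        close_lazy()
        label <- trimws(sub("^@G:?", "", ln))
        open_lazy <- list(label = label, start = length(utterances) + 1L)
      } else if (grepl("^@End\\b", ln)) {
        close_lazy()
      } else {
        m <- regmatches(ln, regexec("^@([^:]+):?[ \t]*(.*)$", ln))[[1]]
        metadata[nrow(metadata) + 1L, ] <- list(m[2], m[3])
      }
    } else if (first == "*") {
      m <- regmatches(ln, regexec("^\\*([^:]+):[ \t]*(.*)$", ln))[[1]]
      if (length(m) < 3L) {
        stop("line ", li, ": malformed main tier: ", ln, call. = FALSE)
      }
      tk <- tokenize_tier(m[3])
      utterances[[length(utterances) + 1L]] <-
        new_utterance(m[2], tk$tokens, terminator = tk$terminator,
                      unknown_codes = tk$unknown_codes, raw_line = ln)
    } else if (first == "%") {
      m <- regmatches(ln, regexec("^%([^:]+):[ \t]*(.*)$", ln))[[1]]
      if (length(m) < 3L || !length(utterances)) {
        stop("line ", li, ": dependent tier without main tier: ", ln,
             call. = FALSE)
      }
      u <- utterances[[length(utterances)]]
      name <- tolower(m[2])
      u$deps[[name]] <- m[3]
      if (name == "mor") {
        entries <- parse_mor_tier(m[3])
        expected <- sum(!is.na(u$tokens$mor_index))
        if (length(entries) == expected) {
          u$mor <- entries
        } else {
          u$mor_warning <- TRUE
        }
      }
      utterances[[length(utterances)]] <- u
    } else {
      stop("line ", li, ": not a header, main tier, or dependent tier: ",
           ln, call. = FALSE)
    }
  }
  close_lazy()
  for (g in open_bg) {
    gems[nrow(gems) + 1L, ] <- list(g$label, g$start, length(utterances),
                                    "bounded")
  }
  new_transcript(metadata, utterances, gems)
}

#' Read a CHAT file
#'
#' @param path Path to a `.cha` file.
#' @return A `clx_transcript`; see [parse_chat()].
#' @export
read_chat <- function(path) {
  out <- tryCatch(parse_chat(readLines(path, warn = FALSE, encoding = "UTF-8")),
                  error = function(e) {
                    stop(path, ": ", conditionMessage(e), call. = FALSE)
                  })
  out
}

# ---- writing ----

render_token_core <- function(tok) {
  s <- tok$surface
  if (tok$replacement_style == "single") {
    s <- paste0(s, " [: ", tok$replacement_target, "]")
  } else if (tok$replacement_style == "double") {
    s <- paste0(s, " [:: ", tok$replacement_target, "]")
  }
  if (nzchar(tok$error_codes)) {
    for (code in strsplit(tok$error_codes, ";", fixed = TRUE)[[1]]) {
      s <- paste0(s, " [* ", code, "]")
    }
  }
  s
}

render_utterance_body <- function(u) {
  tk <- u$tokens
  out <- character(0)
  i <- 1L
  while (i <= nrow(tk)) {
    g <- tk$scope_group[i]
    if (!is.na(g)) {
      idx <- which(!is.na(tk$scope_group) & tk$scope_group == g)
      mark <- if (tk$scope_role[i] == "retrace_material") "[//]" else "[/]"
      inner <- vapply(idx, function(j) render_token_core(tk[j, ]), "")
      grp <- if (length(idx) == 1L) inner else
        paste0("<", paste(inner, collapse = " "), ">")
      out <- c(out, paste(grp, mark))
      i <- max(idx) + 1L
    } else {
      out <- c(out, render_token_core(tk[i, ]))
      i <- i + 1L
    }
  }
  paste(c(out, u$terminator), collapse = " ")
}

# the stored %mor tier is only re-emitted while still aligned with the token
# table; reformatting (unhide_revisions) invalidates it, mirroring the need
# to re-run morphological tagging after reformatting
mor_is_current <- function(u) {
  if (is.null(u$mor)) return(FALSE)
  tk <- u$tokens
  parsed <- tk$scope_role == "plain" & !tk$is_filler & !tk$is_unintelligible
  sum(parsed) == length(u$mor) && !any(parsed & is.na(tk$mor_index))
}

#' Serialize a transcript back to CHAT text
#'
#' Writes the supported CHAT subset so that `parse_chat(write_chat(t))` is
#' equivalent to `t`. A stored `%mor` tier is re-emitted only while it still
#' aligns with the token table; after [unhide_revisions()] has made retrace
#' material scoreable the stale tier is dropped (the scoring pipeline then
#' uses the fallback analyzer, standing in for a morphology re-run). Other
#' dependent tiers are preserved verbatim.
#'
#' @param t A `clx_transcript`.
#' @param path Optional file path; when given, lines are written there.
#' @return Character vector of CHAT lines (invisibly when `path` is given).
#' @export
write_chat <- function(t, path = NULL) {
  lines <- "@Begin"
  if (nrow(t$metadata)) {
    keep <- !(t$metadata$key %in% c("Begin", "End"))
    lines <- c(lines, ifelse(
      nzchar(t$metadata$value[keep]),
      paste0("@", t$metadata$key[keep], ":\t", t$metadata$value[keep]),
      paste0("@", t$metadata$key[keep])
    ))
  }
  gems <- t$gems
  for (i in seq_along(t$utterances)) {
    if (nrow(gems)) {
      for (gi in which(gems$start == i)) {
        tag <- if (gems$style[gi] == "lazy") "@G:\t" else "@Bg:\t"
        lines <- c(lines, paste0(tag, gems$label[gi]))
      }
    }
    u <- t$utterances[[i]]
    lines <- c(lines, paste0("*", u$speaker, ":\t", render_utterance_body(u)))
    for (name in names(u$deps)) {
      if (name == "mor") {
        if (mor_is_current(u)) {
          raws <- vapply(u$mor, function(e) e$raw, "")
          lines <- c(lines, paste0("%mor:\t",
                                   paste(c(raws, u$terminator), collapse = " ")))
        }
      } else {
        lines <- c(lines, paste0("%", name, ":\t", u$deps[[name]]))
      }
    }
    if (nrow(gems)) {
      for (gi in which(gems$end == i & gems$style == "bounded")) {
        lines <- c(lines, paste0("@Eg:\t", gems$label[gi]))
      }
    }
  }
  lines <- c(lines, "@End")
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Select utterances by speaker code
#'
#' Speaker codes are matched case-insensitively; order is preserved. This is
#' how investigator speech is excluded from scoring (the `+t*par` switch of
#' the original command-line workflow).
#'
#' @param t A `clx_transcript`.
#' @param code Speaker tier code, e.g. `"PAR"`.
#' @return List of utterances (possibly empty), with the original utterance
#'   indices in attribute `"indices"`.
#' @export
select_speaker <- function(t, code) {
  idx <- which(vapply(t$utterances,
                      function(u) identical(toupper(u$speaker), toupper(code)),
                      logical(1)))
  structure(t$utterances[idx], indices = idx)
}

#' Extract one task's gem segment from a session transcript
#'
#' Resolves `task_id` against the gem labels in the transcript using the
#' task alias table (see [register_gem_alias()]) and returns the
#' sub-transcript between that task's gem markers, metadata preserved.
#'
#' @param t A `clx_transcript`.
#' @param task_id Canonical task id (e.g. `"CatRescue"`) or a gem label.
#' @return A `clx_transcript` containing only the task's utterances.
#' @export
extract_task_segment <- function(t, task_id) {
  if (!nrow(t$gems)) {
    stop("task \"", task_id, "\" absent: transcript has no gem markers",
         call. = FALSE)
  }
  want <- resolve_task(task_id)
  hit <- which(vapply(t$gems$label, function(l) {
    identical(resolve_task(l), want) || canon_label(l) == canon_label(task_id)
  }, logical(1)))
  if (!length(hit)) {
    stop("task \"", task_id, "\" absent; gems present: ",
         paste(unique(t$gems$label), collapse = ", "), call. = FALSE)
  }
  g <- t$gems[hit[1], ]
  idx <- seq.int(g$start, g$end)
  gems <- g
  gems$start <- 1L
  gems$end <- length(idx)
  new_transcript(t$metadata, t$utterances[idx], gems)
}

#' @export
print.clx_transcript <- function(x, ...) {
  cat("<CHAT transcript>\n")
  cat("  utterances:", length(x$utterances))
  if (length(x$utterances)) {
    cat(" (speakers: ",
        paste(unique(vapply(x$utterances, `[[`, "", "speaker")),
              collapse = ", "), ")", sep = "")
  }
  cat("\n  gems:", if (nrow(x$gems)) paste(x$gems$label, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
print.clx_utterance <- function(x, ...) {
  cat("*", x$speaker, ": ", render_utterance_body(x), "\n", sep = "")
  invisible(x)
}
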