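# Main-tier tokenizer for the supported CHAT subset.
#
# Recognised inline material:
#   <a b> [//]   retrace (revision): scoped words marked retrace_material
#   <a b> [/]    repetition: scoped words marked repetition_material
#   w [: t]      single-colon target replacement (target is analyzed)
#   w [:: t]     double-colon target replacement (surface is analyzed)
#   w [* s:r]    error class code attached to the preceding word
#   &-um &=laughs &um   fillers
#   xxx yyy www  unintelligible / untranscribed material
#   (be)cause    shortened forms (parentheses removed)
#   word@x       form markers (suffix stripped)
# Utterance terminators (. ? ! +... etc.) are stored separately; commas and
# other prosodic separators are dropped. Unknown [...] codes are kept on the
# utterance's unknown_codes field and in raw_line, never silently lost.

.clx_terminators <- c(".", "?", "!", "+...", "+..?", "+/.", "+//.", "+/?",
                      "+//?", "+\"/.", "+\".", "+!?")

.clx_unintelligible <- c("xxx", "yyy", "www")

# one row per produced token
.clx_empty_tokens <- function() {
  data.frame(
    surface = character(0),
    replacement_target = character(0),
    replacement_style = character(0),
    error_codes = character(0),
    scope_role = character(0),
    scope_group = integer(0),
    is_filler = logical(0),
    is_unintelligible = logical(0),
    mor_index = integer(0),
    stringsAsFactors = FALSE
  )
}

# Tokenize the text part of one main tier.  Returns list(tokens, terminator,
# unknown_codes).  Stops on unbalanced angle brackets.
tokenize_tier <- function(text) {
  text <- chartr("’", "'", text)
  n_open <- lengths(regmatches(text, gregexpr("<", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(">", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced <...> scope brackets in: ", text, call. = FALSE)
  }
  pat <- "<[^<>]*>|\\[[^][]*\\]|[^[:space:]<>\\[\\]]+"
  syms <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]

  surface <- character(0); target <- character(0); style <- character(0)
  errors <- character(0); scope <- character(0); group <- integer(0)
  filler <- logical(0); unint <- logical(0)
  pending <- integer(0)
  next_group <- 1L
  terminator <- "."
  unknown <- character(0)

  push <- function(word) {
    is_f <- grepl("^&", word)
    if (!is_f) {
      word <- gsub("[()]", "", word)
      word <- sub("@.*$", "", word)
      if (grepl("[.?!]+$", word)) {   # terminator glued to the last word
        terminator <<- regmatches(word, regexpr("[.?!]+$", word))
        word <- sub("[.?!]+$", "", word)
      }
      word <- sub(",+$", "", word)
    }
    is_u <- word %in% .clx_unintelligible
    if (!nzchar(word)) return(invisible(NULL))
    surface[length(surface) + 1L] <<- word
    target[length(target) + 1L] <<- NA_character_
    style[length(style) + 1L] <<- "none"
    errors[length(errors) + 1L] <<- ""
    scope[length(scope) + 1L] <<- "plain"
    group[length(group) + 1L] <<- NA_integer_
    filler[length(filler) + 1L] <<- is_f
    unint[length(unint) + 1L] <<- is_u
    invisible(length(surface))
  }

  for (sym in syms) {
    if (startsWith(sym, "<")) {
      inner <- trimws(substr(sym, 2L, nchar(sym) - 1L))
      words <- strsplit(inner, "[[:space:]]+")[[1]]
      idxs <- integer(0)
      for (w in words) {
        i <- push(w)
        if (!is.null(i)) idxs <- c(idxs, i)
      }
      pending <- idxs
    } else if (startsWith(sym, "[")) {
      body <- trimws(substr(sym, 2L, nchar(sym) - 1L))
      if (body %in% c("/", "//")) {
        role <- if (body == "//") "retrace_material" else "repetition_material"
        if (length(pending)) {
          scope[pending] <- role
          group[pending] <- next_group
          next_group <- next_group + 1L
        }
        pending <- integer(0)
      } else if (grepl("^::", body)) {
        if (length(pending)) {
          i <- pending[length(pending)]
          target[i] <- trimws(sub("^::", "", body))
          style[i] <- "double"
        }
      } else if (grepl("^:([[:space:]]|$)", body)) {
        if (length(pending)) {
          i <- pending[length(pending)]
          target[i] <- trimws(sub("^:", "", body))
          style[i] <- "single"
        }
      } else if (grepl("^\\*", body)) {
        if (length(pending)) {
          i <- pending[length(pending)]
          code <- trimws(sub("^\\*", "", body))
          errors[i] <- if (nzchar(errors[i])) paste(errors[i], code, sep = ";")
                       else code
        }
      } else {
        unknown <- c(unknown, sym)
      }
    } else if (sym %in% .clx_terminators || grepl("^[.?!]+$", sym)) {
      terminator <- sym
    } else if (grepl("^[+,‡„]", sym)) {
      # linkers / prosodic separators: ignorable, preserved via raw_line
    } else {
      i <- push(sym)
      if (!is.null(i)) pending <- i
    }
  }

  tokens <- data.frame(
    surface = surface, replacement_target = target,
    replacement_style = style, error_codes = errors,
    scope_role = scope, scope_group = group,
    is_filler = filler, is_unintelligible = unint,
    mor_index = NA_integer_, stringsAsFactors = FALSE
  )
  # tokens the %mor tier would parse get sequential indices; revision- and
  # repetition-scoped material, fillers and unintelligibles are skipped
  parsed <- tokens$scope_role == "plain" & !tokens$is_filler &
    !tokens$is_unintelligible
  tokens$mor_index[parsed] <- seq_len(sum(parsed))
  list(tokens = tokens, terminator = terminator, unknown_codes = unknown)
}

# ---- %mor tier ----

.clx_mor_punct_pos <- c("cm", "end", "bq", "eq", "beg", "bq2", "eq2")

# "v|knock-3S" / "pro:per|it~aux|be&3S" -> list(raw=, parts=data.frame)
parse_mor_word <- function(sym) {
  clean <- sub("[.?!]+$", "", sym)
  segs <- strsplit(clean, "~", fixed = TRUE)[[1]]
  lemma <- character(0); pos <- character(0); tags <- character(0)
  for (seg in segs) {
    bar <- regexpr("|", seg, fixed = TRUE)
    if (bar > 0) {
      p <- substr(seg, 1L, bar - 1L)
      stem <- substr(seg, bar + 1L, nchar(seg))
    } else {
      p <- NA_character_
      stem <- seg
    }
    lem <- sub("[-&].*$", "", stem)
    tg <- strsplit(sub("^[^-&]*[-&]?", "", stem), "[-&]")[[1]]
    lemma <- c(lemma, tolower(lem))
    pos <- c(pos, p)
    tags <- c(tags, paste(tg[nzchar(tg)], collapse = ";"))
  }
  list(raw = clean,
       parts = data.frame(lemma = lemma, pos = pos, tags = tags,
                          stringsAsFactors = FALSE))
}

# full %mor tier text -> list of mor-word entries (punctuation dropped)
parse_mor_tier <- function(text) {
  syms <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  syms <- syms[nzchar(syms)]
  out <- list()
  for (sym in syms) {
    if (grepl("^[.?!,]+$", sym)) next
    entry <- parse_mor_word(sym)
    if (nrow(entry$parts) == 1L &&
        !is.na(entry$parts$pos[1]) &&
        entry$parts$pos[1] %in% .clx_mor_punct_pos) next
    if (!nzchar(entry$parts$lemma[1])) next
    out[[length(out) + 1L]] <- entry
  }
  out
}
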