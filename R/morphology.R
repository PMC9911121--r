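# Fallback morphological analyzer: a bounded inflection lexicon.
#
# The scoring rules credit a checklist item for any inflected, contracted,
# or dialectal realisation of its lemma. When a transcript carries a %mor
# tier the lemma comes from there; otherwise this analyzer maps a surface
# form to its dictionary form using, in order:
#   1. the dialect table         (gonna -> going to -> go + to)
#   2. contraction handling      (isn't -> be + not; special forms won't, can't)
#   3. an inflection index built from irregular-verb / irregular-plural
#      tables plus regular paradigms generated over the package vocabulary
#   4. regular suffix heuristics (-s/-es, -ed, -ing, -ies, ...)
#   5. identity (lowercased surface), recorded as unanalyzed
# All tables are editable UTF-8 TSV files under extdata/morphology.

read_kv_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df
}

morph_tables <- function() {
  if (!is.null(.clx$morph)) return(.clx$morph)
  dir <- clx_extdata("morphology")
  irr_v <- read_kv_tsv(file.path(dir, "irregular_verbs.tsv"))
  irr_n <- read_kv_tsv(file.path(dir, "irregular_plurals.tsv"))
  contr <- read_kv_tsv(file.path(dir, "contractions.tsv"))
  dial <- read_kv_tsv(file.path(dir, "dialect.tsv"))
  verbs <- readLines(file.path(dir, "verbs.txt"), warn = FALSE)
  closed <- readLines(file.path(dir, "closed_class.txt"), warn = FALSE)
  strip_comments <- function(x) {
    x <- trimws(x[!grepl("^#", x)])
    x[nzchar(x)]
  }
  dialect <- setNames(strsplit(dial$expansion, ";", fixed = TRUE), dial$form)
  contractions <- setNames(
    lapply(seq_len(nrow(contr)), function(i) {
      list(lemma = contr$lemma[i], pos = contr$pos[i])
    }),
    contr$suffix
  )
  .clx$morph <- list(
    irregular_verbs = setNames(strsplit(irr_v$forms, ";", fixed = TRUE),
                               irr_v$base),
    irregular_plurals = setNames(irr_n$singular, irr_n$plural),
    contractions = contractions,
    dialect = dialect,
    verbs = strip_comments(verbs),
    closed = strip_comments(closed)
  )
  .clx$morph
}

# ---- regular paradigms ----

ends_with <- function(w, s) grepl(paste0(s, "$"), w)

regular_s_form <- function(w) {
  if (grepl("(s|x|z|ch|sh|o)$", w)) paste0(w, "es")
  else if (grepl("[^aeiou]y$", w)) paste0(sub("y$", "", w), "ies")
  else paste0(w, "s")
}

# final-consonant doubling: single vowel + single final consonant
doubles_final <- function(w) {
  grepl("^([^aeiou]*[aeiou])[bdgklmnprt]$", w) ||
    grepl("[^aeiou][aeiou][bdgklmnprt]$", w)
}

regular_past <- function(w) {
  if (ends_with(w, "e")) paste0(w, "d")
  else if (grepl("[^aeiou]y$", w)) paste0(sub("y$", "", w), "ied")
  else if (doubles_final(w)) paste0(w, substr(w, nchar(w), nchar(w)), "ed")
  else paste0(w, "ed")
}

regular_ing <- function(w) {
  if (ends_with(w, "ie")) paste0(sub("ie$", "", w), "ying")
  else if (ends_with(w, "e") && !ends_with(w, "ee")) paste0(sub("e$", "", w), "ing")
  else if (doubles_final(w)) paste0(w, substr(w, nchar(w), nchar(w)), "ing")
  else paste0(w, "ing")
}

# forward paradigm for one lemma given its (rough) word class
gen_regular_forms <- function(lemma, class) {
  switch(class,
         closed = character(0),
         verb = unique(c(regular_s_form(lemma), regular_past(lemma),
                         regular_ing(lemma))),
         unique(regular_s_form(lemma)))   # default: noun-like, plural only
}

lemma_class <- function(lemma, m = morph_tables()) {
  if (lemma %in% m$closed) "closed"
  else if (lemma %in% m$verbs || lemma %in% names(m$irregular_verbs)) "verb"
  else "noun"
}

# vocabulary the inflection index is generated over: checklist lemmas,
# distractor words, dialect expansions, irregular bases
inflection_vocab <- function() {
  m <- morph_tables()
  lex_lemmas <- unlist(lapply(builtin_tasks(), function(lx) {
    unlist(lx$items$accepted)
  }), use.names = FALSE)
  unique(c(names(m$irregular_verbs), m$verbs, lex_lemmas,
           distractor_words(), tolower(unlist(m$dialect, use.names = FALSE))))
}

#' @rdname analyze_surface
#' @export
distractor_words <- function() {
  if (is.null(.clx$distractors)) {
    x <- readLines(clx_extdata("distractors.txt"), warn = FALSE)
    x <- trimws(x[!grepl("^#", x)])
    .clx$distractors <- tolower(x[nzchar(x)])
  }
  .clx$distractors
}

# form -> lemma map plus lemma -> invertible forms map.
# Irregulars are registered first and win collisions; a colliding regular
# form is removed from the loser's forward list so generation stays exact.
inflection_index <- function() {
  if (!is.null(.clx$idx)) return(.clx$idx)
  m <- morph_tables()
  rev <- new.env(parent = emptyenv())
  fwd <- list()
  add <- function(form, lemma, tag) {
    if (form == lemma) return(TRUE)
    if (!is.null(rev[[form]])) return(FALSE)
    rev[[form]] <- c(lemma = lemma, tag = tag)
    TRUE
  }
  for (base in names(m$irregular_verbs)) {
    ok <- vapply(m$irregular_verbs[[base]], add, logical(1),
                 lemma = base, tag = "IRR")
    fwd[[base]] <- unique(c(base, m$irregular_verbs[[base]][ok]))
  }
  for (pl in names(m$irregular_plurals)) {
    sg <- m$irregular_plurals[[pl]]
    if (add(pl, sg, "PL")) fwd[[sg]] <- unique(c(fwd[[sg]], sg, pl))
  }
  for (lemma in sort(inflection_vocab())) {
    cls <- lemma_class(lemma, m)
    forms <- gen_regular_forms(lemma, cls)
    kept <- forms[vapply(forms, add, logical(1), lemma = lemma, tag = "REG")]
    fwd[[lemma]] <- unique(c(fwd[[lemma]], lemma, kept))
  }
  .clx$idx <- list(rev = rev, fwd = fwd)
  .clx$idx
}

# regular suffix-stripping heuristics for out-of-vocabulary forms;
# returns c(lemma, tag) or NULL
strip_suffix <- function(w) {
  n <- nchar(w)
  if (ends_with(w, "ies") && n > 4) return(c(sub("ies$", "y", w), "PL"))
  if (ends_with(w, "ied") && n > 4) return(c(sub("ied$", "y", w), "PAST"))
  if (ends_with(w, "oes") && n > 3) return(c(sub("es$", "", w), "3S"))
  if (grepl("(s|x|z|ch|sh)es$", w)) return(c(sub("es$", "", w), "PL"))
  if (ends_with(w, "s") && !grepl("(ss|us|is)$", w) && n > 2) {
    return(c(sub("s$", "", w), "PL"))
  }
  if (ends_with(w, "ing") && n > 4) {
    stem <- sub("ing$", "", w)
    if (nchar(stem) > 2 &&
        substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1L, nchar(stem) - 1L) &&
        !grepl("(ll|ss)$", stem)) {
      stem <- substr(stem, 1L, nchar(stem) - 1L)
    }
    return(c(stem, "PRESP"))
  }
  if (ends_with(w, "ed") && n > 3) {
    stem <- sub("ed$", "", w)
    if (nchar(stem) > 2 &&
        substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1L, nchar(stem) - 1L) &&
        !grepl("(ll|ss)$", stem)) {
      stem <- substr(stem, 1L, nchar(stem) - 1L)
    }
    return(c(stem, "PAST"))
  }
  NULL
}

mor_part <- function(lemma, pos = NA_character_, tags = "") {
  data.frame(lemma = lemma, pos = pos, tags = tags, stringsAsFactors = FALSE)
}

analyze_single <- function(w) {
  m <- morph_tables()
  idx <- inflection_index()
  cls_pos <- function(l) switch(lemma_class(l, m), verb = "v",
                                closed = "x", "n")
  hit <- idx$rev[[w]]
  if (!is.null(hit)) {
    return(list(parts = mor_part(hit[["lemma"]], cls_pos(hit[["lemma"]]),
                                 hit[["tag"]]),
                analyzed = TRUE))
  }
  if (w %in% names(idx$fwd) || w %in% m$closed) {
    return(list(parts = mor_part(w, cls_pos(w)), analyzed = TRUE))
  }
  s <- strip_suffix(w)
  if (!is.null(s)) {
    return(list(parts = mor_part(s[1], NA_character_, s[2]), analyzed = TRUE))
  }
  list(parts = mor_part(w), analyzed = FALSE)
}

#' Analyze a surface word form into lemma, tags, and clitic parts
#'
#' The fallback morphological analyzer used when a transcript carries no
#' usable `%mor` tier, and for material that tier never covers (words made
#' scoreable by reformatting, surfaces behind double-colon replacements).
#' It implements the scoring equivalences: regular and irregular plurals
#' and verb inflections reduce to their dictionary form; contractions split
#' into their components (`"isn't"` counts both *be* and *not*); dialect
#' forms expand to their standard equivalents (`"gonna"` counts both *go*
#' and *to*). Unknown forms pass through with the lowercased surface as the
#' lemma and `analyzed = FALSE`.
#'
#' `distractor_words()` returns the packaged filler vocabulary used by the
#' synthetic generator; every entry analyzes to a lemma outside all built-in
#' checklists.
#'
#' @param surface A single orthographic word.
#' @return List with `surface` (normalized), `lemma` (first part), `pos`,
#'   `tags`, `parts` (data frame, one row per component; several rows for
#'   contractions and dialect forms), and `analyzed`.
#' @examples
#' analyze_surface("went")$lemma    # "go"
#' analyze_surface("isn't")$parts$lemma  # "be" "not"
#' analyze_surface("gonna")$parts$lemma  # "go" "to"
#' @export
analyze_surface <- function(surface) {
  stopifnot(is.character(surface), length(surface) == 1L)
  w <- tolower(trimws(surface))
  w <- chartr("’", "'", w)
  w <- gsub("[()]", "", w)
  w <- sub("@.*$", "", w)
  w <- gsub("[.,!?;:]+$", "", w)
  m <- morph_tables()
  out <- NULL
  analyzed <- TRUE
  if (w %in% names(m$dialect)) {
    parts <- do.call(rbind, lapply(m$dialect[[w]], function(comp) {
      analyze_single(tolower(comp))$parts
    }))
    parts$tags[1] <- paste(c("DIAL", parts$tags[1][nzchar(parts$tags[1])]),
                           collapse = ";")
    out <- parts
  } else if (grepl("'", w, fixed = TRUE)) {
    suffixes <- names(m$contractions)
    hit <- suffixes[vapply(suffixes, function(s) endsWith(w, s), logical(1))]
    if (length(hit)) {
      hit <- hit[which.max(nchar(hit))]
      base <- substr(w, 1L, nchar(w) - nchar(hit))
      cl <- m$contractions[[hit]]
      clitics <- mor_part(cl$lemma, cl$pos)
      if (nzchar(base)) {
        ba <- analyze_single(base)
        out <- rbind(ba$parts, clitics)
      } else {
        out <- clitics
      }
    } else {
      a <- analyze_single(w)
      out <- a$parts
      analyzed <- a$analyzed
    }
  } else {
    a <- analyze_single(w)
    out <- a$parts
    analyzed <- a$analyzed
  }
  out$lemma <- tolower(out$lemma)
  list(surface = w, lemma = out$lemma[1], pos = out$pos[1],
       tags = out$tags[1], parts = out, analyzed = analyzed)
}

# forms of a lemma that are guaranteed to analyze back to it (generator use)
invertible_forms <- function(lemma) {
  idx <- inflection_index()
  f <- idx$fwd[[lemma]]
  if (is.null(f)) lemma else f
}

# pick a (possibly inflected) surface realisation of a lemma
inflect_form <- function(lemma) {
  forms <- invertible_forms(lemma)
  if (length(forms) == 1L) return(forms)
  # favour the base form, as real discourse does
  w <- c(2, rep(1, length(forms) - 1L))
  sample(forms, 1L, prob = w / sum(w))
}
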