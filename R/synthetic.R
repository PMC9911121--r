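# Synthetic CHAT transcript generator with exact ground-truth scores.
#
# The generator emulates the surface phenomena that make checklist scoring
# non-trivial — inflected realisations, fillers, retraces and repetitions,
# coded semantic and phonemic paraphasias, dialect forms — while keeping
# the implied checklist score exact by construction: distractor vocabulary
# is packaged disjoint from every checklist's accepted-lemma set, retrace
# material is drawn from distractors, and paraphasia targets are tracked
# directly into the ground truth.

#' Configuration for the synthetic transcript generator
#'
#' @param task_id Task whose checklist the transcript responds to.
#' @param coverage Probability that a checklist item is produced. A single
#'   value, or a length-2 range from which each transcript draws its own
#'   coverage — the default range emulates the wide severity spread of
#'   aphasia cohorts, which is what gives real corpora their large
#'   between-sample score variance.
#' @param filler_rate,retrace_rate,repetition_rate Per-token probabilities
#'   of inserting a filler, a retrace (`<...> [//]`, revised material drawn
#'   from distractors), or a verbatim repetition (`w [/] w`).
#' @param semantic_paraphasia_rate Per-item probability of inserting a
#'   coded semantic paraphasia `wrong [: target] [* s:r]` whose target is
#'   an unproduced checklist item (never credited in the ground truth).
#' @param phonemic_paraphasia_rate Per-item probability of inserting a
#'   coded phonemic paraphasia `nonce [: target] [* p:n]` (the target is
#'   credited).
#' @param dialect_rate Per-item probability of inserting a dialect form
#'   (e.g. `gonna`); checklist items covered by its expansion are credited.
#' @param distractor_vocab_size Number of distinct non-checklist words
#'   available as distractors.
#' @param include_mor Emit a `%mor` tier consistent with the main tier.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return A `clx_genconfig` list.
#' @export
generation_config <- function(task_id = "BrokenWindow",
                              coverage = c(0.35, 0.95),
                              filler_rate = 0.08,
                              retrace_rate = 0.04,
                              repetition_rate = 0.05,
                              semantic_paraphasia_rate = 0.02,
                              phonemic_paraphasia_rate = 0.02,
                              dialect_rate = 0.03,
                              distractor_vocab_size = 40,
                              include_mor = TRUE,
                              seed = NULL) {
  probs <- c(coverage, filler_rate, retrace_rate, repetition_rate,
             semantic_paraphasia_rate, phonemic_paraphasia_rate,
             dialect_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all rates and coverage values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(coverage) %in% 1:2, distractor_vocab_size >= 1)
  structure(list(task_id = task_id, coverage = coverage,
                 filler_rate = filler_rate, retrace_rate = retrace_rate,
                 repetition_rate = repetition_rate,
                 semantic_paraphasia_rate = semantic_paraphasia_rate,
                 phonemic_paraphasia_rate = phonemic_paraphasia_rate,
                 dialect_rate = dialect_rate,
                 distractor_vocab_size = distractor_vocab_size,
                 include_mor = include_mor, seed = seed),
            class = "clx_genconfig")
}

# a nonce form for phonemic paraphasias: first letter substituted, checked
# against the inflection index and accepted lemmas so it never credits
nonce_form <- function(word, accepted) {
  for (ch in c("z", "v", "q", "j", "x", "k", "b")) {
    cand <- paste0(ch, substr(word, 2L, nchar(word)))
    if (cand == word) next
    an <- analyze_surface(cand)
    if (!any(an$parts$lemma %in% accepted)) return(cand)
  }
  paste0("z", word, "z")
}

render_mor_sym <- function(an) {
  parts <- an$parts
  syms <- vapply(seq_len(nrow(parts)), function(i) {
    pos <- parts$pos[i]
    if (is.na(pos) || !nzchar(pos)) pos <- "x"
    tg <- parts$tags[i]
    paste0(pos, "|", parts$lemma[i],
           if (!is.na(tg) && nzchar(tg)) {
             paste0("-", gsub(";", "-", tg))
           } else "")
  }, "")
  paste(syms, collapse = "~")
}

# %mor line for one tokenized utterance body (mirrors tier alignment rules)
mor_line_for <- function(body, terminator) {
  tk <- tokenize_tier(paste(body, terminator))$tokens
  parsed <- which(!is.na(tk$mor_index))
  syms <- vapply(parsed, function(i) {
    word <- if (tk$replacement_style[i] == "single") {
      tk$replacement_target[i]
    } else {
      tk$surface[i]
    }
    render_mor_sym(analyze_surface(word))
  }, "")
  paste0("%mor:\t", paste(c(syms, terminator), collapse = " "))
}

#' Generate a synthetic CHAT transcript with known ground truth
#'
#' Produces a parseable transcript for one task — header, gem marker, an
#' investigator prompt, and participant utterances of 4–9 token units —
#' together with the exact checklist score it implies.
#'
#' @param cfg A [generation_config()].
#' @param lex Checklist to generate against (default: the built-in list for
#'   `cfg$task_id`).
#' @param sample_id Identifier recorded on the ground-truth score.
#' @return List with `transcript` (`clx_transcript`), `truth`
#'   (`clx_score`), and `lines` (the CHAT text).
#' @export
generate_transcript <- function(cfg, lex = builtin_lexicon(cfg$task_id),
                                sample_id = "synth") {
  stopifnot(inherits(cfg, "clx_genconfig"), inherits(lex, "clx_lexicon"))
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)

  labels <- lex$items$label
  n_items <- length(labels)
  accepted_all <- unlist(lex$items$accepted)
  credited <- setNames(logical(n_items), labels)

  p_cov <- if (length(cfg$coverage) == 2L) {
    stats::runif(1, cfg$coverage[1], cfg$coverage[2])
  } else {
    cfg$coverage
  }

  units <- character(0)

  # checklist items actually produced, randomly inflected
  produced <- stats::runif(n_items) < p_cov
  for (i in which(produced)) {
    lemma <- sample(lex$items$accepted[[i]], 1L)
    units <- c(units, inflect_form(lemma))
    credited[i] <- TRUE
  }

  # distractor stream
  pool <- distractor_words()
  pool <- pool[!pool %in% accepted_all]
  pool <- sample(pool, min(cfg$distractor_vocab_size, length(pool)))
  n_d <- max(3L, round(0.8 * n_items))
  units <- c(units, sample(pool, n_d, replace = TRUE))

  # coded semantic paraphasias: target = an unproduced item, never credited
  open <- labels[!credited]
  n_sem <- min(stats::rbinom(1L, n_items, cfg$semantic_paraphasia_rate),
               length(open))
  if (n_sem > 0) {
    for (tgt in sample(open, n_sem)) {
      units <- c(units,
                 paste0(sample(pool, 1L), " [: ", tgt, "] [* s:r]"))
    }
  }

  # coded phonemic paraphasias: target credited
  n_ph <- stats::rbinom(1L, n_items, cfg$phonemic_paraphasia_rate)
  if (n_ph > 0) {
    for (tgt in sample(labels, min(n_ph, n_items))) {
      units <- c(units,
                 paste0(nonce_form(tgt, accepted_all), " [: ", tgt,
                        "] [* p:n]"))
      credited[tgt] <- TRUE
    }
  }

  # dialect forms; items covered by the expansion are credited
  m <- morph_tables()
  n_dial <- stats::rbinom(1L, n_items, cfg$dialect_rate)
  if (n_dial > 0) {
    for (dw in sample(names(m$dialect), n_dial, replace = TRUE)) {
      units <- c(units, dw)
      lemmas <- analyze_surface(dw)$parts$lemma
      for (i in seq_len(n_items)) {
        if (any(lemmas %in% lex$items$accepted[[i]])) credited[i] <- TRUE
      }
    }
  }

  units <- sample(units)

  # token-level decoration
  decorated <- character(0)
  for (u in units) {
    if (stats::runif(1) < cfg$filler_rate) {
      decorated <- c(decorated, sample(c("&-um", "&-uh"), 1L))
    }
    if (stats::runif(1) < cfg$retrace_rate) {
      rw <- sample(pool, sample(1:2, 1L), replace = TRUE)
      decorated <- c(decorated, if (length(rw) == 1L) {
        paste(rw, "[//]")
      } else {
        paste0("<", paste(rw, collapse = " "), "> [//]")
      })
    }
    plain_word <- !grepl("[][]", u)
    if (plain_word && stats::runif(1) < cfg$repetition_rate) {
      u <- paste(u, "[/]", u)
    }
    decorated <- c(decorated, u)
  }

  # 4-9 units per utterance
  bodies <- character(0)
  i <- 1L
  while (i <= length(decorated)) {
    take <- min(sample(4:9, 1L), length(decorated) - i + 1L)
    bodies <- c(bodies, paste(decorated[i:(i + take - 1L)], collapse = " "))
    i <- i + take
  }
  if (!length(bodies)) bodies <- "xxx"

  lines <- c(
    "@Begin",
    "@Languages:\teng",
    "@Participants:\tPAR Participant, INV Investigator",
    paste0("@ID:\teng|synthetic|PAR||||", lex$task_id, "|Participant|||"),
    paste0("@G:\t", lex$task_id)
  )
  inv_body <- "tell me the story"
  lines <- c(lines, paste0("*INV:\t", inv_body, " ."))
  if (cfg$include_mor) lines <- c(lines, mor_line_for(inv_body, "."))
  for (b in bodies) {
    lines <- c(lines, paste0("*PAR:\t", b, " ."))
    if (cfg$include_mor) lines <- c(lines, mor_line_for(b, "."))
  }
  lines <- c(lines, "@End")

  truth <- new_checklist_score(sample_id, lex$task_id,
                               setNames(as.integer(credited), labels),
                               lex$hash)
  list(transcript = parse_chat(lines), truth = truth, lines = lines)
}

derive_seed <- function(master, i) {
  if (is.null(master)) return(NULL)
  as.integer((as.double(master) * 7919 + i * 104729) %% 2147483629)
}

#' Generate a synthetic corpus of CHAT files with a truth table
#'
#' Writes `n` transcripts (independent per-file seeds derived from the
#' master seed in `cfg`) plus `truth.csv`, the ground-truth score table.
#'
#' @param n Number of transcripts.
#' @param cfg A [generation_config()].
#' @param dir Output directory (created if needed).
#' @param lex Checklist (default: built-in list for `cfg$task_id`).
#' @return List with `dir`, `files`, and `truth` (score table).
#' @export
generate_corpus <- function(n, cfg, dir = tempfile("corpus"),
                            lex = builtin_lexicon(cfg$task_id)) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    sid <- sprintf("synth%03d", i)
    g <- generate_transcript(cfg_i, lex, sample_id = sid)
    files[i] <- file.path(dir, paste0(sid, ".cha"))
    writeLines(g$lines, files[i], useBytes = TRUE)
    truths[[i]] <- g$truth
  }
  truth <- score_table(truths)
  write_scores(truth, file.path(dir, "truth.csv"))
  list(dir = dir, files = files, truth = truth)
}

#' Simulate a manual scorer that commits omission errors
#'
#' Manual checklist-scoring errors are overwhelmingly omissions: the item
#' was produced but the scorer missed it. This simulator flips credited
#' cells (1) to 0 independently with the given omission rate and never
#' invents credits.
#'
#' @param truth A score table (typically a generator truth table).
#' @param omission_rate Per-cell probability of missing a credited item.
#' @param seed RNG seed.
#' @return A score table with omissions applied and totals recomputed.
#' @export
simulate_manual_scorer <- function(truth, omission_rate, seed = NULL) {
  stopifnot(omission_rate >= 0, omission_rate <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  items <- attr(truth, "item_labels")
  out <- truth
  for (it in items) {
    ones <- which(out[[it]] == 1L)
    if (length(ones)) {
      drop <- ones[stats::runif(length(ones)) < omission_rate]
      out[[it]][drop] <- 0L
    }
  }
  out$total <- as.integer(rowSums(out[, items, drop = FALSE]))
  out
}
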