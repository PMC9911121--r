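# Inter-method reliability: two-way random absolute-agreement ICC with
# F-based confidence interval, interpretation bands, item-level discrepancy
# audit, and error-proportion summaries.

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Computes the ICC for a samples-by-methods ratings matrix under the
#' two-way random-effects model with absolute agreement — the statistic
#' used to validate automated against manual checklist scoring. Absolute
#' agreement (unlike consistency) penalizes systematic offsets between
#' methods. From the two-way ANOVA mean squares (rows = samples MSR,
#' columns = methods MSC, residual MSE), single-measures:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' and average-measures \eqn{ICC(A,k) = (MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)}.
#' The confidence interval uses the F-distribution method of McGraw & Wong
#' (1996) with Satterthwaite degrees of freedom; average-measures limits are
#' the Spearman–Brown step-up of the single-measures limits.
#'
#' @param m Numeric matrix or data frame, n samples (rows) x k methods
#'   (columns), n >= 2, k >= 2, no missing cells.
#' @param type `"single"` (each sample rated once per method; default) or
#'   `"average"`.
#' @param conf Confidence level (default 0.95).
#' @return A `clx_icc`: list with `icc`, `ci_low`, `ci_high`, `band` (see
#'   [interpret_icc()]), `model`, `type`, mean squares `ms_rows`,
#'   `ms_cols`, `ms_error`, dimensions `n`, `k`, and `degenerate` (TRUE
#'   when all cells are equal, in which case the ICC is defined as 1).
#' @examples
#' m <- cbind(rater1 = c(9, 6, 8, 7, 10, 6), rater2 = c(2, 1, 4, 1, 5, 2))
#' icc_agreement(m)
#' @export
icc_agreement <- function(m, type = c("single", "average"), conf = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(m)) stop("ratings matrix has missing cells", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 samples and 2 methods",
                           call. = FALSE)
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  degenerate <- sst < .Machine$double.eps * length(m)
  if (degenerate) {
    icc1 <- 1
    ci1 <- c(1, 1)
  } else {
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse == 0 && msc == 0) {
      ci1 <- c(1, 1)
    } else {
      alpha <- 1 - conf
      a <- (k * icc1) / (n * (1 - icc1))
      b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
      if (!is.finite(a)) {           # icc1 == 1 with noise-free agreement
        ci1 <- c(1, 1)
      } else {
        v <- (a * msc + b * mse)^2 /
          ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
        fl <- stats::qf(1 - alpha / 2, n - 1, v)
        fu <- stats::qf(1 - alpha / 2, v, n - 1)
        lo <- n * (msr - fl * mse) /
          (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
        hi <- n * (fu * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fu * msr)
        ci1 <- c(min(lo, icc1), max(hi, icc1))
      }
    }
  }

  if (type == "single") {
    icc <- icc1
    ci <- ci1
  } else {
    sb <- function(r) ifelse(r >= 1, 1, k * r / (1 + (k - 1) * r))
    icc <- if (degenerate) 1 else (msr - mse) / (msr + (msc - mse) / n)
    ci <- sb(ci1)
    ci <- c(min(ci[1], icc), max(ci[2], icc))
  }

  structure(list(
    icc = icc, ci_low = ci[1], ci_high = ci[2], conf = conf,
    band = interpret_icc(icc),
    model = "two-way random, absolute agreement",
    type = type, ms_rows = msr, ms_cols = msc, ms_error = mse,
    n = n, k = k, degenerate = degenerate
  ), class = "clx_icc")
}

#' Interpret an ICC value as a reliability band
#'
#' Standard interpretation bands: poor below .5, moderate from .5, good
#' from .75, excellent from .9 (boundaries left-closed).
#'
#' @param value ICC point estimate(s), each at most 1.
#' @return Character vector of band labels.
#' @examples
#' interpret_icc(c(0.49, 0.5, 0.75, 0.978))
#' @export
interpret_icc <- function(value) {
  stopifnot(all(value <= 1 + 1e-12))
  as.character(cut(value, c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
                   labels = c("poor", "moderate", "good", "excellent")))
}

#' Item-level discrepancy audit between two scoring modalities
#'
#' Lists every (sample, item) cell where the two score tables disagree,
#' with the direction of the disagreement (`a_only`: credited by `a` but
#' not `b`; `b_only`: the reverse). Both tables must cover the same
#' samples, task, and checklist version.
#'
#' @param a,b Score tables ([batch_score()] / [read_scores()]).
#' @return A `clx_discrepancy`: tibble with `sample_id`, `item`,
#'   `value_a`, `value_b`, `direction`; direction counts in attribute
#'   `"counts"`. Empty iff the tables agree cell-for-cell.
#' @export
compare_modalities <- function(a, b) {
  ta <- attr(a, "task_id"); tb <- attr(b, "task_id")
  if (!is.na(ta) && !is.na(tb) && !identical(ta, tb)) {
    stop("task mismatch: ", ta, " vs ", tb, call. = FALSE)
  }
  ha <- attr(a, "lexicon_hash"); hb <- attr(b, "lexicon_hash")
  if (!is.null(ha) && !is.null(hb) && !is.na(ha) && !is.na(hb) &&
      !identical(ha, hb)) {
    stop("checklist version mismatch: scores were produced against ",
         "different lexicons", call. = FALSE)
  }
  if (!setequal(a$sample_id, b$sample_id) ||
      anyDuplicated(a$sample_id) || anyDuplicated(b$sample_id)) {
    stop("sample mismatch between the two score tables", call. = FALSE)
  }
  items <- intersect(attr(a, "item_labels") %||%
                       setdiff(names(a), c("sample_id", "task", "total")),
                     attr(b, "item_labels") %||%
                       setdiff(names(b), c("sample_id", "task", "total")))
  if (!length(items)) stop("no common item columns", call. = FALSE)
  b <- b[match(a$sample_id, b$sample_id), ]
  rows <- list()
  for (it in items) {
    diff <- which(a[[it]] != b[[it]])
    for (i in diff) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = a$sample_id[i], item = it,
        value_a = a[[it]][i], value_b = b[[it]][i],
        direction = if (a[[it]][i] == 1) "a_only" else "b_only"
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(sample_id = character(0), item = character(0),
                   value_a = integer(0), value_b = integer(0),
                   direction = character(0))
  out <- out[order(out$sample_id, out$item), ]
  attr(out, "counts") <- c(a_only = sum(out$direction == "a_only"),
                           b_only = sum(out$direction == "b_only"))
  class(out) <- c("clx_discrepancy", class(out))
  out
}

#' Proportion of scoring errors out of the total error opportunities
#'
#' `n_errors / (n_items * n_samples)`: each checklist item on each sample
#' is one opportunity for a scoring error.
#'
#' @param n_errors Number of scoring errors observed.
#' @param n_items Checklist length.
#' @param n_samples Number of samples scored.
#' @return Fraction in \[0, 1\].
#' @examples
#' error_proportion(13, 24, 48)  # ~0.0113
#' @export
error_proportion <- function(n_errors, n_items, n_samples) {
  stopifnot(n_errors >= 0, n_items >= 0, n_samples >= 0)
  if (n_items * n_samples == 0) {
    stop("zero error opportunities: n_items * n_samples must be positive",
         call. = FALSE)
  }
  n_errors / (n_items * n_samples)
}

#' Totals matrix for reliability analysis
#'
#' Joins two score tables on sample id into the n x 2 ratings matrix of
#' totals that [icc_agreement()] consumes.
#'
#' @param a,b Score tables.
#' @param labels Column (method) labels.
#' @return Numeric matrix with sample ids as row names.
#' @export
totals_matrix <- function(a, b, labels = c("a", "b")) {
  if (!setequal(a$sample_id, b$sample_id)) {
    stop("sample mismatch between the two score tables", call. = FALSE)
  }
  b <- b[match(a$sample_id, b$sample_id), ]
  m <- cbind(a$total, b$total)
  dimnames(m) <- list(a$sample_id, labels)
  m
}

#' @export
print.clx_icc <- function(x, ...) {
  cat("ICC (", x$model, ", ", x$type, " measures)\n", sep = "")
  cat(sprintf("  ICC = %.4f, %d%% CI [%.4f, %.4f] — %s\n", x$icc,
              round(100 * x$conf), x$ci_low, x$ci_high, x$band))
  cat(sprintf("  MS rows %.4f, MS cols %.4f, MS error %.4f (n=%d, k=%d)\n",
              x$ms_rows, x$ms_cols, x$ms_error, x$n, x$k))
  if (x$degenerate) cat("  note: zero total variance; ICC defined as 1\n")
  invisible(x)
}

#' @export
print.clx_discrepancy <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("<discrepancy report>", nrow(x), "disagreeing cells (a_only:",
      counts[["a_only"]], ", b_only:", counts[["b_only"]], ")\n")
  if (nrow(x)) print(tibble::as_tibble(unclass(x)[names(x)]))
  invisible(x)
}
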