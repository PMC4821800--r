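# Document-level scoring of system annotations against a gold standard.
#
# A "positive" is a document for which the system emits an annotation for the
# characteristic under evaluation; a true positive additionally requires the
# value to agree with gold (sex: same category; age: same day-normalized
# range, optionally within a small tolerance).

#' Document-level confusion matrix
#'
#' Per document: gold reported & system reported & values agree = TP;
#' system reported & (gold absent or values disagree) = FP; gold reported &
#' system absent = FN; both absent = TN.  A system report with the wrong
#' value therefore counts once, as a false positive, so
#' `tp + tn + fp + fn` equals the number of evaluated documents.
#'
#' @param system An annotation tibble (see [annotate_document()]).
#' @param gold A gold tibble (see [read_gold_annotations()]); every system
#'   `doc_id` must have a gold entry, otherwise an error lists the offenders.
#' @param characteristic `"sex"` or `"age"`.
#' @param age_tolerance_days Age ranges agree if both endpoints match within
#'   this many days after unit normalization (default 0: exact equality).
#' @return An object of class `mr_confusion`: a list with integer fields
#'   `tp`, `tn`, `fp`, `fn`, plus `n` and `characteristic`.
#' @export
confusion_matrix <- function(system, gold,
                             characteristic = c("sex", "age"),
                             age_tolerance_days = 0) {
  characteristic <- match.arg(characteristic)
  missing <- setdiff(system$doc_id, gold$doc_id)
  if (length(missing) > 0) {
    stop("no gold annotation for doc_id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- gold[match(system$doc_id, gold$doc_id), ]
  if (characteristic == "sex") {
    sys_rep <- system$sex_status != "none"
    gold_rep <- g$sex_status != "none"
    agree <- sys_rep & gold_rep & system$sex_status == g$sex_status
  } else {
    sys_rep <- system$age_status != "none"
    gold_rep <- g$age_status != "none"
    agree <- rep(FALSE, nrow(system))
    both <- which(sys_rep & gold_rep)
    if (length(both) > 0) {
      s_d <- normalize_age_table(system[both, c("age_min", "age_max", "age_unit")])
      g_d <- normalize_age_table(g[both, c("age_min", "age_max", "age_unit")])
      agree[both] <- abs(s_d$min_days - g_d$min_days) <= age_tolerance_days &
        abs(s_d$max_days - g_d$max_days) <= age_tolerance_days
    }
  }
  tp <- sum(agree)
  fp <- sum(sys_rep & !agree)
  fn <- sum(!sys_rep & gold_rep)
  tn <- sum(!sys_rep & !gold_rep)
  structure(
    list(tp = as.integer(tp), tn = as.integer(tn), fp = as.integer(fp),
         fn = as.integer(fn), n = nrow(system),
         characteristic = characteristic),
    class = "mr_confusion"
  )
}

#' @export
print.mr_confusion <- function(x, ...) {
  cat(sprintf("<mr_confusion: %s> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$characteristic, x$tp, x$tn, x$fp, x$fn, x$n))
  invisible(x)
}

# confusion matrix from raw counts (e.g. a published evaluation table)
#' @rdname confusion_matrix
#' @param tp,tn,fp,fn Non-negative integer document counts.
#' @export
confusion_counts <- function(tp, tn = 0, fp = 0, fn = 0,
                             characteristic = "sex") {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(
    list(tp = as.integer(tp), tn = as.integer(tn), fp = as.integer(fp),
         fn = as.integer(fn), n = as.integer(tp + tn + fp + fn),
         characteristic = characteristic),
    class = "mr_confusion"
  )
}

#' Precision, recall and F-score on the percent scale
#'
#' `precision()` is `100 * tp / (tp + fp)`, `recall()` is
#' `100 * tp / (tp + fn)`, and `f_score(p, r)` is the harmonic mean
#' `2 * p * r / (p + r)` of two percentages.  Undefined cases
#' (`tp + fp == 0`, `tp + fn == 0`, `p + r == 0`) are signalled by a warning
#' and return `NA`, never 0.
#'
#' @param cm An `mr_confusion` object.
#' @return A percentage in `[0, 100]` (unrounded; see [present_pct()] for the
#'   one-decimal presentation form).
#' @examples
#' precision(confusion_counts(tp = 29, tn = 16, fp = 3, fn = 2))
#' @export
precision <- function(cm) {
  if (cm$tp + cm$fp == 0) {
    warning("precision undefined: tp + fp = 0", call. = FALSE)
    return(NA_real_)
  }
  100 * cm$tp / (cm$tp + cm$fp)
}

#' @rdname precision
#' @export
recall <- function(cm) {
  if (cm$tp + cm$fn == 0) {
    warning("recall undefined: tp + fn = 0", call. = FALSE)
    return(NA_real_)
  }
  100 * cm$tp / (cm$tp + cm$fn)
}

#' @rdname precision
#' @param p,r Precision and recall percentages.
#' @export
f_score <- function(p, r) {
  if (is.na(p) || is.na(r) || p + r == 0) {
    warning("F-score undefined: p + r = 0 (or undefined input)",
            call. = FALSE)
    return(NA_real_)
  }
  2 * p * r / (p + r)
}

#' Present a percentage to one decimal (truncation)
#'
#' Published evaluation tables of this kind truncate rather than round:
#' truncation reproduces e.g. 90.625 -> 90.6, 96.875 -> 96.8,
#' 88.571 -> 88.5 — and, applied to an F-score computed from the truncated
#' P/R pair, 92.46 -> 92.4.  Raw unrounded values are exposed alongside.
#'
#' @param x A percentage (vectorized).
#' @return `x` truncated to one decimal.
#' @export
present_pct <- function(x) {
  floor(x * 10 + 1e-9) / 10
}

#' Evaluate system annotations against gold
#'
#' Builds the document-level confusion matrix for each characteristic and
#' derives precision, recall and F-score.  Displayed metrics are presented to
#' one decimal by truncation, with the F-score computed from the presented
#' P/R pair (matching how such tables are laid out); `_raw` columns carry the
#' unrounded values, with `f_score_raw` computed from unrounded P and R.
#'
#' @inheritParams confusion_matrix
#' @param characteristics Which characteristics to score.
#' @return A tibble with one row per characteristic: `characteristic`, `tp`,
#'   `tn`, `fp`, `fn`, `precision`, `recall`, `f_score`, `precision_raw`,
#'   `recall_raw`, `f_score_raw`.
#' @export
evaluate_annotations <- function(system, gold,
                                 characteristics = c("sex", "age"),
                                 age_tolerance_days = 0) {
  purrr::map_dfr(characteristics, function(ch) {
    cm <- confusion_matrix(system, gold, ch,
                           age_tolerance_days = age_tolerance_days)
    p <- precision(cm)
    r <- recall(cm)
    pp <- present_pct(p)
    rp <- present_pct(r)
    tibble::tibble(
      characteristic = ch,
      tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
      precision = pp, recall = rp,
      f_score = present_pct(f_score(pp, rp)),
      precision_raw = p, recall_raw = r, f_score_raw = f_score(p, r)
    )
  })
}
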