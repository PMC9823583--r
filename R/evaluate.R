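#' Construct a confusion summary
#'
#' @param tp,fp,fn Non-negative integer counts of true positives, false
#'   positives and false negatives (gold total is `tp + fn`).
#' @return An object of class `dao_confusion`.
#' @examples
#' prf(dao_confusion(tp = 2640, fp = 683, fn = 999))
#' @export
dao_confusion <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         gold_total = as.integer(tp + fn)),
    class = "dao_confusion"
  )
}

#' @export
print.dao_confusion <- function(x, ...) {
  cat("<dao_confusion> tp=", x$tp, " fp=", x$fp, " fn=", x$fn,
      " (gold ", x$gold_total, ")\n", sep = "")
  invisible(x)
}

check_spans <- function(spans, who) {
  if (!nrow(spans)) return(invisible(TRUE))
  bad <- spans$start < 0 | spans$end <= spans$start
  if (any(bad)) {
    abort(paste0("malformed ", who, " spans"), class = "dao_integrity_error")
  }
  invisible(TRUE)
}

#' Match predicted spans against gold spans
#'
#' Pairs predictions with gold annotations per document, greedily in span
#' order, each gold matching at most one prediction. Under the `exact`
#' criterion a pair matches on identical `(start, end, concept_id)`; under
#' `overlap`, any character overlap with the same concept suffices.
#' Invariants: `tp + fn = |gold|` and `tp + fp = |predicted|`.
#'
#' @param gold,predicted Span tibbles with columns `doc_id`, `start`,
#'   `end`, `concept_id`.
#' @param criterion `"exact"` (default) or `"overlap"`.
#' @return A `dao_confusion` object.
#' @export
match_spans <- function(gold, predicted, criterion = c("exact", "overlap")) {
  criterion <- match.arg(criterion)
  gold <- as_tibble(gold)
  predicted <- as_tibble(predicted)
  check_spans(gold, "gold")
  check_spans(predicted, "predicted")
  tp <- 0L
  docs <- union(unique(gold$doc_id), unique(predicted$doc_id))
  for (d in docs) {
    g <- gold[gold$doc_id == d, , drop = FALSE]
    p <- predicted[predicted$doc_id == d, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    used <- rep(FALSE, nrow(p))
    for (i in seq_len(nrow(g))) {
      hit <- if (criterion == "exact") {
        which(!used & p$start == g$start[i] & p$end == g$end[i] &
                p$concept_id == g$concept_id[i])
      } else {
        which(!used & p$start < g$end[i] & p$end > g$start[i] &
                p$concept_id == g$concept_id[i])
      }
      if (length(hit)) {
        used[hit[1]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  dao_confusion(tp = tp, fp = nrow(predicted) - tp, fn = nrow(gold) - tp)
}

#' Precision, recall and F1 from a confusion summary
#'
#' Percent-scale precision `100 tp / (tp + fp)`, recall
#' `100 tp / (tp + fn)` and their harmonic mean. A degenerate summary
#' (empty denominator) reports zeros with `degenerate = TRUE`.
#'
#' @param confusion A `dao_confusion`, or anything with `tp`, `fp`, `fn`
#'   fields.
#' @return One-row tibble with `precision`, `recall`, `f1` (percent) and
#'   `degenerate`.
#' @examples
#' prf(dao_confusion(tp = 66, fp = 117, fn = 0))  # 36.1% precision
#' @export
prf <- function(confusion) {
  tp <- confusion$tp; fp <- confusion$fp; fn <- confusion$fn
  degenerate <- (tp + fp) == 0L || (tp + fn) == 0L
  precision <- if ((tp + fp) > 0) 100 * tp / (tp + fp) else 0
  recall <- if ((tp + fn) > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble(precision = precision, recall = recall, f1 = f1,
         degenerate = degenerate)
}

#' @rdname dao_confusion
#' @param x A `dao_confusion` object.
#' @param ... Unused.
#' @export
tidy.dao_confusion <- function(x, ...) {
  tibble(quantity = c("tp", "fp", "fn", "gold_total"),
         count = c(x$tp, x$fp, x$fn, x$gold_total))
}

#' @rdname dao_confusion
#' @export
glance.dao_confusion <- function(x, ...) {
  dplyr::bind_cols(tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                          gold_total = x$gold_total), prf(x))
}

#' Evaluate predicted standoff annotations against gold
#'
#' Convenience wrapper: matches spans and reports counts plus
#' percent-scale precision/recall/F1 rounded for display.
#'
#' @inheritParams match_spans
#' @return One-row tibble combining counts and metrics.
#' @export
evaluate_spans <- function(gold, predicted,
                           criterion = c("exact", "overlap")) {
  glance(match_spans(gold, predicted, criterion))
}
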