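#' Construct a directed gold standard
#'
#' A gold standard is the set of labeled TF-to-target pairs against which a
#' predicted network is benchmarked.  Pairs absent from `edges` are outside
#' the scored universe (the partial-gold convention of the DREAM
#' challenges): metrics only consider the labeled pairs.
#'
#' @param edges data frame with character columns `tf`, `target` and an
#'   integer `label` column in \eqn{\{0, 1\}} (missing label column means
#'   all listed pairs are positives).
#' @param tf_ids,gene_ids optional identifier universes kept with the
#'   object (used when expanding priors or networks).
#' @return An object of class `"grn_gold"`.
#' @export
gold_standard <- function(edges, tf_ids = NULL, gene_ids = NULL) {
  if (!is.data.frame(edges) || !all(c("tf", "target") %in% names(edges)))
    stop_kpcboost("format_error", "'edges' must be a data frame with columns tf, target[, label]")
  if (is.null(edges$label)) edges$label <- 1L
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  edges$label <- as.integer(edges$label)
  if (any(!edges$label %in% c(0L, 1L)))
    stop_kpcboost("format_error", "gold labels must be 0 or 1")
  if (any(edges$tf == edges$target))
    stop_kpcboost("format_error", "gold standard contains self-loops")
  key <- paste(edges$tf, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop_kpcboost("format_error", "duplicated TF-target pairs in gold standard")
  structure(list(edges = edges[, c("tf", "target", "label")],
                 tf_ids = if (is.null(tf_ids)) sort(unique(edges$tf)) else tf_ids,
                 gene_ids = if (is.null(gene_ids))
                   sort(unique(c(edges$tf, edges$target))) else gene_ids),
            class = "grn_gold")
}

#' @export
print.grn_gold <- function(x, ...) {
  cat(sprintf("Directed gold standard: %d labeled pairs (%d positive), %d TFs, %d genes\n",
              nrow(x$edges), sum(x$edges$label), length(x$tf_ids), length(x$gene_ids)))
  invisible(x)
}

# Turn scores (kboost fit, named matrix, or tf/target/score data frame)
# into the vector of scores over the gold universe, paired with labels.
align_scores <- function(scores, gold) {
  if (inherits(scores, "kboost")) scores <- scores$raw
  ed <- gold$edges
  if (is.matrix(scores)) {
    ri <- match(ed$target, rownames(scores))
    ci <- match(ed$tf, colnames(scores))
    if (anyNA(ri) || anyNA(ci))
      stop_kpcboost("invalid_input_error", "scores matrix is missing some gold-standard pairs")
    s <- scores[cbind(ri, ci)]
  } else if (is.data.frame(scores)) {
    key <- paste(scores$tf, scores$target, sep = "\r")
    i <- match(paste(ed$tf, ed$target, sep = "\r"), key)
    if (anyNA(i))
      stop_kpcboost("invalid_input_error", "scores are missing some gold-standard pairs")
    s <- scores$score[i]
  } else {
    stop_kpcboost("invalid_input_error", "'scores' must be a kboost fit, a named matrix or a tf/target/score data frame")
  }
  if (any(!is.finite(s)))
    stop_kpcboost("invalid_input_error", "non-finite scores over the gold universe")
  list(s = as.numeric(s), y = ed$label)
}

#' Area under the ROC curve of a predicted network
#'
#' Area under recall versus false-positive rate over all score thresholds,
#' with tied scores handled by trapezoidal averaging — numerically
#' identical to the normalized Mann-Whitney U statistic.  0.5 is the
#' random-guessing level, 1 a perfect ranking.
#'
#' @param scores a fitted [kboost()] object, a genes-by-TFs matrix with
#'   dimnames, or a data frame with columns `tf`, `target`, `score`.  Every
#'   labeled gold pair must have a score.
#' @param gold a [gold_standard()].
#' @return AUROC in \eqn{[0, 1]}.
#' @export
auroc <- function(scores, gold) {
  a <- align_scores(scores, gold)
  npos <- sum(a$y == 1L)
  nneg <- sum(a$y == 0L)
  if (npos == 0L || nneg == 0L)
    stop_kpcboost("undefined_metric_error",
                  "AUROC needs at least one positive and one negative pair")
  r <- rank(a$s)   # average ranks on ties = trapezoidal ROC
  (sum(r[a$y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve of a predicted network
#'
#' Precision is the fraction of predicted interactions that are true;
#' recall the fraction of true interactions recovered.  The area is the
#' step-wise sum over distinct score thresholds in descending order (tied
#' scores grouped at a single threshold, no interpolation between steps).
#'
#' @inheritParams auroc
#' @return AUPR in \eqn{(0, 1]}.
#' @export
aupr <- function(scores, gold) {
  a <- align_scores(scores, gold)
  npos <- sum(a$y == 1L)
  if (npos == 0L)
    stop_kpcboost("undefined_metric_error", "AUPR needs at least one positive pair")
  ord <- order(a$s, decreasing = TRUE)
  s <- a$s[ord]
  y <- a$y[ord]
  tp <- cumsum(y)
  pp <- seq_along(y)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  recall <- tp[last] / npos
  precision <- tp[last] / pp[last]
  sum(diff(c(0, recall)) * precision)
}

#' Best F1 score over probability thresholds
#'
#' Scans candidate thresholds (every distinct score value, plus one value
#' below the minimum so that "keep everything" is attainable) with the
#' keep-if-strictly-greater rule, and returns the threshold maximizing
#' \eqn{F1 = 2 \cdot \mathrm{precision} \cdot \mathrm{recall} /
#' (\mathrm{precision} + \mathrm{recall})}.  Ties go to the lowest
#' threshold.
#'
#' @inheritParams auroc
#' @return A list with elements `threshold` and `f1`.
#' @export
best_f1_threshold <- function(scores, gold) {
  a <- align_scores(scores, gold)
  npos <- sum(a$y == 1L)
  if (npos == 0L)
    stop_kpcboost("undefined_metric_error", "F1 needs at least one positive pair")
  cands <- c(min(a$s) - 1, sort(unique(a$s)))
  best_f1 <- -1
  best_t <- NA_real_
  for (t in cands) {
    keep <- a$s > t
    tp <- sum(a$y[keep] == 1L)
    f1 <- if (tp == 0L) 0 else {
      prec <- tp / sum(keep)
      rec <- tp / npos
      2 * prec * rec / (prec + rec)
    }
    if (f1 > best_f1) {  # strict ">": lowest threshold wins ties
      best_f1 <- f1
      best_t <- t
    }
  }
  list(threshold = best_t, f1 = best_f1)
}
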