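#' Entry-level inflation report between two count matrices
#'
#' Compares matrix `A` (e.g. counts published by a study) against matrix
#' `B` (e.g. a re-analysis) entry by entry over shared sample/genus pairs.
#' At each count threshold `T`, the pairs considered are those with
#' `A >= T`; a pair is flagged ten-fold inflated when `A >= 10 * B`
#' (`B = 0` satisfies the flag whenever the pair is considered — the
#' ratio is infinite); at the smallest threshold only, a pair is flagged
#' within-50% when `B >= 1` and `0.5 * B <= A <= 1.5 * B`. Fractions are
#' exact ratios; any rounding happens only at display time.
#'
#' @param A,B [count_matrix] objects (or bare integer matrices) sharing
#'   sample and genus ids.
#' @param thresholds Count thresholds (default `c(10, 100)`).
#' @return An object of class `inflation_report`: a `data.frame` with one
#'   row per threshold and columns `threshold`, `n_pairs`, `n_tenfold`,
#'   `frac_tenfold`, `n_within50`, `frac_within50` (the within-50% columns
#'   are `NA` except at the smallest threshold).
#' @export
inflation_report <- function(A, B, thresholds = c(10, 100)) {
  a <- if (inherits(A, "count_matrix")) A$counts else A
  b <- if (inherits(B, "count_matrix")) B$counts else B
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    only_a <- c(setdiff(rownames(a), rownames(b)), setdiff(colnames(a), colnames(b)))
    only_b <- c(setdiff(rownames(b), rownames(a)), setdiff(colnames(b), colnames(a)))
    stop("A and B ids disagree; only in A: {",
         paste(only_a, collapse = ", "), "}; only in B: {",
         paste(only_b, collapse = ", "), "}")
  }
  thresholds <- sort(thresholds)
  rows <- lapply(seq_along(thresholds), function(i) {
    tt <- thresholds[i]
    idx <- a >= tt
    n_pairs <- sum(idx)
    n_tenfold <- sum(idx & (a >= 10 * b))
    if (i == 1L) {
      n_w50 <- sum(idx & b >= 1 & a >= 0.5 * b & a <= 1.5 * b)
      data.frame(threshold = tt, n_pairs = n_pairs, n_tenfold = n_tenfold,
                 frac_tenfold = if (n_pairs) n_tenfold / n_pairs else NA_real_,
                 n_within50 = n_w50,
                 frac_within50 = if (n_pairs) n_w50 / n_pairs else NA_real_)
    } else {
      data.frame(threshold = tt, n_pairs = n_pairs, n_tenfold = n_tenfold,
                 frac_tenfold = if (n_pairs) n_tenfold / n_pairs else NA_real_,
                 n_within50 = NA_integer_, frac_within50 = NA_real_)
    }
  })
  structure(do.call(rbind, rows), class = c("inflation_report", "data.frame"))
}

#' Duplicate-value clusters within a sample group
#'
#' Finds groups of samples sharing an identical normalized value — the
#' smoking gun of fitted-value tagging. Values are compared after rounding
#' to `sig_digits` significant digits (default 9, the precision at which
#' published normalized matrices print their repeated values); singleton
#' clusters are omitted.
#'
#' @param values Numeric vector (one normalized feature column).
#' @param group Optional logical/integer index selecting a sample subset;
#'   must select at least one sample.
#' @param sig_digits Significant digits for equality.
#' @return `data.frame` with columns `value` and `size`, sorted by
#'   decreasing size.
#' @export
duplicate_value_clusters <- function(values, group = NULL, sig_digits = 9L) {
  v <- if (is.null(group)) values else values[group]
  if (!length(v)) stop("empty sample group")
  key <- signif(v, sig_digits)
  tab <- table(key)
  tab <- tab[tab >= 2L]
  if (!length(tab)) return(data.frame(value = numeric(0), size = integer(0)))
  out <- data.frame(value = as.numeric(names(tab)), size = as.integer(tab))
  out <- out[order(-out$size, out$value), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Evaluate a single-feature threshold decision rule
#'
#' Predicts the positive class when `value <direction> threshold`
#' (`direction` one of `ge`, `gt`, `le`, `lt`) and reports the confusion
#' statistics. Arithmetic is exact (integer counts divided once);
#' displayed rounding never feeds back.
#'
#' @param values Numeric vector.
#' @param labels Logical vector (`TRUE` = positive) or a two-level factor
#'   (see `positive`). Both classes must be present.
#' @param threshold Decision threshold.
#' @param direction Comparison direction for predicting positive.
#' @param positive When `labels` is a factor, the positive level (defaults
#'   to the second level).
#' @return A list with `sensitivity`, `specificity`, `error_rate`,
#'   `n_errors`, and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
threshold_rule_eval <- function(values, labels, threshold,
                                direction = c("ge", "gt", "le", "lt"),
                                positive = NULL) {
  direction <- match.arg(direction)
  if (!is.logical(labels)) {
    f <- factor(labels)
    if (is.null(positive)) positive <- levels(f)[nlevels(f)]
    labels <- f == positive
  }
  if (all(labels) || !any(labels))
    stop("labels must contain both classes")
  pred <- switch(direction,
                 ge = values >= threshold, gt = values > threshold,
                 le = values <= threshold, lt = values < threshold)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       error_rate = (fp + fn) / length(labels), n_errors = fp + fn,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Best single-feature threshold rule by balanced accuracy
#'
#' Exhaustively scans midpoints between consecutive sorted unique values,
#' in both inclusive directions (`ge` and `le`), and returns the rule
#' maximizing balanced accuracy `(sensitivity + specificity) / 2`. Because
#' both orientations of every split are scanned, the optimum is never
#' below 0.5. Ties prefer the smallest threshold and direction `ge`.
#'
#' @inheritParams threshold_rule_eval
#' @return A list with `threshold`, `direction`, `balanced_accuracy`.
#' @export
best_threshold_rule <- function(values, labels, positive = NULL) {
  if (!is.logical(labels)) {
    f <- factor(labels)
    if (is.null(positive)) positive <- levels(f)[nlevels(f)]
    labels <- f == positive
  }
  if (all(labels) || !any(labels))
    stop("labels must contain both classes")
  u <- sort(unique(values))
  cand <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else u
  P <- sum(labels); N <- sum(!labels)
  # cumulative positives/negatives at values <= each candidate
  ord <- order(values)
  vs <- values[ord]; ls <- labels[ord]
  cpos <- cumsum(ls); cneg <- cumsum(!ls)
  idx <- findInterval(cand, vs)  # count of values <= cand
  pos_le <- c(0L, cpos)[idx + 1L]
  neg_le <- c(0L, cneg)[idx + 1L]
  ba_ge <- ((P - pos_le) / P + neg_le / N) / 2   # predict + when value >= cand
  ba_le <- (pos_le / P + (N - neg_le) / N) / 2   # predict + when value <= cand
  best <- max(ba_ge, ba_le, 0.5)
  hit_ge <- which(ba_ge == best)
  hit_le <- which(ba_le == best)
  if (length(hit_ge) && (!length(hit_le) || cand[hit_ge[1L]] <= cand[hit_le[1L]]))
    list(threshold = cand[hit_ge[1L]], direction = "ge", balanced_accuracy = best)
  else if (length(hit_le))
    list(threshold = cand[hit_le[1L]], direction = "le", balanced_accuracy = best)
  else
    list(threshold = u[1L], direction = "ge", balanced_accuracy = 0.5)
}

#' Zero-raw discordance scan
#'
#' Diagnoses a normalized matrix against its raw counterpart, feature by
#' feature: a feature is *discordant* when its raw column is effectively
#' informationless (all zero, or non-zero in fewer than
#' `prevalence_frac` of samples) and yet its normalized values support a
#' single-threshold rule with balanced accuracy above `ba_cutoff`. Such
#' features can only discriminate through the normalization itself. For
#' labels with more than two classes, each class is evaluated one-vs-rest
#' and the best class is reported.
#'
#' @param raw A [count_matrix] (or integer matrix).
#' @param normalized A [normalized_matrix] (or numeric matrix) of the same
#'   shape.
#' @param labels Per-sample class labels.
#' @param prevalence_frac Raw-sparsity cutoff as a fraction of samples
#'   (default 0.01).
#' @param ba_cutoff Balanced-accuracy cutoff for the discordance flag
#'   (default 0.75).
#' @return An object of class `feature_diagnostics`: a `data.frame` with
#'   one row per feature and columns `feature`, `n_nonzero_raw`, `sparse`,
#'   `best_class`, `threshold`, `direction`, `sensitivity`, `specificity`,
#'   `error_rate`, `balanced_accuracy`, `max_cluster`, `discordant`.
#' @export
discordance_scan <- function(raw, normalized, labels,
                             prevalence_frac = 0.01, ba_cutoff = 0.75) {
  rawm <- if (inherits(raw, "count_matrix")) raw$counts else raw
  normm <- if (inherits(normalized, "normalized_matrix")) normalized$values else normalized
  stopifnot(identical(dim(rawm), dim(normm)))
  labels <- factor(labels)
  n <- nrow(rawm)
  classes <- levels(labels)
  rows <- lapply(seq_len(ncol(rawm)), function(j) {
    nz <- sum(rawm[, j] != 0)
    sparse <- nz < max(1, prevalence_frac * n)
    best <- NULL; best_class <- NA_character_
    for (cl in classes) {
      y <- labels == cl
      if (!any(y) || all(y)) next
      r <- best_threshold_rule(normm[, j], y)
      if (is.null(best) || r$balanced_accuracy > best$balanced_accuracy) {
        best <- r; best_class <- cl
      }
    }
    ev <- threshold_rule_eval(normm[, j], labels == best_class,
                              best$threshold, best$direction)
    clus <- unlist(lapply(classes, function(cl) {
      d <- duplicate_value_clusters(normm[, j], labels == cl)
      if (nrow(d)) d$size[1L] else 1L
    }))
    data.frame(feature = colnames(rawm)[j] %||% as.character(j),
               n_nonzero_raw = nz, sparse = sparse,
               best_class = best_class,
               threshold = best$threshold, direction = best$direction,
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               error_rate = ev$error_rate,
               balanced_accuracy = best$balanced_accuracy,
               max_cluster = max(clus),
               discordant = sparse && best$balanced_accuracy > ba_cutoff,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("feature_diagnostics", "data.frame"))
}
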