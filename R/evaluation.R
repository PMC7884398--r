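#' Number of leave-k-out splits
#'
#' Exact count of ways to hold `k` subjects out of `n`, computed by the
#' multiplicative binomial recurrence (every intermediate value is an
#' exact integer, so the result is exact for all cohort-scale `n`).
#'
#' @param n Cohort size.
#' @param k Holdout size, `0 < k < n`.
#' @return The binomial coefficient `C(n, k)` as a double holding an
#'   exact integer.
#' @export
count_leave_k_out <- function(n, k) {
  n <- as.double(n); k <- as.double(k)
  if (!(k > 0 && k < n)) stop("usage error: need 0 < k < n")
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) res <- res * (n - k + i) / i
  round(res)
}

# rank-th k-combination of 1..n in lexicographic order (1-based rank)
nth_combination <- function(n, k, rank) {
  combo <- integer(k)
  r <- rank - 1
  x <- 1L
  for (pos in seq_len(k)) {
    remaining <- k - pos
    repeat {
      n_here <- if (remaining == 0) 1 else choose(n - x, remaining)
      if (r < n_here) break
      r <- r - n_here
      x <- x + 1L
    }
    combo[pos] <- x
    x <- x + 1L
  }
  combo
}

#' Enumerate (or subsample) leave-k-out splits
#'
#' Generates training/validation splits of a cohort in deterministic
#' lexicographic order of the held-out subject set. Each split is tagged
#' `balanced` when both sides contain equal numbers of the two classes.
#' When `max_splits` is smaller than the total count, a seeded uniform
#' subsample of split ranks is drawn (without replacement) and returned
#' in lexicographic order — the desk-scale mode for large cohorts where
#' each split costs an LVQ training run.
#'
#' Splits are stored compactly (a matrix of held-out indices); use
#' [get_split()] or `[[` to materialize an individual split plan.
#'
#' @param ids Character vector of subject ids.
#' @param k Holdout (validation-side) size.
#' @param labels Class label per id (parallel to `ids`).
#' @param max_splits Optional cap on the number of splits.
#' @param seed Seed for the subsampling draw.
#' @return A `split_plan_set` with `$ranks`, `$validation_idx`
#'   (splits x k matrix), `$balanced`, `$ids`, `$labels`.
#' @export
enumerate_leave_k_out <- function(ids, k, labels, max_splits = NULL,
                                  seed = 1L) {
  n <- length(ids)
  k <- as.integer(k)
  if (!(k > 0 && k < n)) stop("usage error: need 0 < k < length(ids)")
  stopifnot(length(labels) == n)
  total <- count_leave_k_out(n, k)

  if (is.null(max_splits) || max_splits >= total) {
    val_idx <- t(utils::combn(n, k))
    ranks <- seq_len(total)
  } else {
    ranks <- withr::with_seed(as.integer(seed),
                              sort(sample.int(total, max_splits)))
    val_idx <- t(vapply(ranks, function(r) nth_combination(n, k, r),
                        integer(k)))
  }

  is_pos <- labels == labels[1] # balance only needs a 2-way partition
  pos_total <- sum(is_pos)
  val_pos <- matrix(is_pos[val_idx], nrow = nrow(val_idx))
  val_pos_count <- rowSums(val_pos)
  balanced <- (val_pos_count * 2 == k) &
    ((pos_total - val_pos_count) * 2 == (n - k))

  structure(list(ranks = ranks, validation_idx = val_idx,
                 balanced = balanced, ids = ids, labels = labels,
                 n_total = total, k = k),
            class = "split_plan_set")
}

#' @export
length.split_plan_set <- function(x) nrow(x$validation_idx)

#' Materialize one split plan from a split set
#'
#' @param splits A `split_plan_set`.
#' @param i Position within the set (1-based).
#' @return A `split_plan`: `training_ids`, `validation_ids`, `balanced`,
#'   `rank` (lexicographic rank among all `C(n, k)` splits).
#' @export
get_split <- function(splits, i) {
  stopifnot(inherits(splits, "split_plan_set"),
            i >= 1, i <= length(splits))
  vi <- splits$validation_idx[i, ]
  structure(list(training_ids = splits$ids[-vi],
                 validation_ids = splits$ids[vi],
                 balanced = splits$balanced[i],
                 rank = splits$ranks[i]),
            class = "split_plan")
}

#' @export
`[[.split_plan_set` <- function(x, i) get_split(x, i)

#' @export
print.split_plan_set <- function(x, ...) {
  cat(sprintf("split_plan_set: %d of %d leave-%d-out splits (%d balanced)\n",
              length(x), x$n_total, x$k, sum(x$balanced)))
  invisible(x)
}

#' Confusion matrix counts from labels
#'
#' @param truth,predicted Character vectors of true and predicted
#'   labels.
#' @param positive Positive-class label (default `"sRCC"`).
#' @return A `confusion_matrix`: list of TP, FP, FN, TN.
#' @export
confusion_counts <- function(truth, predicted, positive = "sRCC") {
  stopifnot(length(truth) == length(predicted))
  structure(list(TP = sum(truth == positive & predicted == positive),
                 FP = sum(truth != positive & predicted == positive),
                 FN = sum(truth == positive & predicted != positive),
                 TN = sum(truth != positive & predicted != positive)),
            class = "confusion_matrix")
}

#' Classifier metrics under the total-cohort denominator convention
#'
#' Accuracy, false positive rate and false negative rate all use the
#' full cohort size as denominator — FPR is the fraction of *all*
#' subjects that are false positives, not the fraction of negatives.
#' Under this convention accuracy + FPR + FNR = 100 exactly. This
#' departs from the conventional per-class rates and is the convention
#' of the reported cohort tables, where one false positive among ten
#' test subjects reads as a 10% false positive rate. PPV and NPV use
#' their usual definitions and are flagged (not thrown) when undefined.
#'
#' The positive class is sarcomatoid (sRCC): a false negative is a
#' sarcomatoid tumor called non-sarcomatoid.
#'
#' @param m A `confusion_matrix` (or anything with TP/FP/FN/TN fields).
#' @return A `metrics_row`: accuracy, fpr, fnr, ppv, npv in percent
#'   (full precision; round only for presentation), plus `ppv_defined` /
#'   `npv_defined` flags.
#' @export
confusion_metrics <- function(m) {
  total <- m$TP + m$FP + m$FN + m$TN
  if (total < 1) stop("usage error: empty confusion matrix")
  ppv_defined <- (m$TP + m$FP) > 0
  npv_defined <- (m$TN + m$FN) > 0
  structure(list(
    accuracy = 100 * (m$TP + m$TN) / total,
    fpr = 100 * m$FP / total,
    fnr = 100 * m$FN / total,
    ppv = if (ppv_defined) 100 * m$TP / (m$TP + m$FP) else NA_real_,
    npv = if (npv_defined) 100 * m$TN / (m$TN + m$FN) else NA_real_,
    ppv_defined = ppv_defined, npv_defined = npv_defined,
    total = total
  ), class = "metrics_row")
}

#' @export
print.metrics_row <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%%  FPR %.2f%%  FNR %.2f%%  PPV %s  NPV %s  (n = %d)\n",
    x$accuracy, x$fpr, x$fnr,
    if (x$ppv_defined) sprintf("%.2f%%", x$ppv) else "undefined",
    if (x$npv_defined) sprintf("%.2f%%", x$npv) else "undefined",
    x$total))
  invisible(x)
}

#' Cross-validate an LVQ classifier over a split set
#'
#' For every split, trains an LVQ on the training-side activation
#' vectors and evaluates accuracy on both sides. Training uses the same
#' `lvq_config` (including its seed) for every split, so duplicated
#' splits give identical rows and the whole table is reproducible.
#'
#' @param vectors Named matrix (subjects x 81) of flattened activation
#'   maps, or named list of `activation_map`s.
#' @param labels Named character vector of class labels (names =
#'   subject ids).
#' @param config An `lvq_config`.
#' @param splits A `split_plan_set` over the same subject ids.
#' @return Data frame with one row per split: `rank`, `validation_ids`
#'   (semicolon-joined), `balanced`, `train_accuracy`,
#'   `validation_accuracy` (percent).
#' @export
cross_validate <- function(vectors, labels, config, splits) {
  stopifnot(inherits(splits, "split_plan_set"))
  if (is.list(vectors) && is.null(dim(vectors))) {
    nm <- names(vectors)
    vectors <- do.call(rbind, lapply(vectors, flatten_map))
    rownames(vectors) <- nm
  }
  missing <- setdiff(splits$ids, rownames(vectors))
  if (length(missing) > 0)
    stop("usage error: no activation vector for subject(s): ",
         paste(missing, collapse = ", "))
  missing_lab <- setdiff(splits$ids, names(labels))
  if (length(missing_lab) > 0)
    stop("usage error: no label for subject(s): ",
         paste(missing_lab, collapse = ", "))

  acc <- function(model, ids)
    100 * mean(predict(model, vectors[ids, , drop = FALSE]) == labels[ids])

  rows <- lapply(seq_len(length(splits)), function(i) {
    sp <- get_split(splits, i)
    model <- train_lvq(vectors[sp$training_ids, , drop = FALSE],
                       labels[sp$training_ids], config)
    data.frame(rank = sp$rank,
               validation_ids = paste(sp$validation_ids, collapse = ";"),
               balanced = sp$balanced,
               train_accuracy = acc(model, sp$training_ids),
               validation_accuracy = acc(model, sp$validation_ids))
  })
  do.call(rbind, rows)
}

#' Select candidate models from a cross-validation table
#'
#' Keeps splits whose training AND validation accuracies meet the
#' threshold, optionally restricted to class-balanced splits, ordered by
#' validation accuracy, then training accuracy, then lexicographic split
#' rank. An empty result is allowed.
#'
#' @param cv_table Output of [cross_validate()].
#' @param threshold Accuracy threshold in percent (both sides).
#' @param require_balanced Keep only balanced splits.
#' @return The filtered, reordered subset of `cv_table`.
#' @export
select_model <- function(cv_table, threshold = 83, require_balanced = FALSE) {
  if (is.null(cv_table) || nrow(cv_table) == 0)
    stop("usage error: empty cross-validation table")
  keep <- cv_table$train_accuracy >= threshold &
    cv_table$validation_accuracy >= threshold
  if (require_balanced) keep <- keep & cv_table$balanced
  out <- cv_table[keep, , drop = FALSE]
  out[order(-out$validation_accuracy, -out$train_accuracy, out$rank), ,
      drop = FALSE]
}
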