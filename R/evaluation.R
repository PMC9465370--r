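#' Ligand RMSD between a docked pose and a reference
#'
#' In-place (no superposition) root-mean-square deviation over
#' corresponding atoms — the docking convention for judging whether a pose
#' reproduces the crystal ligand. Atom correspondence is by input order.
#'
#' @param pose_coords,reference_coords n x 3 numeric matrices (or data
#'   frames) of matching ligand atom coordinates, Angstrom.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose_coords, reference_coords) {
  a <- as.matrix(pose_coords)
  b <- as.matrix(reference_coords)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3)
    stop("coordinate sets must be equal-length n x 3 matrices")
  if (nrow(a) < 1) stop("at least one atom is required")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Label poses as near-native by an RMSD threshold
#'
#' @param pose_ids character pose identifiers.
#' @param rmsds ligand RMSD values, Angstrom.
#' @param threshold near-native boundary (default 2.5 Angstrom, inclusive).
#' @return data frame `pose_id`, `rmsd`, `near_native`.
#' @export
label_poses <- function(pose_ids, rmsds, threshold = 2.5) {
  stopifnot(length(pose_ids) == length(rmsds), all(rmsds >= 0))
  data.frame(pose_id = as.character(pose_ids), rmsd = as.numeric(rmsds),
             near_native = rmsds <= threshold, stringsAsFactors = FALSE)
}

#' Select the lowest- and highest-RMSD pose of a docking case
#'
#' Mirrors the validation-set construction in which only the best and worst
#' pose of each complex are retained. Ties are broken by the
#' lexicographically smallest pose id; a single-pose input returns the same
#' id twice with `degenerate = TRUE`.
#'
#' @param poses data frame with columns `pose_id` and `rmsd`.
#' @return list with `lowest`, `highest` (pose ids) and `degenerate`.
#' @export
select_extreme_poses <- function(poses) {
  if (nrow(poses) < 1) stop("empty pose list")
  ord <- order(poses$rmsd, poses$pose_id)
  lo <- poses$pose_id[ord[1]]
  ord_hi <- order(-poses$rmsd, poses$pose_id)
  hi <- poses$pose_id[ord_hi[1]]
  list(lowest = lo, highest = hi, degenerate = nrow(poses) == 1)
}

#' ROC analysis with Youden-index cutoff selection
#'
#' Thresholds are the unique score values; the decision rule is score >=
#' threshold implies positive. Sensitivity/specificity are empirical; AUC
#' is the trapezoid area under the (FPR, TPR) curve (equal to the
#' normalised Mann-Whitney U statistic with half credit for ties). The
#' Youden cutoff maximises J = sensitivity + specificity - 1, with ties
#' resolved to the smallest threshold.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels logical (or 0/1) true-class flags; both classes required.
#' @return list of class `pf_roc`: `thresholds` (ascending), `sensitivity`,
#'   `specificity` (parallel), `auc`, `youden_cutoff`, `youden_sens`,
#'   `youden_spec`, `youden_j`.
#' @export
roc_with_youden <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0)
    stop("both classes must be present for ROC analysis")
  th <- sort(unique(scores))
  sens <- spec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    sens[i] <- sum(pred & y) / np
    spec[i] <- sum(!pred & !y) / nn
  }
  # trapezoid over the curve from (0,0) [threshold above max] down to (1,1)
  fpr <- c(0, rev(1 - spec))
  tpr <- c(0, rev(sens))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- sens + spec - 1
  # ties (within numerical noise) resolve to the smallest threshold
  best <- which(j >= max(j) - 1e-12)[1]
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, youden_cutoff = th[best],
                 youden_sens = sens[best], youden_spec = spec[best],
                 youden_j = j[best]),
            class = "pf_roc")
}

#' @export
print.pf_roc <- function(x, ...) {
  cat(sprintf("<pf_roc: AUC %.4f; Youden cutoff %g (sens %.3f, spec %.3f, J %.3f)>\n",
              x$auc, x$youden_cutoff, x$youden_sens, x$youden_spec,
              x$youden_j))
  invisible(x)
}

#' Confusion-table metrics
#'
#' Closed-form metrics from a 2x2 contingency table. Metrics with a zero
#' denominator are returned as NA (an explicit undefined marker), never as
#' an error.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return list: `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty contingency table")
  frac <- function(a, b) if (b == 0) NA_real_ else a / b
  list(accuracy = (tp + tn) / total,
       sensitivity = frac(tp, tp + fn),
       specificity = frac(tn, tn + fp),
       ppv = frac(tp, tp + fp),
       npv = frac(tn, tn + fn))
}

#' Seeded random train/test split
#'
#' Shuffles items with the given seed and splits at
#' `round(n * train_fraction)`. With `groups` supplied, whole groups are
#' assigned to one side (shuffled group order, cumulative fill of the
#' training side) so dependent items — e.g. the two extreme poses of one
#' complex — never straddle the split.
#'
#' @param n number of items, or a vector/data frame whose length/rows
#'   define it.
#' @param train_fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @param groups optional grouping vector of length n.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n, train_fraction = 0.7, seed = 1,
                             groups = NULL) {
  if (!is.numeric(n) || length(n) > 1)
    n <- if (is.data.frame(n)) nrow(n) else length(n)
  n <- as.integer(n)
  if (n < 2) stop("need at least two items to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(n * train_fraction)
  .pf_with_seed(seed, {
    if (is.null(groups)) {
      perm <- sample.int(n)
      list(train = sort(perm[seq_len(n_train)]),
           test = sort(perm[-seq_len(n_train)]))
    } else {
      stopifnot(length(groups) == n)
      gs <- sample(unique(groups))
      train <- integer(0)
      for (g in gs) {
        if (length(train) >= n_train) break
        train <- c(train, which(groups == g))
      }
      list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
    }
  })
}

#' Compare the five classifier families on a two-feature pose dataset
#'
#' Splits the data, trains logistic regression, k-nearest neighbours,
#' decision tree, random forest and gradient boosting on the training side,
#' and reports test-side AUC plus confusion metrics at a probability cutoff
#' of 0.5 — the layout of the published model-comparison table.
#'
#' @param features data frame with `pattern_num`, `pattern_ratio`.
#' @param labels logical near-native flags.
#' @param algorithms families to include (default all five).
#' @param seed integer seed (controls the split and every fit).
#' @param train_fraction passed to [split_train_test].
#' @param prob_cutoff operating point for the confusion metrics.
#' @return data frame, one row per algorithm: `algorithm`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
compare_models <- function(features, labels, algorithms = .pf_algorithms,
                           seed = 1, train_fraction = 0.7,
                           prob_cutoff = 0.5) {
  y <- as.logical(labels)
  sp <- split_train_test(length(y), train_fraction, seed)
  ytr <- y[sp$train]; yte <- y[sp$test]
  if (length(unique(ytr)) < 2 || length(unique(yte)) < 2)
    stop("both classes must be present in both split halves")
  ftr <- features[sp$train, , drop = FALSE]
  fte <- features[sp$test, , drop = FALSE]
  rows <- lapply(algorithms, function(alg) {
    clf <- train_pose_classifier(ftr, ytr, alg, seed = seed)
    p <- predict_probability(clf, fte$pattern_num, fte$pattern_ratio)
    auc <- roc_with_youden(p, yte)$auc
    pred <- p >= prob_cutoff
    cm <- confusion_metrics(tp = sum(pred & yte), fp = sum(pred & !yte),
                            tn = sum(!pred & !yte), fn = sum(!pred & yte))
    data.frame(algorithm = alg, auc = auc, accuracy = cm$accuracy,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               ppv = cm$ppv, npv = cm$npv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
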