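#' Screening thresholds
#'
#' Defaults are the published operating points: a potential target must show
#' at least 600 significant interaction pairs and at the same time a
#' significant-pair ratio of at least 0.8; the Youden-index optimal cutoffs
#' from the pose-validation ROC analysis are 285 (pattern count) and 0.679
#' (pattern ratio).
#'
#' @param target_min_num minimum significant-pair count for the target rule.
#' @param target_min_ratio minimum significant-pair ratio for the target
#'   rule.
#' @param youden_num Youden-optimal pattern-count cutoff.
#' @param youden_ratio Youden-optimal pattern-ratio cutoff.
#' @return list of class `pf_thresholds`.
#' @export
pf_thresholds <- function(target_min_num = 600, target_min_ratio = 0.8,
                          youden_num = 285, youden_ratio = 0.679) {
  stopifnot(target_min_num >= 0, youden_num >= 0,
            target_min_ratio >= 0, target_min_ratio <= 1,
            youden_ratio >= 0, youden_ratio <= 1)
  structure(list(target_min_num = target_min_num,
                 target_min_ratio = target_min_ratio,
                 youden_num = youden_num, youden_ratio = youden_ratio),
            class = "pf_thresholds")
}

#' Apply the screening rules to pair counts
#'
#' The target rule is a strict conjunction: a pose (or pooled target)
#' passes only when the significant-pair count meets `target_min_num` AND
#' the significant-pair ratio meets `target_min_ratio`. The two Youden
#' cutoffs are independent flags. The ratio is defined as 0 when
#' `total_pairs` is 0.
#'
#' @param pattern_num significant-pair count.
#' @param total_pairs all interaction pairs.
#' @param thresholds a [pf_thresholds].
#' @return list: `pattern_num`, `total_pairs`, `pattern_ratio`,
#'   `target_rule_pass`, `youden_num_pass`, `youden_ratio_pass`.
#' @export
apply_screening_rules <- function(pattern_num, total_pairs,
                                  thresholds = pf_thresholds()) {
  stopifnot(pattern_num >= 0, total_pairs >= 0, pattern_num <= total_pairs)
  ratio <- if (total_pairs > 0) pattern_num / total_pairs else 0
  list(pattern_num = as.integer(pattern_num),
       total_pairs = as.integer(total_pairs),
       pattern_ratio = ratio,
       target_rule_pass = pattern_num >= thresholds$target_min_num &&
         ratio >= thresholds$target_min_ratio,
       youden_num_pass = pattern_num >= thresholds$youden_num,
       youden_ratio_pass = ratio >= thresholds$youden_ratio)
}

#' Score a docked pose against a pattern library
#'
#' Extracts the pose's interaction pairs at the library's cutoff, counts how
#' many are assigned to significant patterns (`pattern_num`), forms the
#' ratio to all pairs (`pattern_ratio`, defined as 0 for a contact-free
#' pose), and applies the screening rules: the target rule is the strict
#' conjunction pattern_num >= target_min_num AND pattern_ratio >=
#' target_min_ratio; the two Youden cutoffs are reported as independent
#' flags. Refuses to score when the pose-processing conventions do not match
#' the library metadata.
#'
#' @param pose a [pf_complex] docked pose.
#' @param library a [pf_pattern_library].
#' @param thresholds a [pf_thresholds] (defaults to the published values).
#' @param classifier optional [train_pose_classifier] artifact; adds a
#'   near-native probability to the result.
#' @param mahalanobis_gate passed to [assign_pairs].
#' @return list of class `pf_pose_score`: `pose_id`, `pattern_num`,
#'   `total_pairs`, `pattern_ratio`, `target_rule_pass`, `youden_num_pass`,
#'   `youden_ratio_pass`, `probability` (NA without a classifier).
#' @export
score_pose <- function(pose, library, thresholds = pf_thresholds(),
                       classifier = NULL, mahalanobis_gate = FALSE) {
  md <- library$metadata
  if (!identical(md$fragment_convention, .pf_fragment_convention) ||
      !identical(md$sybyl_version, .pf_sybyl_version))
    stop(sprintf(
      "convention mismatch: library built with (%s, %s) but this build uses (%s, %s)",
      md$fragment_convention, md$sybyl_version,
      .pf_fragment_convention, .pf_sybyl_version))
  pairs <- extract_interaction_pairs(strip_hydrogens(pose),
                                     cutoff = md$cutoff)
  total <- nrow(pairs)
  num <- if (total) sum(assign_pairs(pairs, library, mahalanobis_gate)) else 0L
  res <- apply_screening_rules(num, total, thresholds)
  res$probability <- if (is.null(classifier)) NA_real_ else
    predict_probability(classifier, res$pattern_num, res$pattern_ratio)
  structure(c(list(pose_id = pose$source_id), res),
            class = "pf_pose_score")
}

#' @export
print.pf_pose_score <- function(x, ...) {
  cat(sprintf("<pose %s: %d/%d significant pairs (ratio %.3f), target rule %s, prob %s>\n",
              x$pose_id, x$pattern_num, x$total_pairs, x$pattern_ratio,
              ifelse(x$target_rule_pass, "PASS", "fail"),
              ifelse(is.na(x$probability), "-",
                     sprintf("%.3f", x$probability))))
  invisible(x)
}

.pf_algorithms <- c("lr", "knn", "dt", "rf", "gbt")

.pf_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Train a two-feature near-native pose classifier
#'
#' Fits one of the five supported model families on exactly the two
#' screening features (significant-pair count, significant-pair ratio) to
#' predict whether a pose is near-native (ligand RMSD within 2.5 Angstrom of
#' the crystal pose). Training is deterministic given the seed.
#'
#' Default hyperparameters: LR = plain logistic regression; KNN k = 5
#' (features standardised by training mean/sd); DT = rpart defaults; RF =
#' 500 trees; GBT = 100 rounds, depth 3, eta 0.3, single thread.
#'
#' @param features data frame with columns `pattern_num`, `pattern_ratio`.
#' @param labels logical (or 0/1) near-native flags.
#' @param algorithm one of `"lr"`, `"knn"`, `"dt"`, `"rf"`, `"gbt"` (the
#'   gradient-boosted default mirrors the deployed screen).
#' @param seed integer seed.
#' @param params optional named list overriding family hyperparameters.
#' @return object of class `pf_classifier`.
#' @export
train_pose_classifier <- function(features, labels,
                                  algorithm = c("gbt", "lr", "knn", "dt", "rf"),
                                  seed = 1, params = list()) {
  algorithm <- match.arg(algorithm)
  X <- data.frame(pattern_num = as.numeric(features$pattern_num),
                  pattern_ratio = as.numeric(features$pattern_ratio))
  if (any(!is.finite(as.matrix(X)))) stop("features must be finite")
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    stop("labels contain a single class; cannot train a classifier")
  model <- .pf_with_seed(seed, switch(algorithm,
    lr = stats::glm(y ~ pattern_num + pattern_ratio,
                    data = cbind(X, y = y), family = stats::binomial()),
    knn = {
      k <- if (!is.null(params$k)) params$k else 5L
      mu <- colMeans(X); sdv <- pmax(apply(X, 2, stats::sd), 1e-9)
      list(train = scale(as.matrix(X), mu, sdv), cl = y, k = k,
           center = mu, scale = sdv)
    },
    dt = rpart::rpart(factor(y) ~ pattern_num + pattern_ratio,
                      data = cbind(X, y = y), method = "class"),
    rf = randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)),
      ntree = if (!is.null(params$ntree)) params$ntree else 500),
    gbt = {
      nr <- if (!is.null(params$nrounds)) params$nrounds else 100
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = if (!is.null(params$max_depth))
                        params$max_depth else 3,
                      eta = if (!is.null(params$eta)) params$eta else 0.3,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(as.matrix(X), label = y),
        nrounds = nr, verbose = 0)
    }))
  structure(list(algorithm = algorithm, model = model,
                 feature_names = c("pattern_num", "pattern_ratio"),
                 seed = as.integer(seed)),
            class = "pf_classifier")
}

#' Predict the near-native probability of a pose
#'
#' @param classifier a [pf_classifier].
#' @param pattern_num significant-pair count(s), non-negative.
#' @param pattern_ratio significant-pair ratio(s) in `[0, 1]`.
#' @return numeric probability vector in `[0, 1]`.
#' @export
predict_probability <- function(classifier, pattern_num, pattern_ratio) {
  if (any(pattern_num < 0)) stop("pattern_num must be non-negative")
  if (any(pattern_ratio < 0 | pattern_ratio > 1))
    stop("pattern_ratio must lie in [0, 1]")
  nd <- data.frame(pattern_num = as.numeric(pattern_num),
                   pattern_ratio = as.numeric(pattern_ratio))
  m <- classifier$model
  p <- switch(classifier$algorithm,
    lr = as.numeric(stats::predict(m, newdata = nd, type = "response")),
    knn = .pf_with_seed(classifier$seed, {
      # seed fixed so knn's random distance-tie handling stays reproducible
      tst <- scale(as.matrix(nd), m$center, m$scale)
      pr <- class::knn(m$train, tst, factor(m$cl, levels = c(0, 1)),
                       k = m$k, prob = TRUE)
      won <- attr(pr, "prob")
      ifelse(pr == "1", won, 1 - won)
    }),
    dt = as.numeric(stats::predict(m, newdata = nd, type = "prob")[, "1"]),
    rf = as.numeric(stats::predict(m, newdata = nd, type = "prob")[, "1"]),
    gbt = as.numeric(stats::predict(m, xgboost::xgb.DMatrix(as.matrix(nd)))))
  pmin(pmax(p, 0), 1)
}
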