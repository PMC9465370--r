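.pf_library_schema <- "posefilter-library-1"

# Deterministic per-group seed: polynomial rolling hash of the group key
# folded into the master seed, modulo 2^31 - 1.
derive_group_seed <- function(master_seed, key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(master_seed) + h) %% 2147483647)
}

#' Build a significant-interaction-pattern library
#'
#' Runs the training pipeline: per complex, strip hydrogens and extract
#' interaction pairs; pool pairs across complexes; group them by (SYBYL
#' type, fragment type); fit a Bayesian-Gaussian mixture per group over the
#' fragment-local ligand coordinates; flag components with at least
#' `min_members` member atoms as significant interaction patterns. Groups
#' are fitted in sorted key order with per-group seeds derived from the
#' master seed, so the result is fully deterministic given the seed and
#' input order.
#'
#' @param complexes list of [pf_complex] objects.
#' @param cutoff contact cutoff, Angstrom (default 5).
#' @param min_members significance threshold (default 20 member atoms).
#' @param max_components mixture-size cap per group (default 10).
#' @param seed master integer seed.
#' @param training_id free-text descriptor of the training set.
#' @return object of class `pf_pattern_library`: `groups` (named list, per
#'   group key, of component lists) and `metadata`.
#' @export
build_pattern_library <- function(complexes, cutoff = 5.0, min_members = 20,
                                  max_components = 10, seed = 1,
                                  training_id = "unnamed") {
  stopifnot(length(complexes) >= 1)
  pooled <- list()
  skipped <- character(0)
  for (cx in complexes) {
    pr <- tryCatch(
      extract_interaction_pairs(strip_hydrogens(cx), cutoff = cutoff),
      error = function(e) e)
    if (inherits(pr, "error")) {
      skipped <- c(skipped, cx$source_id)
      message(sprintf("skipping complex %s: %s", cx$source_id,
                      conditionMessage(pr)))
      next
    }
    pooled[[length(pooled) + 1]] <- pr
  }
  pairs <- do.call(rbind, pooled)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no interaction pairs extracted from the training set")
  groups <- group_pairs(pairs)

  fitted <- list()
  warn_groups <- character(0)
  for (key in names(groups)) {
    pts <- as.matrix(groups[[key]][, c("lx", "ly", "lz")])
    fit <- fit_group_bgmm(pts, max_components = max_components,
                          seed = derive_group_seed(seed, key),
                          min_members = min_members)
    if (!fit$converged) warn_groups <- c(warn_groups, key)
    fitted[[key]] <- fit$components
  }
  structure(list(
    groups = fitted,
    metadata = list(
      schema_version = .pf_library_schema,
      cutoff = cutoff,
      min_members = as.integer(min_members),
      max_components = as.integer(max_components),
      seed = as.integer(seed),
      fragment_convention = .pf_fragment_convention,
      sybyl_version = .pf_sybyl_version,
      training_set = training_id,
      n_complexes = length(complexes),
      n_skipped = length(skipped),
      n_pairs = nrow(pairs),
      unconverged_groups = warn_groups)),
    class = "pf_pattern_library")
}

#' @export
print.pf_pattern_library <- function(x, ...) {
  nsig <- sum(vapply(x$groups, function(g)
    sum(vapply(g, `[[`, logical(1), "significant")), integer(1)))
  cat(sprintf("<pf_pattern_library: %d groups, %d significant patterns, %d training pairs>\n",
              length(x$groups), nsig, x$metadata$n_pairs))
  invisible(x)
}

#' Test docked interaction pairs for significance
#'
#' A pair whose group key is absent from the library is not significant. A
#' pair in a known group is significant when the component with maximum
#' responsibility at its local coordinates is a significant pattern; with
#' `mahalanobis_gate = TRUE` the pair must additionally lie within the
#' component's 99% chi-square (3 d.o.f.) Mahalanobis contour.
#'
#' @param pairs data frame from [extract_interaction_pairs] (any subset of
#'   rows).
#' @param library a [pf_pattern_library].
#' @param mahalanobis_gate optional stringency gate (default FALSE).
#' @return logical vector, one flag per pair.
#' @export
assign_pairs <- function(pairs, library, mahalanobis_gate = FALSE) {
  n <- nrow(pairs)
  out <- logical(n)
  if (n == 0) return(out)
  gate <- stats::qchisq(0.99, df = 3)
  for (key in unique(pairs$group_key)) {
    comps <- library$groups[[key]]
    idx <- which(pairs$group_key == key)
    if (is.null(comps)) next
    X <- as.matrix(pairs[idx, c("lx", "ly", "lz")])
    r <- .pf_bgmm_responsibilities(comps, X)
    best <- max.col(r, ties.method = "first")
    sig <- vapply(comps, `[[`, logical(1), "significant")[best]
    if (mahalanobis_gate) {
      for (q in seq_along(idx)) {
        if (!sig[q]) next
        cp <- comps[[best[q]]]
        dv <- X[q, ] - cp$mean
        sig[q] <- drop(t(dv) %*% solve(cp$cov, dv)) <= gate
      }
    }
    out[idx] <- sig
  }
  out
}

#' @rdname assign_pairs
#' @param pair a single-row pair data frame.
#' @export
assign_pair <- function(pair, library, mahalanobis_gate = FALSE) {
  assign_pairs(pair[1, , drop = FALSE], library, mahalanobis_gate)[1]
}

.pf_comp_to_json <- function(cp) {
  list(mean = cp$mean, cov = lapply(seq_len(nrow(cp$cov)),
                                    function(i) cp$cov[i, ]),
       weight = cp$weight, member_count = cp$member_count,
       significant = cp$significant)
}

#' Save / load a pattern library
#'
#' Libraries persist as schema-versioned JSON with full numeric precision;
#' the round trip is lossless and byte-stable for a fixed library.
#'
#' @param library a [pf_pattern_library].
#' @param path file path.
#' @export
save_library <- function(library, path) {
  doc <- list(schema_version = .pf_library_schema,
              metadata = library$metadata,
              groups = lapply(library$groups, function(g)
                lapply(g, .pf_comp_to_json)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_library
#' @return `load_library` returns the [pf_pattern_library].
#' @export
load_library <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse library document: ",
                         conditionMessage(e)))
  sv <- doc$schema_version
  if (is.null(sv) || !identical(sv, .pf_library_schema))
    stop(sprintf("library schema version mismatch: document has '%s', this build reads '%s'",
                 if (is.null(sv)) "<missing>" else sv, .pf_library_schema))
  groups <- lapply(doc$groups, function(g) lapply(g, function(cp) {
    d <- length(cp$mean)
    list(mean = as.numeric(unlist(cp$mean)),
         cov = matrix(as.numeric(unlist(cp$cov)), d, d, byrow = TRUE),
         weight = as.numeric(cp$weight),
         member_count = as.integer(cp$member_count),
         significant = as.logical(cp$significant))
  }))
  md <- doc$metadata
  md$unconverged_groups <- as.character(unlist(md$unconverged_groups))
  for (f in c("cutoff")) md[[f]] <- as.numeric(md[[f]])
  for (f in c("min_members", "max_components", "seed", "n_complexes",
              "n_skipped", "n_pairs"))
    md[[f]] <- as.integer(md[[f]])
  structure(list(groups = groups, metadata = md),
            class = "pf_pattern_library")
}
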