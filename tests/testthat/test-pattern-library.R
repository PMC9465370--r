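planted_blobs <- function(means, n_each, sd = 1, seed = 1) {
  withr::with_seed(seed, do.call(rbind, lapply(seq_along(means), function(i)
    matrix(rnorm(3 * n_each[i], sd = sd), ncol = 3) +
      rep(means[[i]], each = n_each[i]))))
}

test_that("groups below the 20-atom rule yield no significant component", {
  X <- planted_blobs(list(c(0, 0, 0)), 12, seed = 3)
  fit <- fit_group_bgmm(X, seed = 5)
  expect_false(any(vapply(fit$components, `[[`, logical(1), "significant")))
  # member counts still partition the 12 points
  expect_equal(sum(vapply(fit$components, `[[`, integer(1), "member_count")),
               12)
})

test_that("two well-separated Gaussians give two significant components", {
  X <- planted_blobs(list(c(0, 0, 0), c(10, 0, 0)), c(100, 100), seed = 7)
  fit <- fit_group_bgmm(X, seed = 5)
  sig <- Filter(function(cp) cp$significant, fit$components)
  expect_length(sig, 2)
  counts <- sort(vapply(sig, `[[`, integer(1), "member_count"))
  expect_true(all(counts >= 80 & counts <= 120))
  means <- sort(vapply(sig, function(cp) cp$mean[1], numeric(1)))
  expect_equal(means, c(0, 10), tolerance = 0.5)
  # independent cross-check: model-based clustering agrees on the count
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(X, G = 1:6, verbose = FALSE)
  expect_equal(length(sig), mc$G)
})

test_that("degenerate identical points collapse to one regularised component", {
  X <- matrix(rep(c(1, 2, 3), each = 200), ncol = 3)
  fit <- fit_group_bgmm(X, seed = 9)
  sig <- Filter(function(cp) cp$significant, fit$components)
  expect_length(sig, 1)
  expect_equal(sig[[1]]$member_count, 200)
  expect_true(all(eigen(sig[[1]]$cov)$values > 0))
})

test_that("member counts always sum to the group size and min_members is monotone", {
  X <- planted_blobs(list(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0)),
                     c(40, 25, 15), seed = 13)
  fit <- fit_group_bgmm(X, seed = 2)
  expect_equal(sum(vapply(fit$components, `[[`, integer(1), "member_count")),
               80)
  n_sig <- function(mm) sum(vapply(
    fit_group_bgmm(X, seed = 2, min_members = mm)$components,
    `[[`, logical(1), "significant"))
  counts <- vapply(c(5, 20, 30, 50), n_sig, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("library building recovers planted patterns and is reproducible", {
  pats <- list(list(element = "C", mean = c(2.5, 1.0, 0.5), sd = 0.3,
                    n_points = 40),
               list(element = "N", mean = c(-1.0, 2.0, -1.5), sd = 0.3,
                    n_points = 35))
  corp <- make_planted_pattern_corpus(pats, seed = 21)
  lib <- build_pattern_library(corp$complexes, seed = 17,
                               training_id = "planted")
  expect_s3_class(lib, "pf_pattern_library")
  sig_per_group <- vapply(lib$groups, function(g)
    sum(vapply(g, `[[`, logical(1), "significant")), integer(1))
  expect_setequal(names(sig_per_group),
                  c("C.3|FRG:X1:X2:X3", "N.3|FRG:X1:X2:X3"))
  expect_true(all(sig_per_group >= 1))
  expect_equal(lib$metadata$n_pairs, 75)

  # byte-identical serialisation under an identical rebuild
  lib2 <- build_pattern_library(corp$complexes, seed = 17,
                                training_id = "planted")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_library(lib, f1); save_library(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pair assignment follows argmax responsibility and the absent-key rule", {
  pats <- list(list(element = "C", mean = c(2.5, 1.0, 0.5), sd = 0.25,
                    n_points = 60),
               list(element = "C", mean = c(-2.5, 1.0, 0.5), sd = 0.25,
                    n_points = 10))
  corp <- make_planted_pattern_corpus(pats, seed = 33)
  lib <- build_pattern_library(corp$complexes, seed = 3)
  mk_pair <- function(key, p) data.frame(
    ligand_atom = 1L, fragment = 1L, sybyl = sub("\\|.*", "", key),
    frag_type = sub(".*\\|", "", key), group_key = key,
    distance = sqrt(sum(p^2)), lx = p[1], ly = p[2], lz = p[3],
    stringsAsFactors = FALSE)
  key <- "C.3|FRG:X1:X2:X3"
  # at the big planted mean: significant
  expect_true(assign_pair(mk_pair(key, c(2.5, 1.0, 0.5)), lib))
  # at the small (<20 members) planted cluster: argmax lands on a
  # non-significant component
  expect_false(assign_pair(mk_pair(key, c(-2.5, 1.0, 0.5)), lib))
  # unseen group key
  expect_false(assign_pair(mk_pair("O.3|FRG:X1:X2:X3", c(2.5, 1, 0.5)), lib))
})

test_that("self-consistency: training pairs mostly land on significant patterns", {
  pats <- list(list(element = "C", mean = c(2.0, 1.0, 1.0), sd = 0.3,
                    n_points = 50))
  corp <- make_planted_pattern_corpus(pats, seed = 41)
  lib <- build_pattern_library(corp$complexes, seed = 5)
  pairs <- do.call(rbind, lapply(corp$complexes, function(cx)
    extract_interaction_pairs(strip_hydrogens(cx))))
  frac <- mean(assign_pairs(pairs, lib))
  sig_members <- sum(unlist(lapply(lib$groups, function(g)
    vapply(g, function(cp) if (cp$significant) cp$member_count else 0L,
           integer(1)))))
  expect_gte(frac, sig_members / nrow(pairs) - 1e-9)
})

test_that("library persistence round-trips losslessly and fails loudly", {
  corp <- make_planted_pattern_corpus(
    list(list(element = "C", mean = c(2, 1, 0), sd = 0.3, n_points = 25)),
    seed = 51)
  lib <- build_pattern_library(corp$complexes, seed = 7)
  tf <- withr::local_tempfile(fileext = ".json")
  save_library(lib, tf)
  lib2 <- load_library(tf)
  expect_identical(names(lib2$groups), names(lib$groups))
  for (k in names(lib$groups)) for (i in seq_along(lib$groups[[k]])) {
    a <- lib$groups[[k]][[i]]; b <- lib2$groups[[k]][[i]]
    expect_equal(b$mean, a$mean, tolerance = 1e-12)
    expect_equal(b$cov, a$cov, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(b$weight, a$weight, tolerance = 1e-12)
    expect_identical(b$member_count, a$member_count)
    expect_identical(b$significant, a$significant)
  }
  expect_identical(lib2$metadata$seed, 7L)
  expect_identical(lib2$metadata$fragment_convention,
                   lib$metadata$fragment_convention)

  # truncated document: parse error, not a silent partial library
  full <- readLines(tf)
  tf2 <- withr::local_tempfile(fileext = ".json")
  writeLines(full[1:(length(full) %/% 2)], tf2)
  expect_error(load_library(tf2), "parse")
  # schema mismatch names both versions
  doc <- jsonlite::read_json(tf)
  doc$schema_version <- "posefilter-library-99"
  tf3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, tf3, auto_unbox = TRUE)
  expect_error(load_library(tf3), "posefilter-library-99.*posefilter-library-1")
})
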