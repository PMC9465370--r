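# Variational Bayesian Gaussian mixture with a Dirichlet weight prior and
# Normal-Wishart component priors (full covariances). A small weight
# concentration (1/K) gives Dirichlet-process-style pruning: surplus
# components drift to zero responsibility, so no per-group model selection
# is needed. This is the clustering engine behind significant-interaction-
# pattern discovery.

.pf_logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# log N(x | mean, cov) for rows of X
.pf_dmvnorm_log <- function(X, mean, cov) {
  d <- ncol(X)
  ch <- chol(cov)
  logdet <- 2 * sum(log(diag(ch)))
  Xc <- sweep(X, 2, mean)
  z <- backsolve(ch, t(Xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
}

# log of the Wishart normalising constant B(W, nu), given log|W|
.pf_log_wishart_B <- function(logdetW, nu, d) {
  -0.5 * nu * logdetW - 0.5 * nu * d * log(2) -
    0.25 * d * (d - 1) * log(pi) -
    sum(lgamma((nu + 1 - seq_len(d)) / 2))
}

# One VB-EM run from a given hard initialisation. Convergence and init
# selection both use the full variational lower bound (ELBO), which is what
# penalises redundant components and drives DP-style pruning.
.pf_vb_run <- function(X, K, z_init, alpha0, beta0, m0, nu0, W0inv,
                       reg, tol, max_iter) {
  n <- nrow(X); d <- ncol(X)
  r <- matrix(0, n, K)
  r[cbind(seq_len(n), z_init)] <- 1
  lb_prev <- -Inf
  lb <- -Inf
  converged <- FALSE
  const <- -0.5 * d * log(2 * pi)
  ch0 <- chol(W0inv)
  logdetW0 <- -2 * sum(log(diag(ch0)))
  W0inv_mat <- W0inv
  for (iter in seq_len(max_iter)) {
    # M-step from current responsibilities
    Nk <- colSums(r) + 1e-10
    xbar <- crossprod(r, X) / Nk
    alpha <- alpha0 + colSums(r)
    beta <- beta0 + Nk
    nu <- nu0 + Nk
    m <- (beta0 * matrix(m0, K, d, byrow = TRUE) + Nk * xbar) / beta
    Winv <- vector("list", K)
    Sk_list <- vector("list", K)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, xbar[k, ])
      Sk <- crossprod(Xc * r[, k], Xc) / Nk[k] + diag(reg, d)
      dm <- xbar[k, ] - m0
      Winv[[k]] <- W0inv + Nk[k] * Sk +
        (beta0 * Nk[k] / (beta0 + Nk[k])) * tcrossprod(dm)
      Sk_list[[k]] <- Sk
    }
    # E-step
    lrho <- matrix(0, n, K)
    e_ln_pi <- digamma(alpha) - digamma(sum(alpha))
    e_ln_lam <- logdetW <- numeric(K)
    W_list <- vector("list", K)
    for (k in seq_len(K)) {
      ch <- chol(Winv[[k]])
      logdetW[k] <- -2 * sum(log(diag(ch)))
      e_ln_lam[k] <- sum(digamma((nu[k] + 1 - seq_len(d)) / 2)) +
        d * log(2) + logdetW[k]
      W_list[[k]] <- chol2inv(ch)
      Xc <- sweep(X, 2, m[k, ])
      maha <- rowSums((Xc %*% W_list[[k]]) * Xc)
      lrho[, k] <- e_ln_pi[k] + 0.5 * e_ln_lam[k] + const -
        0.5 * (d / beta[k] + nu[k] * maha)
    }
    lnorm <- .pf_logsumexp_rows(lrho)
    r <- exp(lrho - lnorm)

    # ELBO with statistics consistent with the fresh responsibilities
    Nk <- colSums(r) + 1e-10
    xbar <- crossprod(r, X) / Nk
    e_pX <- e_pZ <- e_pmulam <- 0
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, xbar[k, ])
      Sk <- crossprod(Xc * r[, k], Xc) / Nk[k]
      dxm <- xbar[k, ] - m[k, ]
      dmm0 <- m[k, ] - m0
      Wk <- W_list[[k]]
      e_pX <- e_pX + 0.5 * Nk[k] *
        (e_ln_lam[k] - d / beta[k] - nu[k] * sum(Sk * Wk) -
         nu[k] * drop(t(dxm) %*% Wk %*% dxm) - d * log(2 * pi))
      e_pmulam <- e_pmulam + 0.5 *
        (d * log(beta0 / (2 * pi)) + e_ln_lam[k] - d * beta0 / beta[k] -
         beta0 * nu[k] * drop(t(dmm0) %*% Wk %*% dmm0)) +
        .pf_log_wishart_B(logdetW0, nu0, d) +
        0.5 * (nu0 - d - 1) * e_ln_lam[k] -
        0.5 * nu[k] * sum(W0inv_mat * Wk)
    }
    e_pZ <- sum(r %*% e_ln_pi)
    e_ppi <- lgamma(K * alpha0) - K * lgamma(alpha0) +
      (alpha0 - 1) * sum(e_ln_pi)
    q_Z <- sum(r[r > 0] * log(r[r > 0]))
    q_pi <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
      sum((alpha - 1) * e_ln_pi)
    q_mulam <- 0
    for (k in seq_len(K)) {
      h_wishart <- -.pf_log_wishart_B(logdetW[k], nu[k], d) -
        0.5 * (nu[k] - d - 1) * e_ln_lam[k] + 0.5 * nu[k] * d
      q_mulam <- q_mulam + 0.5 * e_ln_lam[k] +
        0.5 * d * log(beta[k] / (2 * pi)) - 0.5 * d - h_wishart
    }
    lb <- e_pX + e_pZ + e_ppi + e_pmulam - q_Z - q_pi - q_mulam
    if (is.finite(lb_prev) &&
        abs(lb - lb_prev) < tol * (abs(lb_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    lb_prev <- lb
  }
  list(r = r, alpha = alpha, beta = beta, nu = nu, m = m, Winv = Winv,
       lb = lb, converged = converged)
}

#' Fit a Bayesian-Gaussian mixture to a point cloud
#'
#' Variational inference for a Gaussian mixture with Dirichlet weight prior
#' (concentration 1/K per component, giving DP-style pruning of surplus
#' components) and Normal-Wishart priors on the component parameters.
#' Member counts come from hard (argmax-responsibility) assignment; a
#' component is flagged significant when it has at least `min_members`
#' members — the screening rule applied downstream.
#'
#' @param points numeric matrix (n x d) or data frame of coordinates.
#' @param max_components upper bound on mixture size (capped at the number
#'   of distinct points).
#' @param seed integer seed; the fit is fully deterministic given it.
#' @param min_members significance threshold on member count (default 20).
#' @param n_init number of restarts; restarts initialise from k-means
#'   partitions at a ladder of granularities between `max_components` and 1,
#'   and the best lower bound wins.
#' @param tol relative convergence tolerance on the variational lower
#'   bound.
#' @param max_iter iteration cap per run.
#' @param reg ridge added to component covariances, squared Angstrom.
#' @return object of class `pf_bgmm`: list with `components` (each having
#'   `mean`, `cov`, `weight`, `member_count`, `significant`), `n_points`,
#'   `converged`, `seed`.
#' @export
fit_group_bgmm <- function(points, max_components = 10, seed = 1,
                           min_members = 20, n_init = 5, tol = 1e-3,
                           max_iter = 500, reg = 1e-4) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (n < 1) stop("at least one point is required")
  if (max_components < 1) stop("max_components must be >= 1")
  n_distinct <- nrow(unique(X))
  K <- max(1L, min(as.integer(max_components), n_distinct))

  alpha0 <- 1 / K
  beta0 <- 1
  m0 <- colMeans(X)
  nu0 <- d + 2

  # seeded k-means hard starts; RNG state restored afterwards
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  # Restarts are seeded k-means partitions at a ladder of granularities
  # from K down to 1 (points start in the first k of the K components).
  # Variational updates merge surplus components far more readily than they
  # split merged ones, so at least one start must sit at or just above the
  # true component count; the ELBO then picks the winner across starts.
  k_ladder <- unique(pmax(1L, pmin(K, as.integer(round(
    K^seq(1, 0, length.out = n_init))))))
  fit_with_scale <- function(W0inv) {
    best <- NULL
    for (init in seq_along(k_ladder)) {
      set.seed(seed + 7919L * (init - 1L))
      k_init <- k_ladder[init]
      z0 <- if (k_init == 1) {
        rep(1L, n)
      } else {
        km <- tryCatch(stats::kmeans(X, centers = k_init, iter.max = 25,
                                     nstart = 1),
                       error = function(e) NULL)
        if (is.null(km)) sample.int(k_init, n, replace = TRUE)
        else km$cluster
      }
      run <- .pf_vb_run(X, K, z0, alpha0, beta0, m0, nu0, W0inv,
                        reg, tol, max_iter)
      if (is.null(best) || run$lb > best$lb) best <- run
    }
    best
  }

  # Empirical-Bayes calibration of the Wishart scale: a first pass under a
  # data-covariance prior yields component covariances at roughly the
  # pattern scale; the prior is then reset to their member-weighted average
  # and the model refitted. A prior at the spread of the whole group makes
  # broad merged components cheap; one far below the pattern scale makes
  # needle components cheap — tying it to the fitted scale avoids both.
  vr <- apply(X, 2, stats::var)
  vr[!is.finite(vr) | vr < reg] <- reg
  # Greedy ELBO-guided merge refinement: over-splitting a cluster is the
  # typical local optimum, and variational updates rarely escape it on
  # their own. Re-running from a hard start in which one pair of occupied
  # components is pooled either raises the lower bound (merge accepted) or
  # not (solution kept); repeated until no pooled start wins. Deterministic
  # and monotone in the ELBO.
  merge_refine <- function(best, W0inv) {
    repeat {
      occ <- which(colSums(best$r) > 0.5)
      if (length(occ) < 2) return(best)
      improved <- FALSE
      for (a in seq_along(occ)[-length(occ)]) {
        for (b in seq((a + 1), length(occ))) {
          r2 <- best$r
          r2[, occ[a]] <- r2[, occ[a]] + r2[, occ[b]]
          r2[, occ[b]] <- 0
          run <- .pf_vb_run(X, K, max.col(r2, ties.method = "first"),
                            alpha0, beta0, m0, nu0, W0inv, reg, tol,
                            max_iter)
          if (run$lb > best$lb + 1e-9) {
            best <- run
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) return(best)
    }
  }

  pass1 <- fit_with_scale(diag(vr, d))
  z1 <- max.col(pass1$r, ties.method = "first")
  cnt1 <- tabulate(z1, nbins = K)
  s2 <- 0
  for (k in which(cnt1 > 0)) {
    covk <- pass1$Winv[[k]] / (pass1$nu[k] - d - 1)
    s2 <- s2 + cnt1[k] * mean(diag(covk))
  }
  s2 <- max(s2 / n, reg)
  best <- merge_refine(fit_with_scale(diag(nu0 * s2, d)),
                       diag(nu0 * s2, d))

  z <- max.col(best$r, ties.method = "first")
  counts <- tabulate(z, nbins = K)
  w <- best$alpha / sum(best$alpha)
  comps <- lapply(seq_len(K), function(k) {
    covk <- best$Winv[[k]] / (best$nu[k] - d - 1)
    covk <- (covk + t(covk)) / 2
    list(mean = as.numeric(best$m[k, ]), cov = covk,
         weight = w[k], member_count = as.integer(counts[k]),
         significant = counts[k] >= min_members)
  })
  structure(list(components = comps, n_points = n, d = d,
                 converged = best$converged, seed = as.integer(seed),
                 min_members = as.integer(min_members)),
            class = "pf_bgmm")
}

#' @export
print.pf_bgmm <- function(x, ...) {
  ns <- sum(vapply(x$components, `[[`, logical(1), "significant"))
  cat(sprintf("<pf_bgmm: %d points, %d components (%d significant)%s>\n",
              x$n_points, length(x$components), ns,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

# Posterior responsibilities of new points under a fitted mixture, from the
# serialisable (weight, mean, cov) summary.
.pf_bgmm_responsibilities <- function(comps, X) {
  X <- matrix(as.numeric(X), ncol = length(comps[[1]]$mean))
  lp <- vapply(comps, function(cp)
    log(max(cp$weight, 1e-300)) + .pf_dmvnorm_log(X, cp$mean, cp$cov),
    numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  exp(lp - .pf_logsumexp_rows(lp))
}
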