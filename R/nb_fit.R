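#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalizing sequencing depth: each sample's
#' factor is the median across genes of its counts divided by the gene's
#' geometric mean over samples (genes with a zero anywhere drop out of the
#' reference).  Factors are rescaled so their geometric mean is 1.
#'
#' @param counts numeric gene-by-sample matrix (non-negative; fractional
#'   expected counts are accepted).
#' @return a positive numeric vector, one factor per sample, geometric mean 1.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' estimate_size_factors(m)  # ratio 2, geometric mean 1
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; ",
         "size factors cannot be estimated (consider subsetting to samples ",
         "sharing a positive gene set)", call. = FALSE)
  cp <- counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(cp)))       # geometric-mean reference gene
  sf <- apply(cp / ref, 2L, median)
  sf / exp(mean(log(sf)))
}

#' Fit per-gene negative-binomial GLMs
#'
#' Fits, for every gene at once, the log-link negative-binomial GLM
#' `K_gj ~ NB(mean = s_j * exp(x_j' beta_g), variance = mu + alpha_g mu^2)`
#' by iteratively reweighted least squares, with the library size factors
#' entering as a fixed offset.  All genes share the design matrix; the IRLS
#' normal equations are solved for all genes simultaneously, which is what
#' makes genome-wide fitting fast in pure R.
#'
#' Counts are rounded to the nearest integer (half-to-even) for the
#' log-likelihood, which is defined on integers; the moment equations of the
#' fit itself accept fractional expected counts unchanged.
#'
#' @param counts gene-by-sample matrix (a single gene may be given as a
#'   one-row matrix or a plain vector).
#' @param design_matrix full-rank numeric design matrix, samples x
#'   coefficients.
#' @param size_factors positive per-sample factors (see
#'   [estimate_size_factors()]).
#' @param dispersions per-gene dispersion alpha (recycled if length 1); 0
#'   gives the Poisson limit.
#' @param tol,max_iter IRLS convergence tolerance on coefficient change and
#'   iteration cap.
#' @return an object of class `nb_fit`: list with `coef` and `se`
#'   (genes x coefficients, natural-log scale), `log2fc` convenience matrix
#'   (`coef / log(2)`), `loglik`, `converged`, `mu` (fitted means), plus the
#'   inputs needed by [wald_test()] and [lrt_interaction()].
#' @examples
#' X <- cbind(1, c(0, 0, 1, 1))
#' k <- matrix(c(10, 10, 40, 40), 1)
#' f <- fit_nb_glm(k, X, size_factors = rep(1, 4), dispersions = 0)
#' f$log2fc[, 2]  # exactly 2
#' @export
fit_nb_glm <- function(counts, design_matrix, size_factors, dispersions,
                       tol = 1e-8, max_iter = 100) {
  K <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  X <- as.matrix(design_matrix)
  G <- nrow(K); n <- ncol(K); p <- ncol(X)
  if (nrow(X) != n) stop("design matrix rows must match samples", call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is not full rank", call. = FALSE)
  if (length(size_factors) != n)
    stop("need one size factor per sample", call. = FALSE)
  alpha <- rep_len(pmax(dispersions, 0), G)

  O <- matrix(log(size_factors), G, n, byrow = TRUE)
  LY <- log(sweep(K, 2L, size_factors, "/") + 0.5)
  beta <- LY %*% X %*% solve(crossprod(X))
  XX <- lapply(seq_len(p), function(a) X * X[, a])  # n x p blocks of x_a*x_b

  converged <- rep(FALSE, G)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(tcrossprod(beta, X) + O, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    Z <- (eta - O) + (K - mu) / mu
    B <- (W * Z) %*% X
    A <- lapply(XX, function(xx) W %*% xx)   # A[[a]][g, b] = (X' W_g X)[a, b]
    newbeta <- beta
    if (p == 1L) {
      newbeta[, 1] <- B[, 1] / A[[1]][, 1]
    } else if (p == 2L) {
      a11 <- A[[1]][, 1]; a12 <- A[[1]][, 2]; a22 <- A[[2]][, 2]
      det <- a11 * a22 - a12^2
      newbeta[, 1] <- (a22 * B[, 1] - a12 * B[, 2]) / det
      newbeta[, 2] <- (a11 * B[, 2] - a12 * B[, 1]) / det
    } else {
      for (g in seq_len(G)) {
        Ag <- vapply(A, function(m) m[g, ], numeric(p))
        bg <- tryCatch(solve(Ag, B[g, ]), error = function(e) beta[g, ])
        newbeta[g, ] <- bg
      }
    }
    bad <- !is.finite(newbeta)
    if (any(bad)) newbeta[bad] <- beta[bad]
    delta <- apply(abs(newbeta - beta), 1L, max)
    beta <- newbeta
    converged <- converged | delta < tol * (1 + apply(abs(beta), 1L, max))
    if (all(converged)) break
  }

  eta <- pmin(pmax(tcrossprod(beta, X) + O, -30), 30)
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  se <- matrix(NA_real_, G, p)
  if (p <= 2L) {
    if (p == 1L) {
      se[, 1] <- 1 / sqrt((W %*% XX[[1]])[, 1])
    } else {
      a11 <- (W %*% XX[[1]])[, 1]; a12 <- (W %*% XX[[1]])[, 2]
      a22 <- (W %*% XX[[2]])[, 2]
      det <- a11 * a22 - a12^2
      se[, 1] <- sqrt(a22 / det); se[, 2] <- sqrt(a11 / det)
    }
  } else {
    A <- lapply(XX, function(xx) W %*% xx)
    for (g in seq_len(G)) {
      Ag <- vapply(A, function(m) m[g, ], numeric(p))
      v <- tryCatch(diag(chol2inv(chol(Ag))), error = function(e) rep(NA_real_, p))
      se[g, ] <- sqrt(v)
    }
  }

  Ki <- round(K)  # half-to-even; likelihood is defined on integers
  size <- 1 / pmax(alpha, 1e-12)
  ll <- rowSums(matrix(dnbinom(as.vector(Ki), size = rep(size, n),
                               mu = as.vector(mu), log = TRUE), G))
  pois <- alpha == 0
  if (any(pois)) {
    llp <- rowSums(matrix(dpois(as.vector(Ki[pois, , drop = FALSE]),
                                lambda = as.vector(mu[pois, , drop = FALSE]),
                                log = TRUE), sum(pois)))
    ll[pois] <- llp
  }

  dimnames(beta) <- dimnames(se) <- list(rownames(K), colnames(X))
  structure(list(coef = beta, se = se, log2fc = beta / log(2),
                 loglik = ll, converged = converged, mu = mu,
                 dispersions = alpha, design_matrix = X,
                 size_factors = size_factors, n_iter = it),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("Negative-binomial GLM fit: %d gene(s), %d coefficient(s) [%s]\n",
              nrow(x$coef), ncol(x$coef),
              paste(colnames(x$coef), collapse = ", ")))
  cat(sprintf("  converged: %d/%d (IRLS, %d iterations)\n",
              sum(x$converged), length(x$converged), x$n_iter))
  invisible(x)
}

# Cox-Reid adjusted profile log-likelihood of log-dispersion on a grid,
# for all genes at once; mu is held at fitted means.
cr_loglik_grid <- function(K, mu, X, grid) {
  G <- nrow(K); n <- ncol(K); p <- ncol(X)
  Ki <- round(K)
  Kv <- as.vector(Ki); muv <- as.vector(mu)
  ll <- matrix(0, G, length(grid))
  for (i in seq_along(grid)) {
    a <- exp(grid[i])
    lg <- rowSums(matrix(dnbinom(Kv, size = 1 / a, mu = muv, log = TRUE), G))
    W <- mu / (1 + a * mu)
    # -0.5 log det(X' W X): closed form for p <= 2, chol for the rest
    if (p == 1L) {
      ld <- log(pmax(rowSums(W * X[, 1]^2), 1e-300))
    } else if (p == 2L) {
      a11 <- as.vector(W %*% (X[, 1] * X[, 1]))
      a12 <- as.vector(W %*% (X[, 1] * X[, 2]))
      a22 <- as.vector(W %*% (X[, 2] * X[, 2]))
      ld <- log(pmax(a11 * a22 - a12^2, 1e-300))
    } else {
      XX <- lapply(seq_len(p), function(a2) X * X[, a2])
      A <- lapply(XX, function(xx) W %*% xx)
      ld <- vapply(seq_len(G), function(g) {
        Ag <- vapply(A, function(m) m[g, ], numeric(p))
        d <- tryCatch(2 * sum(log(diag(chol(Ag)))), error = function(e) 0)
        d
      }, numeric(1))
    }
    ll[, i] <- lg - 0.5 * ld
  }
  ll
}

#' Estimate gene-wise negative-binomial dispersions
#'
#' Estimates the dispersion alpha in `variance = mu + alpha * mu^2` for every
#' gene.  Three methods are provided:
#'
#' * `"shrink"` (default): genes are binned by mean normalized count and a
#'   trend dispersion is estimated per bin by maximizing the bin's summed
#'   Cox-Reid-adjusted log-likelihood (pooling makes the trend nearly
#'   unbiased even at a handful of replicates), then smoothed.  Each gene's
#'   final estimate is the posterior mean of its own adjusted likelihood
#'   under a log-normal prior centred on the trend, whose width is estimated
#'   from the excess spread of gene-wise estimates over their known sampling
#'   noise.  This empirical-Bayes moderation is what keeps the downstream
#'   normal-reference Wald test calibrated with as few as three replicates
#'   per group.
#' * `"moments"`: per-gene chi-square matching — alpha solves
#'   `sum (k - mu)^2 / (mu + alpha mu^2) = n - p`, floored at `min_disp`.
#' * `"ml"`: per-gene maximum of the Cox-Reid-adjusted likelihood (no
#'   shrinkage).
#'
#' All-zero genes get `NA` (they carry no information and are excluded from
#' testing).
#'
#' @param counts gene-by-sample matrix.
#' @param size_factors per-sample size factors.
#' @param design_matrix design matrix of the model the dispersion is for.
#' @param method `"shrink"`, `"moments"` or `"ml"`.
#' @param min_disp floor for the estimates.
#' @return numeric vector of per-gene dispersions (named if `counts` has
#'   rownames), with attribute `"trend"` for method `"shrink"`.
#' @export
estimate_dispersion <- function(counts, size_factors, design_matrix,
                                method = c("shrink", "moments", "ml"),
                                min_disp = 1e-8) {
  method <- match.arg(method)
  K <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  X <- as.matrix(design_matrix)
  G <- nrow(K); n <- ncol(K); p <- ncol(X)
  if (n - p < 2)
    stop("need at least 2 residual degrees of freedom per gene", call. = FALSE)
  allzero <- rowSums(K) == 0
  out <- rep(NA_real_, G)
  names(out) <- rownames(K)
  if (all(allzero)) return(out)

  Ku <- K[!allzero, , drop = FALSE]
  fit0 <- fit_nb_glm(Ku, X, size_factors, dispersions = 0.1)
  mu <- fit0$mu

  if (method == "moments") {
    f <- function(a) rowSums((Ku - mu)^2 / (mu + a * mu^2)) - (n - p)
    lo <- rep(min_disp, nrow(Ku)); hi <- rep(100, nrow(Ku))
    at_floor <- f(min_disp) <= 0
    for (i in 1:50) {
      mid <- sqrt(lo * hi)
      v <- f(mid)
      lo <- ifelse(v > 0, mid, lo); hi <- ifelse(v > 0, hi, mid)
    }
    a <- sqrt(lo * hi)
    a[at_floor] <- min_disp
    out[!allzero] <- a
    return(out)
  }

  grid <- seq(log(1e-6), log(20), length.out = 120)
  ll <- cr_loglik_grid(Ku, mu, X, grid)

  if (method == "ml") {
    out[!allzero] <- pmax(exp(grid[max.col(ll, ties.method = "first")]),
                          min_disp)
    return(out)
  }

  # trended empirical-Bayes shrinkage
  mn <- rowMeans(sweep(Ku, 2L, size_factors, "/"))
  ord <- order(mn)
  n_bins <- max(1L, min(floor(nrow(Ku) / 50), 50L))
  bins <- if (n_bins < 2L) list(ord) else
    split(ord, cut(seq_along(ord), n_bins, labels = FALSE))
  bx <- vapply(bins, function(ix) median(log(mn[ix] + 1e-8)), numeric(1))
  by <- vapply(bins, function(ix) {
    grid[which.max(colSums(ll[ix, , drop = FALSE]))]
  }, numeric(1))
  if (n_bins >= 3) {
    sm <- lowess(bx, by, f = 0.3)
    tr <- exp(approx(sm$x, sm$y, xout = log(mn + 1e-8), rule = 2)$y)
  } else {
    tr <- rep(exp(median(by)), nrow(Ku))
  }

  amle <- exp(grid[max.col(ll, ties.method = "first")])
  hi <- mn > 100 & amle > 2e-6 & amle < 15
  s2 <- if (sum(hi) > 50) {
    max(mad(log(amle[hi] / tr[hi]))^2 - trigamma((n - p) / 2), 0.01)
  } else 0.01
  s2 <- min(s2, 2)

  lpost <- ll - 0.5 * outer(log(tr), grid, "-")^2 / s2
  lw <- lpost - apply(lpost, 1L, max)
  w <- exp(lw)
  a <- pmax(exp(as.vector(w %*% grid) / rowSums(w)), min_disp)
  out[!allzero] <- a
  attr(out, "trend") <- tr
  attr(out, "prior_var") <- s2
  out
}

#' Wald test of a GLM coefficient
#'
#' Tests a fitted coefficient against zero with a standard-normal reference:
#' `z = beta / se`, two-sided `p = 2 (1 - Phi(|z|))` or one-sided greater
#' `p = 1 - Phi(z)`.  Genes with a failed fit or zero standard error get a
#' missing p-value (replacement by 1 is the business of the selection stage,
#' where missing comparisons are treated as uninformative).
#'
#' @param fit an [fit_nb_glm()] result.
#' @param coefficient column name or index of the coefficient to test.
#' @param sided `"two"` or `"greater"`.
#' @return list with `statistic` (z) and `p`, one entry per gene.
#' @export
wald_test <- function(fit, coefficient, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  stopifnot(inherits(fit, "nb_fit"))
  b <- fit$coef[, coefficient]
  s <- fit$se[, coefficient]
  z <- b / s
  bad <- !fit$converged | !is.finite(s) | s <= 0
  z[bad] <- NA_real_
  p <- if (sided == "two") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
  list(statistic = z, p = p)
}

#' Likelihood-ratio test for nested negative-binomial GLMs
#'
#' Compares a full and a reduced fit of the same genes (the reduced design
#' must be nested in the full one; in the interaction analysis the reduced
#' model drops the experiment-by-condition interaction, so the test asks
#' whether the IP/input enrichment ratio differs between the two
#' experiments — the "ratio of ratios").  The statistic is
#' `2 (ll_full - ll_reduced)` referred to a chi-square with df equal to the
#' difference in coefficient count.
#'
#' @param full_fit,reduced_fit [fit_nb_glm()] results on the same genes,
#'   fitted with the same dispersions.
#' @return list with `statistic`, `df`, `p`, and `flagged` (genes where the
#'   full model's likelihood fell below the reduced one beyond tolerance,
#'   indicating an optimization failure; their p is missing).
#' @export
lrt_interaction <- function(full_fit, reduced_fit) {
  stopifnot(inherits(full_fit, "nb_fit"), inherits(reduced_fit, "nb_fit"))
  df <- ncol(full_fit$coef) - ncol(reduced_fit$coef)
  if (df < 0)
    stop("reduced design must not have more coefficients than the full design",
         call. = FALSE)
  stat <- 2 * (full_fit$loglik - reduced_fit$loglik)
  flagged <- stat < -1e-6
  stat <- pmax(stat, 0)
  # identical designs give a degenerate 0-df test: statistic 0, p 1
  p <- pchisq(stat, df = max(df, 1L), lower.tail = FALSE)
  p[flagged] <- NA_real_
  list(statistic = stat, df = df, p = p, flagged = flagged)
}
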