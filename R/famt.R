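#' Fit the factor-analytic model for multiple testing
#'
#' Models each gene's expression as `x_gi = mu_g + beta_g * trait_i +
#' b_g' z_i + e_gi`, where the `q`-dimensional scores `z_i ~ N(0, I)` capture
#' expression heterogeneity shared across genes and independent of the trait,
#' and `e_gi ~ N(0, psi_g)` is gene-specific noise. The model is estimated by
#' EM: the E step computes the posterior moments of the factor scores given
#' the current loadings and specific variances, and the M step re-estimates
#' `(mu_g, beta_g, b_g)` jointly by per-gene regression on `(1, trait,
#' E[z])` — re-estimating the trait coefficient inside the loop is what keeps
#' the factors independent of the trait. The EM is initialized
#' deterministically from a principal-component decomposition of the
#' trait-residuals. The factor-adjusted expression is
#' `x - B %*% t(Z)` (the linear dependence kernel subtracted), with `Z` the
#' posterior-mean scores; for `q = 0` it equals the input exactly.
#'
#' @inheritParams correlation_test
#' @param q Number of factors (>= 0); must satisfy `q < n_animals - 2`.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500); non-convergence
#'   raises an error of class `famt_no_convergence` carrying the
#'   log-likelihood trace.
#' @return An object of class `famt_fit` with elements `q`, `loadings`
#'   (genes x q), `scores` (animals x q posterior means), `psi`, `beta`,
#'   `mu`, `adjusted` (genes x animals matrix), `loglik` (per-iteration
#'   trace), `n_iter`, `converged`, `gene_id`, `animals`, `trait`.
#' @export
famt_fit <- function(expr, trait, q, tol = 1e-6, max_iter = 500) {
  X <- expr_matrix(expr)
  y <- extract_trait(trait, colnames(X))
  m <- nrow(X); n <- ncol(X)
  q <- as.integer(q)
  if (q < 0L) stop("q must be >= 0", call. = FALSE)
  if (q >= n - 2L) stop("q must be < n_animals - 2", call. = FALSE)
  if (q >= m) stop("q must be < n_genes", call. = FALSE)

  D <- rbind(1, y)                       # 2 x n design of the fixed part
  ols <- X %*% t(D) %*% solve(D %*% t(D))
  R0 <- X - ols %*% D
  if (q == 0L) {
    psi <- pmax(rowSums(R0^2) / n, 1e-8)
    ll <- diag_loglik(R0, psi)
    return(new_famt_fit(q, matrix(0, m, 0), matrix(0, n, 0), psi,
                        beta = ols[, 2L], mu = ols[, 1L], adjusted = X,
                        loglik = ll, n_iter = 0L, converged = TRUE,
                        gene_id = rownames(X), animals = colnames(X),
                        trait = y))
  }

  sv <- svd(R0, nu = q, nv = 0)
  B <- sv$u %*% diag(sv$d[seq_len(q)] / sqrt(n), q, q)
  v0 <- rowSums(R0^2) / n
  psi <- pmax(v0 - rowSums(B^2), 0.05 * v0)
  Theta <- cbind(ols, matrix(0, m, q))
  ll_trace <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    R <- X - Theta[, 1:2, drop = FALSE] %*% D
    Bp <- B / psi
    M <- diag(q) + crossprod(B, Bp)
    G <- chol2inv(chol(M))
    Zhat <- t(R) %*% Bp %*% G            # n x q posterior means

    ll <- fa_loglik(R, B, psi, Bp, M, G)
    ll_trace <- c(ll_trace, ll)
    if (it > 1L) {
      rel <- abs(ll - ll_trace[it - 1L]) /
        (abs(ll_trace[it - 1L]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }

    W <- cbind(t(D), Zhat)               # n x (2 + q)
    A <- crossprod(W)
    zi <- 2L + seq_len(q)
    A[zi, zi] <- A[zi, zi] + n * G       # E[zz'] correction
    bmat <- X %*% W
    Theta <- bmat %*% solve(A)
    psi <- pmax((rowSums(X^2) - rowSums(Theta * bmat)) / n, 1e-8)
    B <- Theta[, zi, drop = FALSE]
  }
  if (!converged) {
    rlang::abort(
      sprintf("EM did not converge in %d iterations", max_iter),
      class = "famt_no_convergence", loglik_trace = ll_trace
    )
  }
  # Adjustment scores. The EM protects the trait direction while estimating
  # (B, Psi), but the dependence kernel must also capture the *realized*
  # sample correlation between the factors and the trait -- that correlation
  # is precisely what correlates the classical test statistics. The scores
  # used for adjustment are therefore the factor posteriors of the
  # mean-centered data (trait direction included); with few trait-associated
  # genes among many, their leakage into the scores is negligible.
  Bp <- B / psi
  G <- chol2inv(chol(diag(q) + crossprod(B, Bp)))
  Zhat <- t(X - Theta[, 1L]) %*% Bp %*% G
  new_famt_fit(q, B, Zhat, psi, beta = Theta[, 2L], mu = Theta[, 1L],
               adjusted = X - B %*% t(Zhat), loglik = ll_trace,
               n_iter = length(ll_trace), converged = TRUE,
               gene_id = rownames(X), animals = colnames(X), trait = y)
}

fa_loglik <- function(R, B, psi, Bp, M, G) {
  n <- ncol(R); m <- nrow(R)
  U <- crossprod(Bp, R)                  # q x n
  quad <- sum(R^2 / psi) - sum(U * (G %*% U))
  logdet <- as.numeric(determinant(M, logarithm = TRUE)$modulus) +
    sum(log(psi))
  -0.5 * (n * m * log(2 * pi) + n * logdet + quad)
}

diag_loglik <- function(R, psi) {
  n <- ncol(R); m <- nrow(R)
  -0.5 * (n * m * log(2 * pi) + n * sum(log(psi)) + sum(R^2 / psi))
}

new_famt_fit <- function(q, B, Z, psi, beta, mu, adjusted, loglik, n_iter,
                         converged, gene_id, animals, trait) {
  rownames(B) <- gene_id
  rownames(Z) <- animals
  structure(
    list(q = q, loadings = B, scores = Z, psi = psi, beta = beta, mu = mu,
         adjusted = adjusted, loglik = loglik, n_iter = n_iter,
         converged = converged, gene_id = gene_id, animals = animals,
         trait = trait),
    class = "famt_fit"
  )
}

#' @export
print.famt_fit <- function(x, ...) {
  cat(sprintf("<famt_fit: q = %d factors, %d genes x %d animals>\n",
              x$q, length(x$gene_id), length(x$animals)))
  cat(sprintf("  EM %s after %d iterations; log-likelihood %.2f\n",
              if (x$converged) "converged" else "stopped", x$n_iter,
              utils::tail(x$loglik, 1)))
  invisible(x)
}

#' @describeIn famt_fit Per-gene tidy view: trait coefficient, specific
#'   variance and loadings.
#' @param x A `famt_fit`.
#' @param ... Unused.
#' @export
tidy.famt_fit <- function(x, ...) {
  out <- tibble::tibble(gene_id = x$gene_id, beta = unname(x$beta),
                        psi = unname(x$psi))
  if (x$q > 0) {
    L <- tibble::as_tibble(as.data.frame(x$loadings))
    names(L) <- sprintf("loading%d", seq_len(x$q))
    out <- dplyr::bind_cols(out, L)
  }
  out
}

#' @rdname tidy.famt_fit
#' @export
glance.famt_fit <- function(x, ...) {
  tibble::tibble(
    q = x$q, n_genes = length(x$gene_id), n_animals = length(x$animals),
    loglik = utils::tail(x$loglik, 1), n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Factor-adjusted expression as a tibble
#'
#' @param fit A [famt_fit()].
#' @return Wide expression tibble of the factor-adjusted values.
#' @export
adjusted_expression <- function(fit) {
  stopifnot(inherits(fit, "famt_fit"))
  out <- tibble::as_tibble(as.data.frame(fit$adjusted))
  names(out) <- fit$animals
  dplyr::bind_cols(tibble::tibble(gene_id = fit$gene_id), out)
}

#' Factor-adjusted association tests
#'
#' Recomputes the per-gene correlation tests on the factor-adjusted
#' expression of a fitted model. With `q = 0` this equals the classical
#' [correlation_test()] output exactly; with `q > 0` the common-factor
#' contribution has been removed, which decorrelates the test statistics.
#'
#' @param fit A [famt_fit()].
#' @param trait Optional trait; defaults to the trait the model was fitted
#'   with.
#' @return The [correlation_test()] tibble on adjusted expression.
#' @export
factor_adjusted_tests <- function(fit, trait = NULL) {
  stopifnot(inherits(fit, "famt_fit"))
  y <- if (is.null(trait)) fit$trait else extract_trait(trait, fit$animals)
  correlation_test(fit$adjusted, y)
}

#' Choose the number of hidden factors
#'
#' Fits the factor model for `q = 0, ..., q_max` and evaluates, for each `q`,
#' the mean squared off-diagonal gene-gene correlation of the factor-adjusted
#' expression. This is a variance-inflation criterion: the variance of
#' false-positive counts in multiple testing grows with the sum of squared
#' inter-gene correlations, so the criterion measures the dependence left
#' unexplained by `q` factors. Under-adjustment leaves common structure
#' (criterion above its independence level, about `1/(n - 1)`);
#' over-adjustment projects the residuals into fewer effective dimensions and
#' inflates spurious correlations again, so the criterion has an interior
#' minimum. The smallest `q` attaining the minimum is returned; `q = 0` is a
#' legal answer. The robust variance of the adjusted test statistics
#' (squared scaled IQR, ideally 1) is reported alongside as a diagnostic.
#'
#' @inheritParams famt_fit
#' @param q_max Largest number of factors to consider (default 8).
#' @return The selected `q` (integer) with attribute `criterion`, a tibble
#'   with columns `q`, `mean_sq_cor`, `stat_variance`.
#' @export
estimate_n_factors <- function(expr, trait, q_max = 8, tol = 1e-6,
                               max_iter = 500) {
  X <- expr_matrix(expr)
  y <- extract_trait(trait, colnames(X))
  n <- ncol(X)
  q_max <- min(as.integer(q_max), n - 3L)
  if (q_max < 0L) stop("too few animals to fit any factor model", call. = FALSE)
  rows <- vector("list", q_max + 1L)
  for (q in 0:q_max) {
    fit <- famt_fit(X, y, q = q, tol = tol, max_iter = max_iter)
    stats_q <- factor_adjusted_tests(fit)
    v <- (stats::IQR(stats_q$t_corr, na.rm = TRUE) / 1.349)^2
    rows[[q + 1L]] <- tibble::tibble(
      q = q,
      mean_sq_cor = mean_sq_offdiag_cor(fit$adjusted),
      stat_variance = v
    )
  }
  crit <- dplyr::bind_rows(rows)
  q_hat <- crit$q[which.min(crit$mean_sq_cor)]
  attr(q_hat, "criterion") <- crit
  q_hat
}

mean_sq_offdiag_cor <- function(X) {
  keep <- apply(X, 1L, stats::sd) > 0
  Xs <- X[keep, , drop = FALSE]
  Xs <- Xs - rowMeans(Xs)
  Xs <- Xs / sqrt(rowSums(Xs^2))
  m <- nrow(Xs)
  # ||R R'||_F^2 computed on the small n x n Gram matrix; the diagonal of the
  # gene-gene correlation matrix is identically 1.
  A <- crossprod(Xs)
  (sum(A^2) - m) / (m * (m - 1))
}
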