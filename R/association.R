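#' Per-gene correlation tests against the trait
#'
#' Computes, for every gene, the Pearson correlation between its expression
#' and the trait, the t transform `t = r sqrt((n - 2) / (1 - r^2))`, a
#' two-sided p-value on `n - 2` degrees of freedom, and the
#' Benjamini-Hochberg adjusted p-value. Genes with zero expression variance
#' are flagged (`tested = FALSE`) rather than tested.
#'
#' @param expr Wide expression tibble (`gene_id` + one column per animal) or a
#'   genes x animals numeric matrix with rownames.
#' @param trait Numeric trait vector aligned with the animal columns, or a
#'   phenotype tibble with `animal` and `trait` (or `trait_adj`) columns.
#' @return A tibble with one row per gene: `gene_id`, `r`, `t_corr`,
#'   `p_corr`, `p_bh`, `tested`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene_id = "g1", a = 1, b = 2, c = 3, d = 4)
#' correlation_test(expr, c(2, 4, 6, 8))  # r = 1 for an affine image
correlation_test <- function(expr, trait) {
  em <- expr_matrix(expr)
  y <- extract_trait(trait, colnames(em))
  n <- length(y)
  if (n < 4L) stop("at least 4 animals are required", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("degenerate input: the trait is constant", call. = FALSE)
  }
  sds <- apply(em, 1L, stats::sd)
  tested <- sds > 0
  r <- rep(NA_real_, nrow(em))
  r[tested] <- as.numeric(stats::cor(t(em[tested, , drop = FALSE]), y))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  tibble::tibble(
    gene_id = rownames(em),
    r = r,
    t_corr = tstat,
    p_corr = p,
    p_bh = bh_adjust_allow_zero(p),
    tested = tested
  )
}

expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr))) {
      rownames(expr) <- sprintf("gene%04d", seq_len(nrow(expr)))
    }
    return(expr)
  }
  stopifnot("gene_id" %in% names(expr))
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  rownames(m) <- expr$gene_id
  m
}

#' Extreme-group differential expression t-tests
#'
#' Tests each gene for a mean difference between the `k` lowest-trait and `k`
#' highest-trait animals (equal-variance two-sided Student test by default;
#' Welch optional). Ties straddling the k-th rank are broken
#' deterministically by animal order, and such ties are reported in the
#' `ties` attribute.
#'
#' @inheritParams correlation_test
#' @param k Animals per extreme group (default 10).
#' @param var_equal Pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @return A tibble with `gene_id`, `t_ttest`, `p_ttest`, `p_bh_ttest`,
#'   `tested`.
#' @export
extreme_group_ttest <- function(expr, trait, k = 10, var_equal = TRUE) {
  em <- expr_matrix(expr)
  y <- extract_trait(trait, colnames(em))
  n <- length(y)
  if (2 * k > n) stop("2k must not exceed the number of animals", call. = FALSE)
  ord <- order(y, seq_len(n))    # tie-break on input (animal) order
  lo <- ord[seq_len(k)]
  hi <- ord[seq.int(n - k + 1L, n)]
  boundary_tie <- (k < n && y[ord[k]] == y[ord[k + 1L]]) ||
    (k < n && y[ord[n - k + 1L]] == y[ord[n - k]])
  sds <- apply(em, 1L, stats::sd)
  tested <- sds > 0
  tt <- rep(NA_real_, nrow(em))
  pp <- rep(NA_real_, nrow(em))
  for (g in which(tested)) {
    ht <- stats::t.test(em[g, lo], em[g, hi], var.equal = var_equal)
    tt[g] <- unname(ht$statistic)
    pp[g] <- ht$p.value
  }
  out <- tibble::tibble(
    gene_id = rownames(em),
    t_ttest = tt,
    p_ttest = pp,
    p_bh_ttest = bh_adjust_allow_zero(pp),
    tested = tested
  )
  attr(out, "groups") <- list(low = colnames(em)[lo], high = colnames(em)[hi])
  attr(out, "boundary_tie") <- boundary_tie
  if (boundary_tie) {
    message("trait ties straddle the extreme-group boundary; ",
            "broken by animal order")
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, capped at 1
#' and monotone in rank. Values outside (0, 1] are rejected.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(pvals) {
  ok <- stats::na.omit(pvals)
  if (any(ok <= 0 | ok > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

# Internal variant tolerating exact zeros (|r| = 1) and NAs from untested
# genes.
bh_adjust_allow_zero <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Classical trait-associated gene lists
#'
#' Builds the two uncorrected gene lists of the classical analysis: the
#' correlation list (`p_corr < alpha`) and its union with the extreme-group
#' differential-expression list (`p_corr < alpha` or `p_ttest < alpha`).
#'
#' @param corr_results Output of [correlation_test()].
#' @param ttest_results Output of [extreme_group_ttest()] on the same genes.
#' @param alpha Nominal significance cutoff (default 0.05, uncorrected).
#' @return The joined per-gene tibble with logical columns `in_corr_list` and
#'   `in_union_list`.
#' @export
classical_gene_lists <- function(corr_results, ttest_results, alpha = 0.05) {
  stopifnot(identical(corr_results$gene_id, ttest_results$gene_id))
  dplyr::left_join(corr_results,
                   dplyr::select(ttest_results, "gene_id", "t_ttest",
                                 "p_ttest", "p_bh_ttest"),
                   by = "gene_id") |>
    dplyr::mutate(
      in_corr_list = !is.na(.data$p_corr) & .data$p_corr < alpha,
      in_union_list = .data$in_corr_list |
        (!is.na(.data$p_ttest) & .data$p_ttest < alpha)
    )
}
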