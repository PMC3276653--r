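#' Two-way ANOVA of the trait on two QTL haplotype classes
#'
#' Restricts the family to animals with determined calls at both loci, fits
#' `trait ~ proximal * distal` on the 2x2 haplotype factors, and tests the
#' two main effects and their interaction with Type-II sums of squares
#' (appropriate for the unbalanced design; Type III available via `type`).
#' The two conditional Q-vs-q differences at the proximal locus — one on each
#' distal background — are returned with the cell means.
#'
#' @param trait Trait vector aligned with `table$animal`, or a phenotype
#'   tibble with `trait_adj`/`trait`.
#' @param table A [haplotype_table()].
#' @param type Sums-of-squares type, 2 (default) or 3.
#' @return Object of class `qtl_anova`: list with `anova` (tibble `term`,
#'   `df`, `sumsq`, `statistic`, `p.value`), `cell_means`, `conditional_diff`
#'   (named numeric: `given_distal_Q`, `given_distal_q`), `n_used`, `fit`.
#' @export
two_way_anova_interaction <- function(trait, table, type = 2) {
  stopifnot(inherits(table, "haplotype_table"))
  y <- extract_trait(trait, table$animal)
  keep <- table$proximal != "x" & table$distal != "x"
  dat <- data.frame(
    y = y[keep],
    proximal = factor(table$proximal[keep], levels = c("q", "Q")),
    distal = factor(table$distal[keep], levels = c("q", "Q"))
  )
  cells <- table(dat$proximal, dat$distal)
  if (any(cells == 0)) {
    stop("empty haplotype cell(s): the interaction is inestimable",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ proximal * distal, data = dat)
  an <- car::Anova(fit, type = type)
  an_tbl <- tibble::tibble(
    term = rownames(an),
    df = an$Df,
    sumsq = an$`Sum Sq`,
    statistic = an$`F value`,
    p.value = an$`Pr(>F)`
  )
  cm <- dat |>
    dplyr::group_by(.data$proximal, .data$distal) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y), .groups = "drop")
  get_mean <- function(p, d) cm$mean[cm$proximal == p & cm$distal == d]
  cond <- c(
    given_distal_Q = get_mean("Q", "Q") - get_mean("q", "Q"),
    given_distal_q = get_mean("Q", "q") - get_mean("q", "q")
  )
  structure(
    list(anova = an_tbl, cell_means = cm, conditional_diff = cond,
         n_used = nrow(dat), fit = fit, type = type),
    class = "qtl_anova"
  )
}

#' @export
print.qtl_anova <- function(x, ...) {
  cat(sprintf("<qtl_anova: %d animals with both haplotypes determined>\n",
              x$n_used))
  print(as.data.frame(x$anova), row.names = FALSE)
  cat(sprintf("  proximal Q-q difference: %+.3f | distal Q, %+.3f | distal q\n",
              x$conditional_diff[["given_distal_Q"]],
              x$conditional_diff[["given_distal_q"]]))
  invisible(x)
}

#' @export
tidy.qtl_anova <- function(x, ...) x$anova

#' @export
glance.qtl_anova <- function(x, ...) {
  ia <- x$anova[x$anova$term == "proximal:distal", ]
  tibble::tibble(
    n_used = x$n_used,
    f_interaction = ia$statistic,
    p_interaction = ia$p.value,
    diff_given_distal_Q = x$conditional_diff[["given_distal_Q"]],
    diff_given_distal_q = x$conditional_diff[["given_distal_q"]]
  )
}

#' @export
autoplot.qtl_anova <- function(object, ...) {
  cm <- object$cell_means
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$distal, y = .data$mean,
                                   group = .data$proximal,
                                   colour = .data$proximal)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distal haplotype", y = "trait mean",
                  colour = "proximal", size = "n") +
    ggplot2::theme_minimal()
}

#' Fixed-locus interaction and additive two-QTL scans
#'
#' `interaction_scan()` tests "no QTL" against "one QTL in interaction with a
#' second locus fixed at `fixed_pos`": H0 is `y = mu + a_f w(fixed)`, H1 adds
#' `a_x w(x) + gamma w(x) w(fixed)` (2 extra df). `two_qtl_additive_scan()`
#' tests "one QTL" against "two QTL" by adding only `a_x w(x)` (1 extra df).
#' Both use the transmission coding `w = 2 P(Q) - 1` and report
#' `LRT(x) = n log(RSS0/RSS1)` per position, with an empirical threshold
#' simulated under the corresponding H0 polygenic-only null. If the fixed
#' coding is constant across animals the conditioning is degenerate and the
#' interaction scan collapses to the plain one-QTL scan.
#'
#' @inheritParams scan_chromosome
#' @inheritParams empirical_threshold
#' @param fixed_pos Position (cM, on the grid) of the conditioning QTL.
#' @param n_sim Null simulations for the empirical threshold; `0` skips it.
#' @return A `qtl_scan` with `model = "interaction"` or `"additive"`.
#' @export
interaction_scan <- function(trait, profile, fixed_pos, n_sim = 2000,
                             h2 = 0.5, level = 0.05, seed = 1L,
                             drop_lod = 1) {
  fixed_model_scan(trait, profile, fixed_pos, interaction = TRUE,
                   n_sim = n_sim, h2 = h2, level = level, seed = seed,
                   drop_lod = drop_lod)
}

#' @rdname interaction_scan
#' @export
two_qtl_additive_scan <- function(trait, profile, fixed_pos, n_sim = 2000,
                                  h2 = 0.5, level = 0.05, seed = 1L,
                                  drop_lod = 1) {
  fixed_model_scan(trait, profile, fixed_pos, interaction = FALSE,
                   n_sim = n_sim, h2 = h2, level = level, seed = seed,
                   drop_lod = drop_lod)
}

fixed_model_scan <- function(trait, profile, fixed_pos, interaction,
                             n_sim, h2, level, seed, drop_lod) {
  y <- extract_trait(trait, profile$animals)
  W <- transmission_coding(profile)
  w_fixed <- fixed_coding(profile, fixed_pos)
  if (stats::sd(w_fixed) < 1e-10 && interaction) {
    # all-uninformative or constant transmission at the conditioning locus
    if (all(abs(w_fixed) < 1e-10)) {
      stop("transmission at fixed_pos is uninformative for every animal",
           call. = FALSE)
    }
  }
  model <- if (interaction) "interaction" else "additive"
  lrt <- scan_engine(W, cbind(y), model, w_fixed)[, 1L]
  thr <- if (n_sim > 0) {
    empirical_threshold(profile, n_sim = n_sim, h2 = h2, level = level,
                        seed = seed, model = model, fixed_pos = fixed_pos)
  } else {
    NA_real_
  }
  imax <- which.max(lrt)
  wx <- W[, imax]
  fit1 <- if (interaction) {
    stats::lm(y ~ w_fixed + wx + wx:w_fixed)
  } else {
    stats::lm(y ~ w_fixed + wx)
  }
  effect <- 2 * stats::coef(fit1)[["wx"]]
  out <- new_qtl_scan(profile$grid, lrt, length(y), model = model,
                      fixed_pos = fixed_pos, threshold = as.numeric(thr),
                      effect = effect, effect_sd = effect / stats::sd(y),
                      drop_lod = drop_lod)
  attr(out, "null_maxima") <- attr(thr, "maxima")
  out
}

#' Candidate genes whose expression maps to both QTL regions
#'
#' Screens genes for the three-way signature of a transcript controlled by
#' two interacting loci in the same way as the trait: (1) a detected distal
#' eQTL (classical one-locus scan on the gene's expression, no covariate
#' adjustment; empirical p-value below `alpha_distal`) whose one-LOD support
#' interval overlaps the distal trait-QTL
#' interval; (2) a proximal signal under the fixed-locus interaction model
#' with empirical p-value below `alpha_interaction` and support interval
#' overlapping the proximal trait-QTL interval; (3) differential expression
#' between the two lean subtypes (`lean1` vs `lean2` equal-variance t-test,
#' p below `alpha_de`). If the lean subtypes are unavailable, filter (3) is
#' skipped with a warning.
#'
#' Empirical per-gene p-values for both scan models come from a shared
#' polygenic-null distribution of the maximum LRT, simulated once on the
#' profiled family.
#'
#' @inheritParams correlation_test
#' @inheritParams interaction_scan
#' @param trait_distal_ci,trait_proximal_ci Numeric `c(low, high)` support
#'   intervals of the distal and proximal trait QTL, in cM.
#' @param subtypes Tibble `animal`, `subtype` (needs `lean1` and `lean2`
#'   for the differential-expression filter).
#' @param alpha_distal,alpha_interaction,alpha_de Significance cutoffs for
#'   filters (1), (2) and (3) (defaults 0.1).
#' @param proximal_max_cm Only interaction-scan maxima at or below this
#'   position count as proximal (default the midpoint between the proximal CI
#'   upper bound and `fixed_pos`).
#' @return Per-gene tibble: max positions and LRTs of both scans, empirical
#'   p-values, the three filter logicals, and `candidate` (their
#'   conjunction); class `candidate_screen`.
#' @export
eqtl_candidate_filter <- function(expr, profile, fixed_pos,
                                  trait_distal_ci, trait_proximal_ci,
                                  subtypes = NULL, alpha_distal = 0.1,
                                  alpha_interaction = 0.1, alpha_de = 0.1,
                                  n_sim = 500, h2 = 0.5, seed = 1L,
                                  proximal_max_cm = NULL) {
  em <- expr_matrix(expr)
  genes <- rownames(em)
  Y <- t(em)                               # animals x genes
  Y <- Y[match(profile$animals, rownames(Y)), , drop = FALSE]
  W <- transmission_coding(profile)
  w_fixed <- fixed_coding(profile, fixed_pos)
  grid <- profile$grid
  n <- nrow(W)

  lrt_cl <- lrt_scan_null_vs_one(W, Y)     # positions x genes
  lrt_ia <- lrt_scan_fixed(W, Y, w_fixed, interaction = TRUE)

  thr_cl <- empirical_threshold(profile, n_sim = n_sim, h2 = h2,
                                level = 0.05, seed = seed, model = "one_qtl")
  thr_ia <- empirical_threshold(profile, n_sim = n_sim, h2 = h2,
                                level = 0.05, seed = seed,
                                model = "interaction", fixed_pos = fixed_pos)
  null_cl <- attr(thr_cl, "maxima")
  null_ia <- attr(thr_ia, "maxima")

  ci_of <- function(lrt_vec) {
    lod <- lrt_vec / (2 * log(10))
    keep <- which(lod >= max(lod) - 1)
    c(grid[min(keep)], grid[max(keep)])
  }
  overlap <- function(a, b) a[1L] <= b[2L] && b[1L] <= a[2L]

  per_gene <- purrr::map_dfr(seq_along(genes), function(g) {
    cl <- lrt_cl[, g]; ia <- lrt_ia[, g]
    i_cl <- which.max(cl); i_ia <- which.max(ia)
    ci_cl <- ci_of(cl); ci_ia <- ci_of(ia)
    tibble::tibble(
      gene_id = genes[g],
      distal_pos = grid[i_cl], distal_lrt = cl[i_cl],
      distal_p = mean(null_cl >= cl[i_cl]),
      distal_ci_low = ci_cl[1L], distal_ci_high = ci_cl[2L],
      proximal_pos = grid[i_ia], proximal_lrt = ia[i_ia],
      proximal_p = mean(null_ia >= ia[i_ia]),
      proximal_ci_low = ci_ia[1L], proximal_ci_high = ci_ia[2L],
      distal_colocalized = mean(null_cl >= cl[i_cl]) < alpha_distal &&
        overlap(ci_cl, trait_distal_ci),
      proximal_interacting = mean(null_ia >= ia[i_ia]) < alpha_interaction &&
        overlap(ci_ia, trait_proximal_ci)
    )
  })

  if (!is.null(proximal_max_cm)) {
    per_gene$proximal_interacting <- per_gene$proximal_interacting &
      per_gene$proximal_pos <= proximal_max_cm
  }

  has_leans <- !is.null(subtypes) &&
    all(c("lean1", "lean2") %in% subtypes$subtype)
  if (has_leans) {
    a1 <- subtypes$animal[subtypes$subtype == "lean1"]
    a2 <- subtypes$animal[subtypes$subtype == "lean2"]
    de_p <- apply(em, 1L, function(xg) {
      stats::t.test(xg[match(a1, colnames(em))],
                    xg[match(a2, colnames(em))],
                    var.equal = TRUE)$p.value
    })
    per_gene$lean_de_p <- unname(de_p)
    per_gene$lean_de <- per_gene$lean_de_p < alpha_de
  } else {
    warning("lean1/lean2 subtypes unavailable: ",
            "differential-expression filter skipped", call. = FALSE)
    per_gene$lean_de_p <- NA_real_
    per_gene$lean_de <- TRUE
  }
  per_gene$candidate <- per_gene$distal_colocalized &
    per_gene$proximal_interacting & per_gene$lean_de
  class(per_gene) <- c("candidate_screen", class(per_gene))
  per_gene
}
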