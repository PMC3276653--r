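#' Pre-adjust a trait for hatch, dam and body-weight effects
#'
#' Fits `trait ~ hatch + dam + body_weight` by least squares and returns the
#' re-centered residuals, the standard pre-correction applied to the fatness
#' trait before linkage analysis. Factor levels represented by a single
#' animal cannot be distinguished from their own residual; they are pooled
#' into a common level with a warning.
#'
#' @param pheno Phenotype tibble with columns `animal`, `trait`, `hatch`,
#'   `dam`, `body_weight` (see [simulate_phenotypes()]).
#' @return The input tibble with an extra `trait_adj` column.
#' @export
adjust_phenotype <- function(pheno) {
  stopifnot(all(c("animal", "trait", "hatch", "dam", "body_weight")
                %in% names(pheno)))
  dat <- pheno
  for (col in c("hatch", "dam")) {
    f <- droplevels(factor(dat[[col]]))
    singles <- names(which(table(f) < 2L))
    if (length(singles) > 0) {
      warning(sprintf("pooling %s level(s) with a single animal: %s",
                      col, paste(singles, collapse = ", ")), call. = FALSE)
      levels(f)[levels(f) %in% singles] <- "pooled"
    }
    if (nlevels(f) < 2L) {
      f <- factor(rep("all", nrow(dat)))
    }
    dat[[col]] <- f
  }
  fit <- stats::lm(trait ~ hatch + dam + body_weight, data = dat)
  res <- stats::residuals(fit)
  pheno$trait_adj <- as.numeric(res - mean(res))
  pheno
}

# ---- vectorized LRT engines ------------------------------------------------
#
# All scans use the Haley-Knott-style regression approximation: at position x
# the trait is regressed on the transmission coding w_i(x) = 2*pi_i(x) - 1
# and LRT(x) = n * log(RSS0 / RSS1). Y may hold many traits (columns); the
# engines return a positions x traits LRT matrix.

lrt_scan_null_vs_one <- function(W, Y) {
  n <- nrow(W)
  Wc <- sweep(W, 2, colMeans(W))
  Yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(Yc^2)
  if (any(rss0 <= 0)) stop("trait has zero variance", call. = FALSE)
  sxx <- colSums(Wc^2)
  sxy <- crossprod(Wc, Yc)                   # positions x traits
  expl <- sxy^2 / ifelse(sxx > 1e-12, sxx, Inf)
  lrt <- n * log(sweep(expl, 2, rss0, function(e, r) r / (r - e)))
  lrt[lrt < 0] <- 0
  lrt
}

# Nested scans conditional on a fixed locus, via Frisch-Waugh: residualize
# everything on the H0 design [1, w_fixed], then test the added columns
# (w_x, and optionally w_x * w_fixed) at every position x.
lrt_scan_fixed <- function(W, Y, w_fixed, interaction = TRUE) {
  n <- nrow(W)
  X0 <- cbind(1, w_fixed)
  q0 <- qr(X0)
  if (q0$rank < 2L) {
    # Degenerate conditioning: the fixed-locus coding is constant, so the
    # model collapses to the plain one-locus scan.
    return(lrt_scan_null_vs_one(W, Y))
  }
  Y0 <- qr.resid(q0, Y)
  rss0 <- colSums(Y0^2)
  if (any(rss0 <= 0)) stop("trait has zero variance under H0", call. = FALSE)
  P <- ncol(W)
  lrt <- matrix(0, P, ncol(Y))
  for (p in seq_len(P)) {
    Xa <- if (interaction) cbind(W[, p], W[, p] * w_fixed) else W[, p, drop = FALSE]
    Xa0 <- qr.resid(q0, Xa)
    qa <- qr(Xa0)
    if (qa$rank == 0L) next
    expl <- colSums(qr.fitted(qa, Y0)^2)
    lrt[p, ] <- n * log(rss0 / pmax(rss0 - expl, 1e-300))
  }
  lrt[lrt < 0] <- 0
  lrt
}

transmission_coding <- function(profile, animals = NULL) {
  W <- 2 * profile$pi - 1
  if (!is.null(animals)) {
    idx <- match(animals, profile$animals)
    if (anyNA(idx)) {
      stop("animals absent from the transmission profile: ",
           paste(animals[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    W <- W[idx, , drop = FALSE]
  }
  W
}

scan_engine <- function(W, Y, model, w_fixed = NULL) {
  switch(model,
         one_qtl = lrt_scan_null_vs_one(W, Y),
         interaction = lrt_scan_fixed(W, Y, w_fixed, interaction = TRUE),
         additive = lrt_scan_fixed(W, Y, w_fixed, interaction = FALSE),
         stop("unknown scan model: ", model, call. = FALSE))
}

new_qtl_scan <- function(grid, lrt, n, model, fixed_pos = NULL,
                         threshold = NA_real_, effect = NA_real_,
                         effect_sd = NA_real_, drop_lod = 1) {
  scan <- tibble::tibble(pos_cm = grid, lrt = as.numeric(lrt),
                         lod = as.numeric(lrt) / (2 * log(10)))
  imax <- which.max(scan$lrt)           # leftmost maximum on ties
  out <- structure(
    list(scan = scan, max_pos = grid[imax], max_lrt = scan$lrt[imax],
         threshold = threshold, ci = c(NA_real_, NA_real_),
         effect = effect, effect_sd = effect_sd, n = n, model = model,
         fixed_pos = fixed_pos),
    class = "qtl_scan"
  )
  out$ci <- lod_drop_ci(out, drop_lod = drop_lod)
  out
}

#' Interval-mapping scan of one chromosome
#'
#' At each grid position the (pre-adjusted) trait is regressed on the
#' expected-transmission coding `w_i(x) = 2 pi_i(x) - 1` and the approximate
#' likelihood-ratio statistic `LRT(x) = n log(RSS0 / RSS1)` is recorded
#' ("no QTL" vs "one QTL"). The reported substitution effect is the fitted
#' Q-vs-q difference `2 a_hat` at the maximum-LRT position, also expressed in
#' phenotypic SD of the scanned trait.
#'
#' @param trait Numeric trait vector, or a phenotype tibble carrying a
#'   `trait_adj` (preferred) or `trait` column aligned with
#'   `profile$animals`.
#' @param profile A [transmission_probabilities()] profile.
#' @param threshold Optional pre-computed chromosome-wide threshold (see
#'   [empirical_threshold()]); stored in the result.
#' @param drop_lod LOD drop used for the support interval (default 1).
#' @return A `qtl_scan` object; see [tidy.qtl_scan()], [glance.qtl_scan()],
#'   [autoplot.qtl_scan()].
#' @export
scan_chromosome <- function(trait, profile, threshold = NA_real_,
                            drop_lod = 1) {
  y <- extract_trait(trait, profile$animals)
  n <- length(y)
  if (n < 10L) {
    stop("at least 10 offspring with trait values are required", call. = FALSE)
  }
  W <- transmission_coding(profile)
  lrt <- lrt_scan_null_vs_one(W, cbind(y))[, 1L]
  imax <- which.max(lrt)
  w <- W[, imax]
  a_hat <- stats::coef(stats::lm(y ~ w))[["w"]]
  effect <- 2 * a_hat
  out <- new_qtl_scan(profile$grid, lrt, n, model = "one_qtl",
                      threshold = threshold, effect = effect,
                      effect_sd = effect / stats::sd(y), drop_lod = drop_lod)
  out
}

extract_trait <- function(trait, animals) {
  if (is.data.frame(trait)) {
    col <- if ("trait_adj" %in% names(trait)) "trait_adj" else "trait"
    idx <- match(animals, trait$animal)
    if (anyNA(idx)) {
      stop("phenotypes missing for animal(s): ",
           paste(animals[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    as.numeric(trait[[col]][idx])
  } else {
    if (length(trait) != length(animals)) {
      stop("trait length does not match the number of animals", call. = FALSE)
    }
    as.numeric(trait)
  }
}

#' Chromosome-wide empirical significance threshold
#'
#' Simulates traits under a polygenic-only model (no QTL) on the given family
#' structure, scans each simulated trait with the requested model, and returns
#' the `1 - level` quantile of the maximum LRT. Within a single half-sib
#' family the polygenic term decomposes into a family constant (absorbed by
#' the scan intercept) plus independent Mendelian-sampling deviations, so the
#' simulated traits are i.i.d. Gaussian with polygenic and residual variance
#' shares `h2` and `1 - h2`.
#'
#' @inheritParams scan_chromosome
#' @param n_sim Number of null simulations (default 2000).
#' @param h2 Polygenic heritability of the simulated null traits (default
#'   0.5). The LRT is scale-free, so `h2` only documents the generating model.
#' @param level Chromosome-wide type-I error (default 0.05).
#' @param seed Integer seed.
#' @param model `"one_qtl"`, `"interaction"` or `"additive"`; the latter two
#'   condition on `fixed_pos`.
#' @param fixed_pos Conditioning position in cM for the two-locus models.
#' @param animals Optional subset of animals (for reduced-family scans).
#' @return The threshold, with the simulated maxima in attribute `maxima`.
#' @export
empirical_threshold <- function(profile, n_sim = 2000, h2 = 0.5,
                                level = 0.05, seed = 1L,
                                model = "one_qtl", fixed_pos = NULL,
                                animals = NULL) {
  if (n_sim < 100L) stop("n_sim must be >= 100", call. = FALSE)
  if (level <= 0 || level > 1) stop("level must be in (0, 1]", call. = FALSE)
  W <- transmission_coding(profile, animals)
  n <- nrow(W)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * n_sim, 0, sqrt(h2)) +
                stats::rnorm(n * n_sim, 0, sqrt(1 - h2)), n, n_sim)
  w_fixed <- fixed_coding(profile, fixed_pos, animals)
  lrt <- scan_engine(W, Y, model, w_fixed)
  maxima <- apply(lrt, 2L, max)
  thr <- as.numeric(stats::quantile(maxima, 1 - level, type = 7))
  attr(thr, "maxima") <- maxima
  thr
}

fixed_coding <- function(profile, fixed_pos, animals = NULL) {
  if (is.null(fixed_pos)) return(NULL)
  idx <- which.min(abs(profile$grid - fixed_pos))
  spacing <- max(diff(profile$grid), 0)
  if (abs(profile$grid[idx] - fixed_pos) > spacing / 2 + 1e-9) {
    stop("fixed_pos lies outside the scanned grid", call. = FALSE)
  }
  transmission_coding(profile, animals)[, idx]
}

#' One-LOD-drop support interval
#'
#' Converts the LRT curve to LOD (`LOD = LRT / (2 ln 10)`) and returns the
#' outermost grid positions whose LOD is within `drop_lod` of the maximum,
#' clamped to the scanned range. A flat scan yields the full range with a
#' warning.
#'
#' @param scan A `qtl_scan`.
#' @param drop_lod LOD units to drop (default 1).
#' @return Numeric `c(low_cm, high_cm)`.
#' @export
lod_drop_ci <- function(scan, drop_lod = 1) {
  stopifnot(inherits(scan, "qtl_scan"), drop_lod >= 0)
  lod <- scan$scan$lod
  pos <- scan$scan$pos_cm
  if (max(lod) - min(lod) < 1e-12) {
    warning("flat LRT curve: support interval spans the whole scanned range",
            call. = FALSE)
    return(c(pos[1L], pos[length(pos)]))
  }
  keep <- which(lod >= max(lod) - drop_lod)
  c(pos[min(keep)], pos[max(keep)])
}

#' Leave-one-subtype-out linkage scans
#'
#' Runs the full-family scan plus one scan per omitted subtype, each with its
#' own empirical threshold recomputed on the reduced family.
#'
#' @inheritParams scan_chromosome
#' @inheritParams empirical_threshold
#' @param subtypes Tibble with columns `animal` and `subtype` covering every
#'   profiled animal.
#' @param pheno Phenotype tibble (with `trait_adj` or `trait`) or a trait
#'   vector aligned with `profile$animals`.
#' @return A named list of `qtl_scan` objects (class `subtype_scans`): `full`
#'   first, then `drop_<subtype>` in subtype order.
#' @export
leave_one_subtype_out_scans <- function(pheno, profile, subtypes,
                                        n_sim = 2000, h2 = 0.5,
                                        level = 0.05, seed = 1L) {
  stopifnot(all(c("animal", "subtype") %in% names(subtypes)))
  missing <- setdiff(profile$animals, subtypes$animal)
  if (length(missing) > 0) {
    stop("animals without a subtype: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y_all <- extract_trait(pheno, profile$animals)
  labels <- subtypes$subtype[match(profile$animals, subtypes$animal)]
  # factor levels are honored even when empty: omitting an empty subtype
  # reproduces the full-family scan
  groups <- if (is.factor(labels)) levels(labels) else unique(labels)
  out <- list()
  thr <- empirical_threshold(profile, n_sim = n_sim, h2 = h2, level = level,
                             seed = seed)
  out$full <- scan_chromosome(y_all, profile, threshold = thr)
  for (g in groups) {
    keep <- profile$animals[
      subtypes$subtype[match(profile$animals, subtypes$animal)] != g]
    if (length(keep) < length(profile$animals) / 2) {
      warning(sprintf("omitted subtype '%s' is larger than half the family", g),
              call. = FALSE)
    }
    sub_profile <- subset_profile(profile, keep)
    thr_g <- empirical_threshold(sub_profile, n_sim = n_sim, h2 = h2,
                                 level = level, seed = seed + 1L)
    out[[paste0("drop_", g)]] <-
      scan_chromosome(extract_trait(pheno, keep), sub_profile,
                      threshold = thr_g)
  }
  structure(out, class = "subtype_scans")
}

subset_profile <- function(profile, animals) {
  idx <- match(animals, profile$animals)
  structure(
    list(grid = profile$grid, pi = profile$pi[idx, , drop = FALSE],
         animals = animals, map = profile$map,
         flagged = profile$flagged[profile$flagged$animal %in% animals, ,
                                   drop = FALSE],
         sire_phase = profile$sire_phase),
    class = "transmission_profile"
  )
}

# ---- methods ---------------------------------------------------------------

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("<qtl_scan: %s%s>\n", x$model,
              if (!is.null(x$fixed_pos))
                sprintf(" | fixed at %g cM", x$fixed_pos) else ""))
  cat(sprintf("  n = %d; max LRT %.2f at %g cM; threshold %s\n",
              x$n, x$max_lrt, x$max_pos,
              if (is.na(x$threshold)) "not set" else sprintf("%.2f", x$threshold)))
  cat(sprintf("  one-LOD support interval: %g-%g cM\n", x$ci[1L], x$ci[2L]))
  if (!is.na(x$effect)) {
    cat(sprintf("  Q-q substitution effect: %.3f (%.2f SD)\n",
                x$effect, x$effect_sd))
  }
  invisible(x)
}

#' Tidy and summarize interval-mapping scans
#'
#' `tidy()` returns the per-position LRT/LOD curve; `glance()` returns a
#' one-row summary (maximum, threshold, support interval, effect).
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @export
tidy.qtl_scan <- function(x, ...) x$scan

#' @rdname tidy.qtl_scan
#' @export
glance.qtl_scan <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n = x$n,
    max_pos = x$max_pos,
    max_lrt = x$max_lrt,
    threshold = x$threshold,
    significant = if (is.na(x$threshold)) NA else x$max_lrt > x$threshold,
    ci_low = x$ci[1L],
    ci_high = x$ci[2L],
    effect = x$effect,
    effect_sd = x$effect_sd,
    fixed_pos = if (is.null(x$fixed_pos)) NA_real_ else x$fixed_pos
  )
}

#' @export
autoplot.qtl_scan <- function(object, ...) {
  df <- object$scan
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cm, y = .data$lrt)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::annotate("rect", xmin = object$ci[1L], xmax = object$ci[2L],
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$max_pos, linetype = 3) +
    ggplot2::labs(x = "position (cM)", y = "LRT") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = 2, colour = "firebrick")
  }
  p
}

#' @export
tidy.subtype_scans <- function(x, ...) {
  purrr::map_dfr(x, tidy.qtl_scan, .id = "scan")
}

#' @export
glance.subtype_scans <- function(x, ...) {
  purrr::map_dfr(x, glance.qtl_scan, .id = "scan")
}

#' @export
autoplot.subtype_scans <- function(object, ...) {
  df <- tidy.subtype_scans(object)
  thr <- glance.subtype_scans(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cm, y = .data$lrt,
                                   colour = .data$scan)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold,
                                     colour = .data$scan),
                        linetype = 2, alpha = 0.6) +
    ggplot2::labs(x = "position (cM)", y = "LRT", colour = NULL) +
    ggplot2::theme_minimal()
}
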