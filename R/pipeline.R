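#' Pipeline configuration
#'
#' Collects the stage parameters of [run_pipeline()] into a validated list.
#' Unknown keys are rejected, and every random stage draws its seed from the
#' single `seed` field so a report is reproducible from its configuration
#' alone.
#'
#' @param sim A [sim_config()] describing the synthetic study, or `NULL` if
#'   `data` is supplied to [run_pipeline()].
#' @param alpha Nominal cutoff of the association lists (default 0.05).
#' @param q Number of hidden factors; `NULL` estimates it with
#'   [estimate_n_factors()].
#' @param q_max Search bound when `q` is estimated (default 8).
#' @param k Number of subtypes to cut (default 5).
#' @param extreme_k Animals per extreme group in the differential-expression
#'   test (default 10).
#' @param n_sim Null simulations per empirical threshold (default 2000).
#' @param h2 Heritability of the polygenic null simulations (default 0.5).
#' @param level Chromosome-wide significance level (default 0.05).
#' @param grid_step Scan grid step in cM (default 1).
#' @param proximal_region,distal_region `c(center, halfwidth)` in cM of the
#'   two haplotype-calling regions (defaults `c(100, 20)` and `c(168, 15)`).
#' @param call_threshold Posterior probability for a determined haplotype
#'   call (default 0.99).
#' @param fixed_pos Conditioning position of the interaction model; `NULL`
#'   (default) uses the full-family maximum-LRT position.
#' @param alpha_interaction,alpha_de Candidate-filter cutoffs (default 0.1).
#' @param stages Character vector of stages to run, a subset of the default
#'   order.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            alpha = 0.05, q = NULL, q_max = 8, k = 5,
                            extreme_k = 10, n_sim = 2000, h2 = 0.5,
                            level = 0.05, grid_step = 1,
                            proximal_region = c(100, 20),
                            distal_region = c(168, 15),
                            call_threshold = 0.99, fixed_pos = NULL,
                            alpha_interaction = 0.1, alpha_de = 0.1,
                            stages = c("associate", "famt", "cluster",
                                       "scan", "haplotypes", "interaction",
                                       "candidates"),
                            seed = 1L) {
  known <- c("associate", "famt", "cluster", "scan", "haplotypes",
             "interaction", "candidates")
  unknown <- setdiff(stages, known)
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(sim = sim, alpha = alpha, q = q, q_max = q_max, k = k,
         extreme_k = extreme_k, n_sim = n_sim, h2 = h2, level = level,
         grid_step = grid_step, proximal_region = proximal_region,
         distal_region = distal_region, call_threshold = call_threshold,
         fixed_pos = fixed_pos, alpha_interaction = alpha_interaction,
         alpha_de = alpha_de, stages = stages, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full subtype-and-interacting-QTL pipeline
#'
#' Executes the stages in study order — association screens, factor-model
#' fitting and factor-adjusted tests, subtype clustering, full-family and
#' leave-one-subtype-out linkage scans, haplotype calling at the two QTL
#' regions, the two-way ANOVA and fixed-locus interaction scans, and the
#' candidate-gene filter — on either a simulated study (from `config$sim`)
#' or user-supplied `data`. Each stage's outputs land in the returned report
#' together with every seed, count, position, support interval and p-value;
#' stages not requested are marked `"skipped"`.
#'
#' @param config A [pipeline_config()].
#' @param data Optional list with elements `map`, `inherit`, `pheno`, `expr`
#'   (as returned by the readers); when `NULL` the study is simulated.
#' @return A list of class `pipeline_report`; `report$summary` holds the
#'   flat, JSON-ready numbers.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, stages = list())
  run <- function(stage) stage %in% config$stages

  if (is.null(data)) {
    simcfg <- config$sim
    simcfg$seed <- config$seed
    sim <- simulate_family(validate_sim_config(simcfg))
    data <- sim[c("map", "inherit", "pheno", "expr")]
    report$simulated <- TRUE
  } else {
    sim <- NULL
    report$simulated <- FALSE
  }
  check_animal_consistency(pheno = data$pheno, inherit = data$inherit)

  pheno <- adjust_phenotype(data$pheno)
  expr <- data$expr
  animals <- names(expr)[-1L]
  y_adj <- extract_trait(pheno, animals)

  if (run("associate")) {
    corr <- correlation_test(expr, y_adj)
    tt <- extreme_group_ttest(expr, y_adj, k = config$extreme_k)
    lists <- classical_gene_lists(corr, tt, alpha = config$alpha)
    report$stages$associate <- list(
      n_corr_list = sum(lists$in_corr_list),
      n_union_list = sum(lists$in_union_list),
      results = lists
    )
  } else {
    report$stages$associate <- "skipped"
  }

  if (run("famt")) {
    q <- config$q
    if (is.null(q)) q <- as.integer(estimate_n_factors(expr, y_adj,
                                                       q_max = config$q_max))
    fit <- famt_fit(expr, y_adj, q = q)
    fa_stats <- factor_adjusted_tests(fit)
    famt_genes <- fa_stats$gene_id[!is.na(fa_stats$p_corr) &
                                     fa_stats$p_corr < config$alpha]
    report$stages$famt <- list(
      q = q, n_famt_list = length(famt_genes),
      genes = famt_genes, fit = fit, stats = fa_stats
    )
  } else {
    report$stages$famt <- "skipped"
  }

  tert <- trait_tertiles(dplyr::mutate(data$pheno, trait = y_adj))
  if (run("cluster")) {
    if (identical(report$stages$famt, "skipped")) {
      stop("stage 'cluster' requires stage 'famt'", call. = FALSE)
    }
    genes <- report$stages$famt$genes
    if (length(genes) < 2) {
      stop("too few trait-associated genes to cluster on", call. = FALSE)
    }
    adj_expr <- adjusted_expression(report$stages$famt$fit)
    cl <- cluster_animals(adj_expr, genes, k = config$k)
    subtypes <- label_subtypes(cl, tert)
    report$stages$cluster <- list(
      k = config$k,
      sizes = table(subtypes$subtype),
      subtypes = subtypes,
      assignment = cl
    )
  } else {
    report$stages$cluster <- "skipped"
  }

  profile <- transmission_probabilities(data$inherit, data$map,
                                        step = config$grid_step)
  if (run("scan")) {
    if (identical(report$stages$cluster, "skipped")) {
      thr <- empirical_threshold(profile, n_sim = config$n_sim,
                                 h2 = config$h2, level = config$level,
                                 seed = config$seed)
      scans <- structure(list(full = scan_chromosome(pheno, profile,
                                                     threshold = thr)),
                         class = "subtype_scans")
    } else {
      scans <- leave_one_subtype_out_scans(
        pheno, profile, report$stages$cluster$subtypes,
        n_sim = config$n_sim, h2 = config$h2, level = config$level,
        seed = config$seed)
    }
    report$stages$scan <- list(glance = glance.subtype_scans(scans),
                               scans = scans)
  } else {
    report$stages$scan <- "skipped"
  }

  if (run("haplotypes")) {
    calls_p <- call_haplotype(data$inherit, data$map,
                              region_center = config$proximal_region[1L],
                              region_halfwidth = config$proximal_region[2L],
                              threshold = config$call_threshold)
    calls_d <- call_haplotype(data$inherit, data$map,
                              region_center = config$distal_region[1L],
                              region_halfwidth = config$distal_region[2L],
                              threshold = config$call_threshold)
    subt <- if (!identical(report$stages$cluster, "skipped")) {
      report$stages$cluster$subtypes
    } else {
      NULL
    }
    htab <- haplotype_table(calls_p, calls_d, subt)
    report$stages$haplotypes <- list(counts = glance.haplotype_table(htab),
                                     table = htab)
  } else {
    report$stages$haplotypes <- "skipped"
  }

  if (run("interaction")) {
    if (identical(report$stages$haplotypes, "skipped") ||
        identical(report$stages$scan, "skipped")) {
      stop("stage 'interaction' requires stages 'scan' and 'haplotypes'",
           call. = FALSE)
    }
    fixed_pos <- config$fixed_pos
    if (is.null(fixed_pos)) {
      fixed_pos <- report$stages$scan$scans$full$max_pos
    }
    anova <- tryCatch(
      two_way_anova_interaction(pheno, report$stages$haplotypes$table),
      error = function(e) e
    )
    ia <- interaction_scan(pheno, profile, fixed_pos, n_sim = config$n_sim,
                           h2 = config$h2, level = config$level,
                           seed = config$seed + 2L)
    add <- two_qtl_additive_scan(pheno, profile, fixed_pos,
                                 n_sim = config$n_sim, h2 = config$h2,
                                 level = config$level,
                                 seed = config$seed + 3L)
    report$stages$interaction <- list(
      fixed_pos = fixed_pos,
      anova = anova,
      interaction_scan = ia,
      additive_scan = add
    )
  } else {
    report$stages$interaction <- "skipped"
  }

  if (run("candidates")) {
    if (identical(report$stages$interaction, "skipped")) {
      stop("stage 'candidates' requires stage 'interaction'", call. = FALSE)
    }
    ia <- report$stages$interaction$interaction_scan
    full <- report$stages$scan$scans$full
    subt <- if (!identical(report$stages$cluster, "skipped")) {
      report$stages$cluster$subtypes
    } else {
      NULL
    }
    # The trait's proximal support interval comes from the interaction scan
    # restricted to the proximal side of the conditioning locus.
    ia_curve <- ia$scan
    win <- ia_curve$pos_cm < report$stages$interaction$fixed_pos
    lod_w <- ia_curve$lod[win]
    keep_w <- which(lod_w >= max(lod_w) - 1)
    prox_ci <- range(ia_curve$pos_cm[win][keep_w])
    # Downstream candidate screening works on the factor-adjusted expression
    # of the trait-associated gene list (the dependence kernel subtracted).
    screen_expr <- if (!identical(report$stages$famt, "skipped") &&
                         length(report$stages$famt$genes) > 0) {
      adj <- adjusted_expression(report$stages$famt$fit)
      adj[adj$gene_id %in% report$stages$famt$genes, , drop = FALSE]
    } else {
      expr
    }
    screen <- eqtl_candidate_filter(
      screen_expr, profile, fixed_pos = report$stages$interaction$fixed_pos,
      trait_distal_ci = full$ci, trait_proximal_ci = prox_ci,
      subtypes = subt, alpha_interaction = config$alpha_interaction,
      alpha_de = config$alpha_de,
      n_sim = max(200L, config$n_sim %/% 4L),
      h2 = config$h2, seed = config$seed + 4L)
    report$stages$candidates <- list(
      n_candidates = sum(screen$candidate),
      candidate_genes = screen$gene_id[screen$candidate],
      screen = screen
    )
  } else {
    report$stages$candidates <- "skipped"
  }

  if (!is.null(sim)) report$truth <- sim$truth
  report$summary <- pipeline_summary(report)
  class(report) <- "pipeline_report"
  report
}

pipeline_summary <- function(report) {
  s <- list(seed = report$seed)
  st <- report$stages
  if (!identical(st$associate, "skipped")) {
    s$n_corr_list <- st$associate$n_corr_list
    s$n_union_list <- st$associate$n_union_list
  }
  if (!identical(st$famt, "skipped")) {
    s$q <- st$famt$q
    s$n_famt_list <- st$famt$n_famt_list
  }
  if (!identical(st$cluster, "skipped")) {
    s$subtype_sizes <- as.list(st$cluster$sizes)
  }
  if (!identical(st$scan, "skipped")) {
    g <- st$scan$glance
    s$scans <- purrr::transpose(as.list(g))
    names(s$scans) <- g$scan
  }
  if (!identical(st$haplotypes, "skipped")) {
    s$haplotype_counts <- as.list(st$haplotypes$counts)
  }
  if (!identical(st$interaction, "skipped")) {
    s$fixed_pos <- st$interaction$fixed_pos
    if (!inherits(st$interaction$anova, "error")) {
      s$anova <- as.list(glance.qtl_anova(st$interaction$anova))
    }
    s$interaction_scan <- as.list(glance.qtl_scan(st$interaction$interaction_scan))
    s$additive_scan <- as.list(glance.qtl_scan(st$interaction$additive_scan))
  }
  if (!identical(st$candidates, "skipped")) {
    s$n_candidates <- st$candidates$n_candidates
    s$candidate_genes <- st$candidates$candidate_genes
  }
  s
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$stages)) {
    if (identical(x$stages[[nm]], "skipped")) {
      cat(sprintf("  %-12s skipped\n", nm))
    } else {
      cat(sprintf("  %-12s done\n", nm))
    }
  }
  invisible(x)
}
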