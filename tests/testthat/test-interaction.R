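mk_hap_table <- function(prox, dist, animals = sprintf("A%02d", seq_along(prox))) {
  haplotype_table(tibble::tibble(animal = animals, call = prox),
                  tibble::tibble(animal = animals, call = dist))
}

test_that("two-way ANOVA matches the from-scratch Type-II oracle and a permutation test", {
  set.seed(5)
  n <- 40
  prox <- rep(c("q", "Q"), each = n / 2)
  dist <- rep(c("q", "Q"), times = n / 2)
  # unbalanced-ish noise, cell means (0, 0, 0, 10)
  y <- rnorm(n, 0, 1) + ifelse(prox == "Q" & dist == "Q", 10, 0)
  tab <- mk_hap_table(prox, dist)
  res <- two_way_anova_interaction(y, tab)
  oracle <- anova2_typeII_oracle(y, factor(prox, levels = c("q", "Q")),
                                 factor(dist, levels = c("q", "Q")))
  expect_equal(res$anova$statistic[1:3], oracle$F, tolerance = 1e-10)
  expect_equal(res$anova$p.value[1:3], oracle$p, tolerance = 1e-10)
  expect_equal(res$conditional_diff[["given_distal_Q"]],
               mean(y[prox == "Q" & dist == "Q"]) -
                 mean(y[prox == "q" & dist == "Q"]))

  # permutation oracle for the interaction: permute proximal labels within
  # distal strata
  f_obs <- res$anova$statistic[res$anova$term == "proximal:distal"]
  set.seed(6)
  f_null <- replicate(2000, {
    p2 <- prox
    for (d in c("q", "Q")) p2[dist == d] <- sample(prox[dist == d])
    fit <- stats::lm(y ~ factor(p2) * factor(dist))
    a <- stats::anova(fit)
    a[["F value"]][3]
  })
  p_perm <- mean(f_null >= f_obs)
  p_param <- res$anova$p.value[res$anova$term == "proximal:distal"]
  expect_lt(abs(p_perm - p_param), 3 * sqrt(0.05 / 2000) + 0.02)
})

test_that("equal cell means give null F statistics and empty cells are rejected", {
  n <- 32
  prox <- rep(c("q", "Q"), each = n / 2)
  dist <- rep(c("q", "Q"), times = n / 2)
  # every cell holds the same values, so all four cell means are equal and
  # the factor sums of squares vanish exactly
  y <- numeric(n)
  for (p in c("q", "Q")) for (d in c("q", "Q")) {
    idx <- which(prox == p & dist == d)
    y[idx] <- rep(c(-1, 1), length.out = length(idx)) + 5
  }
  res <- two_way_anova_interaction(y, mk_hap_table(prox, dist))
  expect_lt(max(abs(res$anova$statistic[1:3])), 1e-9)
  expect_gt(min(res$anova$p.value[1:3]), 1 - 1e-9)
  y2 <- stats::rnorm(n)
  expect_silent(two_way_anova_interaction(y2, mk_hap_table(prox, dist)))
  prox_bad <- rep("Q", n)
  expect_error(two_way_anova_interaction(y2, mk_hap_table(prox_bad, dist)),
               "empty")
  # x calls are excluded before fitting
  prox_x <- prox; prox_x[1:4] <- "x"
  res_x <- two_way_anova_interaction(y2, mk_hap_table(prox_x, dist))
  expect_equal(res_x$n_used, n - 4)
})

test_that("interaction LRT dominates the additive LRT and collapses under degenerate conditioning", {
  sim <- simulate_family(sim_config(n_genes = 10, n_trait_genes = 1,
                                    n_interacting_eqtl_genes = 1, seed = 71))
  prof <- transmission_probabilities(sim$inherit, sim$map, step = 1)
  ph <- adjust_phenotype(sim$pheno)
  ia <- interaction_scan(ph, prof, fixed_pos = 168, n_sim = 0)
  ad <- two_qtl_additive_scan(ph, prof, fixed_pos = 168, n_sim = 0)
  expect_true(all(ia$scan$lrt >= ad$scan$lrt - 1e-9))
  # affine trait transform leaves both scans unchanged
  ia2 <- interaction_scan(tibble::tibble(animal = ph$animal,
                                         trait = -2 * ph$trait_adj + 3),
                          prof, fixed_pos = 168, n_sim = 0)
  expect_equal(ia$scan$lrt, ia2$scan$lrt, tolerance = 1e-9)
  # constant fixed coding collapses to the plain one-locus scan
  prof0 <- prof
  prof0$pi[, which.min(abs(prof0$grid - 168))] <- 1
  ia0 <- interaction_scan(ph, prof0, fixed_pos = 168, n_sim = 0)
  plain <- scan_chromosome(ph, prof0)
  expect_equal(ia0$scan$lrt, plain$scan$lrt, tolerance = 1e-9)
  prof_na <- prof
  prof_na$pi[, which.min(abs(prof_na$grid - 168))] <- 0.5
  expect_error(interaction_scan(ph, prof_na, fixed_pos = 168, n_sim = 0),
               "uninformative")
})

test_that("null calibration holds for both two-locus scans", {
  sim <- simulate_family(sim_config(n_genes = 10, n_trait_genes = 1,
                                    n_interacting_eqtl_genes = 1,
                                    effect_distal = 0,
                                    effect_proximal_given_distal_Q = 0,
                                    effect_proximal_given_distal_q = 0,
                                    seed = 73))
  prof <- transmission_probabilities(sim$inherit, sim$map, step = 1)
  thr_ia <- empirical_threshold(prof, n_sim = 600, seed = 1,
                                model = "interaction", fixed_pos = 168)
  thr_ad <- empirical_threshold(prof, n_sim = 600, seed = 1,
                                model = "additive", fixed_pos = 168)
  # fresh null traits on the same family
  set.seed(2)
  W <- 2 * prof$pi - 1
  wf <- W[, which.min(abs(prof$grid - 168))]
  Y <- matrix(rnorm(nrow(W) * 500), nrow(W))
  rej_ia <- mean(apply(subtypeqtl:::lrt_scan_fixed(W, Y, wf, TRUE), 2, max) >
                   as.numeric(thr_ia))
  rej_ad <- mean(apply(subtypeqtl:::lrt_scan_fixed(W, Y, wf, FALSE), 2, max) >
                   as.numeric(thr_ad))
  expect_lt(abs(rej_ia - 0.05), 0.025)
  expect_lt(abs(rej_ad - 0.05), 0.025)
})

test_that("purely interactive effects are seen by the interaction scan, additive effects by both", {
  # paired power comparison on the package's generator
  pow <- matrix(0, 2, 2,
                dimnames = list(c("interactive", "additive_truth"),
                                c("ia_scan", "ad_scan")))
  reps <- 30
  for (r in seq_len(reps)) {
    # purely interactive truth: opposite conditional effects, no marginal one
    sim1 <- simulate_family(sim_config(
      n_genes = 5, n_trait_genes = 1, n_interacting_eqtl_genes = 1,
      effect_distal = 1,
      effect_proximal_given_distal_Q = 1.4,
      effect_proximal_given_distal_q = -1.4, seed = 900 + r))
    # purely additive two-QTL truth
    sim2 <- simulate_family(sim_config(
      n_genes = 5, n_trait_genes = 1, n_interacting_eqtl_genes = 1,
      effect_distal = 1,
      effect_proximal_given_distal_Q = 1.4,
      effect_proximal_given_distal_q = 1.4, seed = 950 + r))
    for (case in 1:2) {
      sim <- if (case == 1) sim1 else sim2
      prof <- transmission_probabilities(sim$inherit, sim$map, step = 1)
      ph <- adjust_phenotype(sim$pheno)
      ia <- interaction_scan(ph, prof, fixed_pos = 168, n_sim = 200,
                             seed = r)
      ad <- two_qtl_additive_scan(ph, prof, fixed_pos = 168, n_sim = 200,
                                  seed = r)
      pow[case, 1] <- pow[case, 1] + (ia$max_lrt > ia$threshold) / reps
      pow[case, 2] <- pow[case, 2] + (ad$max_lrt > ad$threshold) / reps
    }
  }
  # interactive truth: interaction scan far above level, additive near level
  expect_gt(pow["interactive", "ia_scan"], 0.4)
  expect_lt(pow["interactive", "ad_scan"], 0.25)
  # additive truth: additive scan at least as powerful as interaction scan
  expect_gte(pow["additive_truth", "ad_scan"] + 0.1,
             pow["additive_truth", "ia_scan"])
})

test_that("the candidate screen returns the engineered two-locus genes and nothing else", {
  # a well-powered family so each filter component has clear margins
  screen_rep <- function(s) {
    sim <- simulate_family(sim_config(
      n_offspring = 90, n_genes = 800, n_trait_genes = 50,
      n_interacting_eqtl_genes = 4, dense_proximal_markers = TRUE,
      eqtl_effect_distal = 3, eqtl_effect_proximal_given_distal_Q = 3,
      seed = 7000 + s))
    prof <- transmission_probabilities(sim$inherit, sim$map, step = 1)
    ph <- suppressWarnings(adjust_phenotype(sim$pheno))
    fit <- famt_fit(sim$expr, ph$trait_adj, q = 6)
    st <- factor_adjusted_tests(fit)
    genes <- st$gene_id[!is.na(st$p_corr) & st$p_corr < 0.05]
    truth <- sim$truth$interacting_gene_ids
    adj <- adjusted_expression(fit)
    tert <- trait_tertiles(dplyr::mutate(sim$pheno, trait = ph$trait_adj))
    s_d <- sim$truth$origin_qtl[, "distal"]
    subt <- tibble::tibble(
      animal = tert$animal,
      subtype = dplyr::case_when(
        tert$status == "L" & s_d == 1L ~ "lean1",
        tert$status == "L" & s_d == 2L ~ "lean2",
        TRUE ~ "other"))
    ia <- interaction_scan(ph, prof, 168, n_sim = 300, seed = s + 1)
    full <- scan_chromosome(ph, prof)
    win <- ia$scan$pos_cm < 168
    lodw <- ia$scan$lod[win]
    prox_ci <- range(ia$scan$pos_cm[win][lodw >= max(lodw) - 1])
    scr <- eqtl_candidate_filter(
      adj[adj$gene_id %in% union(genes, truth), ], prof, fixed_pos = 168,
      trait_distal_ci = full$ci, trait_proximal_ci = prox_ci,
      subtypes = subt, n_sim = 300, seed = s + 2)
    expect_true(all(scr$proximal_p >= 0 & scr$proximal_p <= 1))
    expect_true(all(scr$distal_ci_low <= scr$distal_ci_high))
    cand <- scr$gene_id[scr$candidate]
    c(hits = sum(cand %in% truth), fp = sum(!cand %in% truth),
      exact = setequal(cand, truth))
  }
  res <- sapply(1:5, screen_rep)
  expect_equal(sum(res["fp", ]), 0)            # no gene outside the truth set
  expect_gte(mean(res["hits", ]), 3.5 - 1e-9)  # near-complete recall
  expect_gte(sum(res["exact", ]), 3)           # usually exactly the four
})

test_that("the candidate screen warns and skips the DE filter without lean subtypes", {
  sim <- simulate_family(sim_config(n_genes = 40, n_trait_genes = 4,
                                    n_interacting_eqtl_genes = 2, seed = 81))
  prof <- transmission_probabilities(sim$inherit, sim$map, step = 1)
  expect_warning(
    screen <- eqtl_candidate_filter(
      sim$expr, prof, fixed_pos = 168,
      trait_distal_ci = c(150, 190), trait_proximal_ci = c(80, 110),
      subtypes = NULL, n_sim = 200, seed = 3),
    "skipped")
  expect_equal(nrow(screen), 40)
  expect_true(all(is.na(screen$lean_de_p)))
})
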