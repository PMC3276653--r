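sim_scan_setup <- function(seed, ...) {
  sim <- simulate_family(sim_config(n_genes = 10, n_trait_genes = 2,
                                    n_interacting_eqtl_genes = 1,
                                    seed = seed, ...))
  prof <- transmission_probabilities(sim$inherit, sim$map, step = 1)
  list(sim = sim, prof = prof, pheno = adjust_phenotype(sim$pheno))
}

test_that("phenotype adjustment removes injected covariate effects", {
  s <- sim_scan_setup(seed = 17, n_offspring = 200, hatch_sd = 0,
                      dam_sd = 0, body_weight_effect = 0)
  ph0 <- adjust_phenotype(s$sim$pheno)
  # no injected effects: adjustment is near-identity up to centering
  expect_gt(cor(ph0$trait_adj, s$sim$pheno$trait - mean(s$sim$pheno$trait)),
            0.96)

  cfg <- sim_config(n_offspring = 200, n_genes = 10, n_trait_genes = 1,
                    n_interacting_eqtl_genes = 1, hatch_sd = 2,
                    seed = 18)
  sim <- simulate_family(cfg)
  ph <- adjust_phenotype(sim$pheno)
  raw_spread <- diff(range(tapply(sim$pheno$trait, sim$pheno$hatch, mean)))
  adj_spread <- diff(range(tapply(ph$trait_adj, ph$hatch, mean)))
  expect_gt(raw_spread, 1)          # the injected hatch shifts are visible
  expect_lt(adj_spread, 1e-8)       # and fully removed by adjustment
  # residuals orthogonal to the design columns
  expect_lt(abs(sum(ph$trait_adj * sim$pheno$body_weight)), 1e-6)
})

test_that("singleton covariate levels are pooled with a warning", {
  pheno <- tibble::tibble(
    animal = sprintf("A%d", 1:12),
    trait = rnorm(12),
    hatch = factor(c(rep("h1", 11), "h2")),
    dam = factor(rep(c("d1", "d2"), 6)),
    body_weight = rnorm(12)
  )
  expect_warning(adjust_phenotype(pheno), "pooling")
})

test_that("the LRT scan is invariant to affine trait transforms", {
  s <- sim_scan_setup(seed = 23)
  sc1 <- scan_chromosome(s$pheno$trait_adj, s$prof)
  sc2 <- scan_chromosome(3.7 * s$pheno$trait_adj - 11, s$prof)
  expect_equal(sc1$scan$lrt, sc2$scan$lrt, tolerance = 1e-9)
  expect_equal(sc1$max_pos, sc2$max_pos)
  expect_equal(sc1$effect_sd, sc2$effect_sd, tolerance = 1e-9)
  expect_true(all(sc1$scan$lrt >= 0))
  expect_equal(sc1$max_lrt, max(sc1$scan$lrt))
  expect_error(scan_chromosome(rep(2, 45), s$prof), "variance")
})

test_that("the one-LOD support interval inverts an exact quadratic curve", {
  grid <- seq(0, 200, by = 0.1)
  lrt <- pmax(40 - (grid - 100)^2 / 10, 0)
  sc <- subtypeqtl:::new_qtl_scan(grid, lrt, n = 45, model = "one_qtl")
  expect_equal(sc$ci[1], 100 - sqrt(10 * 2 * log(10)), tolerance = 0.1)
  expect_equal(sc$ci[2], 100 + sqrt(10 * 2 * log(10)), tolerance = 0.1)
  expect_equal(sc$ci, c(93.2, 106.8), tolerance = 0.01)
  # single-point spike: the interval is that grid cell
  spike <- rep(0, length(grid)); spike[500] <- 30
  sc2 <- subtypeqtl:::new_qtl_scan(grid, spike, n = 45, model = "one_qtl")
  expect_equal(sc2$ci, rep(grid[500], 2))
  # widening the drop never shrinks the interval
  ci1 <- lod_drop_ci(sc, drop_lod = 1)
  ci2 <- lod_drop_ci(sc, drop_lod = 2)
  expect_lte(ci2[1], ci1[1])
  expect_gte(ci2[2], ci1[2])
  # flat curve: full range, flagged
  flat <- subtypeqtl:::new_qtl_scan(grid, rep(0, length(grid)), n = 45,
                                    model = "one_qtl")
  expect_warning(ci <- lod_drop_ci(flat), "flat")
  expect_equal(ci, range(grid))
})

test_that("empirical thresholds behave like quantiles of the null maximum", {
  s <- sim_scan_setup(seed = 29)
  thr <- empirical_threshold(s$prof, n_sim = 400, level = 0.05, seed = 1)
  maxima <- attr(thr, "maxima")
  expect_equal(length(maxima), 400)
  expect_equal(as.numeric(empirical_threshold(s$prof, n_sim = 400,
                                              level = 1, seed = 1)),
               min(maxima))
  thr10 <- empirical_threshold(s$prof, n_sim = 400, level = 0.10, seed = 1)
  expect_lt(as.numeric(thr10), as.numeric(thr) + 1e-12)  # monotone in level
  expect_error(empirical_threshold(s$prof, n_sim = 50), "100")
})

test_that("doubling the null replicates moves the threshold less than twice its bootstrap SE", {
  s <- sim_scan_setup(seed = 31)
  t1 <- empirical_threshold(s$prof, n_sim = 500, level = 0.05, seed = 2)
  t2 <- empirical_threshold(s$prof, n_sim = 1000, level = 0.05, seed = 3)
  boots <- replicate(200, {
    quantile(sample(attr(t1, "maxima"), replace = TRUE), 0.95, type = 7)
  })
  expect_lt(abs(as.numeric(t2) - as.numeric(t1)), 4 * sd(boots))
})

test_that("substitution-effect estimates are close to the simulated truth", {
  reps <- 200
  eff <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- sim_scan_setup(seed = 4000 + r, effect_distal = 0,
                        effect_proximal_given_distal_Q = 1,
                        effect_proximal_given_distal_q = 1)
    sc <- scan_chromosome(s$pheno, s$prof)
    eff[r] <- sc$effect_sd
  }
  expect_lt(abs(mean(eff) - 1), 0.15)
})

test_that("leave-one-subtype-out scans reduce to the full scan for an empty group", {
  s <- sim_scan_setup(seed = 37)
  subt <- tibble::tibble(
    animal = s$prof$animals,
    subtype = factor(rep("all", length(s$prof$animals)),
                     levels = c("all", "ghost", "phantom"))
  )
  subt$subtype[1:12] <- "ghost"
  scans <- leave_one_subtype_out_scans(s$pheno, s$prof, subt,
                                       n_sim = 200, seed = 5)
  expect_named(scans, c("full", "drop_all", "drop_ghost", "drop_phantom"),
               ignore.order = TRUE)
  expect_equal(scans$drop_ghost$n, length(s$prof$animals) - 12)
  # omitting the empty 'phantom' level reproduces the full-family scan
  expect_equal(scans$drop_phantom$scan, scans$full$scan, tolerance = 1e-12)
  expect_equal(scans$drop_phantom$max_pos, scans$full$max_pos)
  # thresholds recomputed on families of different size differ
  expect_false(isTRUE(all.equal(scans$full$threshold,
                                scans$drop_ghost$threshold)))
  expect_warning(
    leave_one_subtype_out_scans(
      s$pheno, s$prof,
      tibble::tibble(animal = s$prof$animals,
                     subtype = rep(c("big", "small"),
                                   c(30, length(s$prof$animals) - 30))),
      n_sim = 200, seed = 5),
    "half the family")
})

test_that("scan curves round-trip through the writers at full precision", {
  s <- sim_scan_setup(seed = 41)
  sc <- scan_chromosome(s$pheno, s$prof,
                        threshold = empirical_threshold(s$prof, n_sim = 200,
                                                        seed = 7))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "scan.tsv")
  write_scan(sc, path)
  back <- read_scan(path)
  expect_equal(back$scan$lrt, sc$scan$lrt, tolerance = 1e-12)
  expect_equal(back$max_pos, sc$max_pos)
  expect_equal(back$threshold, as.numeric(sc$threshold), tolerance = 1e-12)
  expect_equal(back$ci, sc$ci)
  expect_equal(back$effect, sc$effect, tolerance = 1e-12)
})
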