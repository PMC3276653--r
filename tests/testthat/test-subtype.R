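blob_data <- function(centers, n_per, n_genes = 30, sd = 0.3, seed = 1) {
  set.seed(seed)
  k <- length(centers)
  X <- do.call(cbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_genes * n_per, centers[j], sd), n_genes, n_per)
  }))
  rownames(X) <- sprintf("g%02d", seq_len(n_genes))
  colnames(X) <- sprintf("a%02d", seq_len(ncol(X)))
  list(X = X, truth = rep(seq_len(k), each = n_per))
}

test_that("well-separated blobs are recovered perfectly and edge cases hold", {
  d <- blob_data(c(-3, 3), n_per = 10)
  cl <- cluster_animals(d$X, rownames(d$X), k = 2)
  expect_equal(adjusted_rand_index(cl$assignment$cluster, d$truth), 1)
  cl1 <- cluster_animals(d$X, rownames(d$X), k = 1)
  expect_equal(unique(cl1$assignment$cluster), 1)
  expect_error(cluster_animals(d$X, character(), k = 2), "empty")
  expect_error(cluster_animals(d$X, rownames(d$X), k = 50), "k must be")
})

test_that("five synthetic signatures are recovered with high agreement", {
  set.seed(9)
  k <- 5; n_per <- 9; n_genes <- 60
  # each subtype gets its own signature over a block of genes
  X <- matrix(rnorm(n_genes * k * n_per, 0, 0.5), n_genes, k * n_per)
  for (j in seq_len(k)) {
    rows <- ((j - 1) * 12 + 1):(j * 12)
    cols <- ((j - 1) * n_per + 1):(j * n_per)
    X[rows, cols] <- X[rows, cols] + 2.5
  }
  rownames(X) <- sprintf("g%02d", seq_len(n_genes))
  colnames(X) <- sprintf("a%02d", seq_len(ncol(X)))
  truth <- rep(seq_len(k), each = n_per)
  cl <- cluster_animals(X, rownames(X), k = 5)
  expect_gt(adjusted_rand_index(cl$assignment$cluster, truth), 0.9)
})

test_that("clustering is invariant to gene order and per-gene affine rescaling", {
  d <- blob_data(c(-2, 0, 2), n_per = 8, seed = 4)
  cl0 <- cluster_animals(d$X, rownames(d$X), k = 3)
  perm <- sample(nrow(d$X))
  cl_perm <- cluster_animals(d$X[perm, ], rownames(d$X)[perm], k = 3)
  expect_equal(adjusted_rand_index(cl0$assignment$cluster,
                                   cl_perm$assignment$cluster), 1)
  X2 <- d$X * runif(nrow(d$X), 0.5, 4) + rnorm(nrow(d$X))
  cl_scaled <- cluster_animals(X2, rownames(X2), k = 3)
  expect_equal(adjusted_rand_index(cl0$assignment$cluster,
                                   cl_scaled$assignment$cluster), 1)
})

test_that("cutting the dendrogram at the stored height reproduces the partition", {
  d <- blob_data(c(-2, 1, 3), n_per = 7, seed = 6)
  cl <- cluster_animals(d$X, rownames(d$X), k = 3)
  again <- stats::cutree(cl$hclust, h = cl$height)
  expect_equal(length(unique(again)), 3)
  expect_equal(adjusted_rand_index(again, cl$assignment$cluster), 1)
})

test_that("trait tertiles follow the 20/20/5 labeling scheme", {
  pheno <- tibble::tibble(animal = sprintf("A%02d", 1:45),
                          trait = c(45:1))
  tert <- trait_tertiles(pheno)
  expect_equal(sum(tert$status == "F"), 20)
  expect_equal(sum(tert$status == "L"), 20)
  expect_equal(sum(tert$status == "I"), 5)
  expect_true(all(tert$trait[tert$status == "F"] >
                    max(tert$trait[tert$status == "I"])))
})

test_that("subgroups are named by majority trait status with size ordering", {
  mk_assignment <- function(clusters, animals) {
    structure(list(
      assignment = tibble::tibble(animal = animals, cluster = clusters),
      hclust = NULL, k = length(unique(clusters)), height = Inf,
      genes = "g"), class = "subtype_assignment")
  }
  # one all-fat and one all-lean group
  animals <- sprintf("A%02d", 1:10)
  tert <- tibble::tibble(animal = animals,
                         trait = c(10:6, 5:1),
                         status = factor(rep(c("F", "L"), each = 5),
                                         levels = c("F", "I", "L")))
  lab <- label_subtypes(mk_assignment(rep(1:2, each = 5), animals), tert)
  expect_equal(unique(lab$subtype[1:5]), "fat1")
  expect_equal(unique(lab$subtype[6:10]), "lean1")

  # five groups: 2 fat-dominated, 2 lean-dominated, 1 mixed
  animals45 <- sprintf("A%02d", 1:45)
  tert45 <- tibble::tibble(
    animal = animals45, trait = 45:1,
    status = factor(rep(c("F", "I", "L"), c(20, 5, 20)),
                    levels = c("F", "I", "L")))
  clusters <- c(rep(1, 12), rep(2, 8), rep(3, 5), rep(4, 11), rep(5, 9))
  lab45 <- label_subtypes(mk_assignment(clusters, animals45), tert45)
  by_cluster <- unique(lab45[, c("cluster", "subtype")])
  expect_setequal(by_cluster$subtype,
                  c("fat1", "fat2", "mixed", "lean1", "lean2"))
  expect_equal(by_cluster$subtype[by_cluster$cluster == 1], "fat1")  # larger
  expect_equal(by_cluster$subtype[by_cluster$cluster == 2], "fat2")
  expect_equal(by_cluster$subtype[by_cluster$cluster == 4], "lean1") # larger
  expect_equal(by_cluster$subtype[by_cluster$cluster == 5], "lean2")
  expect_equal(by_cluster$subtype[by_cluster$cluster == 3], "mixed")

  # a group with no fat/lean majority is mixed
  tert_i <- tibble::tibble(animal = animals[1:4], trait = 4:1,
                           status = factor(c("F", "L", "I", "I"),
                                           levels = c("F", "I", "L")))
  lab_i <- label_subtypes(mk_assignment(rep(1, 4), animals[1:4]), tert_i)
  expect_equal(unique(lab_i$subtype), "mixed")
})

test_that("factor-adjusted expression separates fat and lean better than raw under strong factors", {
  seps <- sapply(1:5, function(s) {
    sim <- simulate_family(sim_config(n_genes = 400, n_trait_genes = 60,
                                      n_interacting_eqtl_genes = 0,
                                      factor_loading_sd = 1.2,
                                      beta_trait = 0.8, seed = 700 + s))
    y <- adjust_phenotype(sim$pheno)$trait_adj
    tert <- trait_tertiles(dplyr::mutate(sim$pheno, trait = y))
    status2 <- as.character(tert$status)
    genes <- sim$truth$trait_gene_ids
    fit <- famt_fit(sim$expr, y, q = 6)
    ari <- function(mat) {
      cl <- cluster_animals(mat, genes, k = 2)
      adjusted_rand_index(cl$assignment$cluster[status2 != "I"],
                          status2[status2 != "I"])
    }
    c(raw = ari(sim$expr), adj = ari(fit$adjusted))
  })
  expect_gt(mean(seps["adj", ] - seps["raw", ]), 0)
  expect_gt(mean(seps["adj", ]), mean(seps["raw", ]))
})
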