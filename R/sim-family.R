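#' Simulate paternal gametes along one chromosome
#'
#' Draws, for each offspring, which of the sire's two homologs (1 or 2) was
#' transmitted at every requested position. Meiosis is modeled as a two-state
#' Markov chain along the chromosome: the origin at the first position is a
#' fair coin, and between adjacent positions the origin switches with the
#' Haldane recombination fraction for the intervening distance (no
#' interference). By convention homolog 1 carries the trait-increasing Q
#' allele at both QTL.
#'
#' @param map A marker map: data frame with a numeric `pos_cm` column in
#'   strictly increasing order (see [sim_marker_map()]), or a bare numeric
#'   vector of positions.
#' @param n Number of offspring.
#' @param seed Integer seed.
#' @param extra_positions Additional positions (e.g. QTL locations) at which
#'   the transmitted origin is also recorded.
#' @return A list with `positions` (sorted union of map and extra positions)
#'   and `origin`, an `n` x `length(positions)` integer matrix of 1/2 labels.
#' @export
#' @examples
#' g <- simulate_paternal_gametes(c(0, 10, 50), n = 5, seed = 1)
#' g$origin
simulate_paternal_gametes <- function(map, n, seed = 1L,
                                      extra_positions = numeric()) {
  pos <- if (is.data.frame(map)) map$pos_cm else as.numeric(map)
  if (length(pos) < 1L) stop("at least one position is required", call. = FALSE)
  if (any(diff(pos) < 0)) {
    stop("map positions must be sorted in increasing order", call. = FALSE)
  }
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  all_pos <- sort(unique(c(pos, extra_positions)))
  p <- length(all_pos)
  origin <- matrix(0L, nrow = n, ncol = p,
                   dimnames = list(NULL, format_pos(all_pos)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  origin[, 1L] <- sample(c(1L, 2L), n, replace = TRUE)
  if (p > 1L) {
    cc <- haldane_c(diff(all_pos))
    for (j in 2L:p) {
      switch_j <- stats::runif(n) < cc[j - 1L]
      origin[, j] <- ifelse(switch_j, 3L - origin[, j - 1L], origin[, j - 1L])
    }
  }
  list(positions = all_pos, origin = origin)
}

format_pos <- function(pos) sprintf("pos_%g", pos)

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Exact variance of the two-QTL genetic contribution. s_d, s_p are +/-1
# origin codes at the distal and proximal QTL with P(equal) = 1 - c for the
# Haldane fraction c of the inter-QTL distance; the proximal substitution
# effect depends on the distal allele.
qtl_variance <- function(cfg) {
  c_dp <- haldane_c(abs(cfg$qtl_distal_pos - cfg$qtl_proximal_pos))
  combos <- expand.grid(s_d = c(1, -1), s_p = c(1, -1))
  pr <- ifelse(combos$s_d == combos$s_p, (1 - c_dp) / 2, c_dp / 2)
  e_p <- ifelse(combos$s_d == 1,
                cfg$effect_proximal_given_distal_Q,
                cfg$effect_proximal_given_distal_q)
  v <- cfg$effect_distal / 2 * combos$s_d + e_p / 2 * combos$s_p
  sum(pr * v^2) - sum(pr * v)^2
}

#' Simulate trait values and covariates for a simulated family
#'
#' The trait is the sum of a two-QTL genetic contribution (distal substitution
#' effect plus a proximal effect conditional on the distal allele), a
#' polygenic term, a residual, and injected hatch/dam/body-weight covariate
#' effects. The polygenic and residual variances are scaled so that the
#' biological trait (QTL + polygenic + residual) has unit variance in
#' expectation; `h2_polygenic` fixes the polygenic share of the non-QTL
#' variance. Within a single half-sib family the polygenic term has no
#' between-animal structure beyond an overall family mean, so both components
#' are drawn i.i.d. Gaussian and recorded separately in the truth.
#'
#' @param truth A ground-truth list as built by [simulate_family()]; must
#'   contain `origin_qtl`, an n x 2 matrix of origins at the (proximal,
#'   distal) QTL.
#' @param config A [sim_config()].
#' @return A tibble with columns `animal`, `trait`, `hatch`, `dam`,
#'   `body_weight`, plus attribute `components` (a tibble with the genetic,
#'   polygenic, residual and covariate parts, in internal SD units).
#' @export
simulate_phenotypes <- function(truth, config) {
  cfg <- validate_sim_config(config)
  n <- nrow(truth$origin_qtl)
  s_p <- ifelse(truth$origin_qtl[, 1L] == 1L, 1, -1)
  s_d <- ifelse(truth$origin_qtl[, 2L] == 1L, 1, -1)
  e_p <- ifelse(s_d == 1,
                cfg$effect_proximal_given_distal_Q,
                cfg$effect_proximal_given_distal_q)
  genetic <- cfg$effect_distal / 2 * s_d + e_p / 2 * s_p
  v_qtl <- qtl_variance(cfg)
  v_env <- max(1 - v_qtl, 0.05)
  polygenic <- stats::rnorm(n, 0, sqrt(cfg$h2_polygenic * v_env))
  residual <- stats::rnorm(n, 0, sqrt((1 - cfg$h2_polygenic) * v_env))

  hatch <- factor(sample(seq_len(cfg$n_hatches), n, replace = TRUE),
                  levels = seq_len(cfg$n_hatches),
                  labels = sprintf("hatch%d", seq_len(cfg$n_hatches)))
  dam <- factor(sample(seq_len(cfg$n_dams), n, replace = TRUE),
                levels = seq_len(cfg$n_dams),
                labels = sprintf("dam%d", seq_len(cfg$n_dams)))
  hatch_eff <- stats::rnorm(cfg$n_hatches, 0, cfg$hatch_sd)[as.integer(hatch)]
  dam_eff <- stats::rnorm(cfg$n_dams, 0, cfg$dam_sd)[as.integer(dam)]
  body_weight <- stats::rnorm(n)
  covariate <- hatch_eff + dam_eff + cfg$body_weight_effect * body_weight

  trait_internal <- genetic + polygenic + residual + covariate
  out <- tibble::tibble(
    animal = truth$animal,
    trait = cfg$trait_scale * trait_internal,
    hatch = hatch,
    dam = dam,
    body_weight = body_weight
  )
  attr(out, "components") <- tibble::tibble(
    animal = truth$animal,
    genetic = genetic, polygenic = polygenic,
    residual = residual, covariate = covariate
  )
  out
}

#' Simulate a factor-structured expression matrix
#'
#' Gene expression follows `x_gi = beta_g * trait_i + b_g' z_i + qtl_gi +
#' e_gi`: `z_i` are `n_factors` hidden scores drawn independently of the
#' trait (shared technical or physiological variation), `beta_g` is nonzero
#' only for the designated trait genes, and the designated interacting genes
#' receive a two-locus genetic contribution — a distal eQTL plus a proximal
#' eQTL expressed conditionally on the distal allele — so that their
#' expression maps to both QTL regions in interaction. The trait entering the
#' trait genes' model is the standardized non-QTL component of the biological
#' trait (polygenic + residual): this keeps the generator's two gene
#' categories distinct — trait-correlated genes carry no QTL signal of their
#' own, and the interacting genes are the only transcripts whose expression
#' maps to the two loci.
#'
#' @inheritParams simulate_phenotypes
#' @return A wide expression tibble: column `gene_id` plus one numeric column
#'   per animal (log-scale units). Truth fields (`loadings`, `factor_scores`,
#'   `beta`, `psi`) are attached as attributes.
#' @export
simulate_expression <- function(truth, config) {
  cfg <- validate_sim_config(config)
  n <- length(truth$animal)
  m <- cfg$n_genes
  q <- cfg$n_factors
  gene_id <- sprintf("gene%04d", seq_len(m))
  trait_genes <- truth$trait_gene_ids
  inter_genes <- truth$interacting_gene_ids

  y <- truth$nonqtl_trait
  y_std <- as.numeric(scale(y))

  beta <- numeric(m)
  beta[match(trait_genes, gene_id)] <-
    cfg$beta_trait * sample(c(-1, 1), length(trait_genes), replace = TRUE)

  B <- if (q > 0) {
    matrix(stats::rnorm(m * q, 0, cfg$factor_loading_sd), m, q)
  } else {
    matrix(0, m, 0)
  }
  Z <- if (q > 0) matrix(stats::rnorm(n * q), n, q) else matrix(0, n, 0)

  psi <- stats::runif(m, 0.6, 1.4)
  X <- beta %o% y_std +
    (if (q > 0) B %*% t(Z) else 0) +
    matrix(stats::rnorm(m * n, 0, 1), m, n) * sqrt(psi)

  if (length(inter_genes) > 0) {
    s_p <- ifelse(truth$origin_qtl[, 1L] == 1L, 1, -1)
    s_d <- ifelse(truth$origin_qtl[, 2L] == 1L, 1, -1)
    e_p <- ifelse(s_d == 1,
                  cfg$eqtl_effect_proximal_given_distal_Q,
                  cfg$eqtl_effect_proximal_given_distal_q)
    sig <- cfg$eqtl_effect_distal / 2 * s_d + e_p / 2 * s_p
    X[match(inter_genes, gene_id), ] <-
      X[match(inter_genes, gene_id), , drop = FALSE] +
      matrix(sig, length(inter_genes), n, byrow = TRUE)
  }

  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- truth$animal
  out <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), out)
  attr(out, "loadings") <- B
  attr(out, "factor_scores") <- Z
  attr(out, "beta") <- beta
  attr(out, "psi") <- psi
  out
}

#' Simulate a complete half-sib study
#'
#' Runs the whole generator — paternal gametes, marker observations with
#' missingness, trait + covariates, expression matrix — and returns every
#' observable table alongside the ground truth, so each downstream stage of
#' the pipeline can be tested against known answers.
#'
#' @param config A [sim_config()].
#' @return A list of class `halfsib_sim` with elements:
#'   \describe{
#'     \item{map}{marker map tibble (`marker`, `chrom`, `pos_cm`).}
#'     \item{inherit}{wide tibble `animal` x markers of observed paternal
#'       origins (1 = Q-carrying homolog, 2 = q-carrying, `NA` =
#'       uninformative meiosis).}
#'     \item{pheno}{phenotype tibble from [simulate_phenotypes()].}
#'     \item{expr}{expression tibble from [simulate_expression()].}
#'     \item{truth}{ground truth: full origin matrix at markers + QTL,
#'       origins at the QTL, trait components, trait/interacting gene ids,
#'       factor loadings and scores.}
#'   }
#' @export
#' @examples
#' sim <- simulate_family(sim_config(n_genes = 50, n_trait_genes = 5, seed = 2))
#' names(sim)
simulate_family <- function(config) {
  cfg <- validate_sim_config(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed)

  map <- sim_marker_map(cfg)
  qtl_pos <- c(cfg$qtl_proximal_pos, cfg$qtl_distal_pos)
  gam <- simulate_paternal_gametes(map, cfg$n_offspring,
                                   seed = sample.int(.Machine$integer.max, 1),
                                   extra_positions = qtl_pos)
  animal <- sprintf("A%02d", seq_len(cfg$n_offspring))

  marker_idx <- match(map$pos_cm, gam$positions)
  qtl_idx <- match(qtl_pos, gam$positions)
  origin_markers <- gam$origin[, marker_idx, drop = FALSE]
  colnames(origin_markers) <- map$marker
  origin_qtl <- gam$origin[, qtl_idx, drop = FALSE]
  colnames(origin_qtl) <- c("proximal", "distal")

  observed <- origin_markers
  if (cfg$missing_marker_rate > 0) {
    mask <- matrix(stats::runif(length(observed)) < cfg$missing_marker_rate,
                   nrow = nrow(observed))
    observed[mask] <- NA_integer_
  }
  inherit <- dplyr::bind_cols(
    tibble::tibble(animal = animal),
    tibble::as_tibble(as.data.frame(observed))
  )

  gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  ids <- sample(gene_id, cfg$n_trait_genes + cfg$n_interacting_eqtl_genes)
  truth <- list(
    animal = animal,
    positions = gam$positions,
    origin = gam$origin,
    origin_qtl = origin_qtl,
    trait_gene_ids = sort(utils::head(ids, cfg$n_trait_genes)),
    interacting_gene_ids = sort(utils::tail(ids, cfg$n_interacting_eqtl_genes)),
    sire_phase = c(homolog_Q = 1L, homolog_q = 2L)
  )

  pheno <- simulate_phenotypes(truth, cfg)
  comp <- attr(pheno, "components")
  truth$components <- comp
  truth$biological_trait <- comp$genetic + comp$polygenic + comp$residual
  truth$nonqtl_trait <- comp$polygenic + comp$residual

  expr <- simulate_expression(truth, cfg)
  truth$loadings <- attr(expr, "loadings")
  truth$factor_scores <- attr(expr, "factor_scores")
  truth$beta <- attr(expr, "beta")

  structure(
    list(map = map, inherit = inherit, pheno = pheno, expr = expr,
         truth = truth, config = cfg),
    class = "halfsib_sim"
  )
}

#' @export
print.halfsib_sim <- function(x, ...) {
  cat("<halfsib_sim>\n")
  cat(sprintf("  %d offspring, %d markers, %d genes\n",
              x$config$n_offspring, nrow(x$map), nrow(x$expr)))
  invisible(x)
}
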