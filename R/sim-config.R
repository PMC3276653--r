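#' Configuration for the half-sib family simulator
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' The defaults emulate a single-sire chicken half-sib design: 45 offspring,
#' one 200 cM chromosome genotyped at ten microsatellites, a sire heterozygous
#' (Qq) at two linked fatness QTL — a distal locus at 168 cM and a proximal
#' locus at 85 cM — whose proximal substitution effect depends on the distal
#' allele, a polygenic + residual trait model, and a hepatic expression matrix
#' with a low-rank hidden-factor component independent of the trait.
#'
#' Effects are expressed in phenotypic standard deviations: the defaults map
#' the +15 g / -4 g conditional proximal pattern onto +1.19 / -0.32 SD
#' (phenotypic SD taken as 12.6 g, which also makes the distal effect 1.03 SD).
#' The generator rescales the polygenic and residual components so that the
#' total phenotypic variance (QTL included) is 1; `trait_scale` then converts
#' to output units, so `trait_scale = 12.6` reproduces the gram-scale
#' narrative.
#'
#' @param n_offspring Number of half-sib offspring (default 45).
#' @param chromosome_length Chromosome length in cM (default 200).
#' @param marker_positions Ordered marker positions in cM. Defaults to the ten
#'   microsatellites at 83, 100, 125, 151, 162, 166, 175, 187, 190, 192 cM.
#' @param dense_proximal_markers If `TRUE`, add six SNPs at 67, 77, 80, 86,
#'   89, 95 cM that densify the proximal region.
#' @param qtl_proximal_pos,qtl_distal_pos QTL positions in cM (85 and 168).
#' @param effect_distal Q-vs-q substitution effect of the distal QTL, in
#'   phenotypic SD (default 1.03).
#' @param effect_proximal_given_distal_Q,effect_proximal_given_distal_q
#'   Conditional proximal substitution effects given the paternal allele
#'   received at the distal QTL (defaults +1.19 / -0.32 SD).
#' @param h2_polygenic Share of the non-QTL variance attributed to the
#'   polygenic term (default 0.5).
#' @param n_genes,n_factors Number of genes and hidden expression factors
#'   (defaults 2000 and 6).
#' @param n_trait_genes Number of genes with a direct trait coefficient
#'   (default 50).
#' @param n_interacting_eqtl_genes Number of genes whose expression is
#'   controlled by the two QTL in interaction (default 4).
#' @param missing_marker_rate Probability that the paternal origin at a marker
#'   is uninformative and masked to `NA` (default 0.15, which best reproduces
#'   the reference haplotype table's determined-animal counts on the
#'   ten-marker design).
#' @param factor_loading_sd SD of the factor loadings shared by all genes
#'   (default 0.5; with 6 factors this puts roughly half of each gene's
#'   variance on the common factors).
#' @param beta_trait Absolute trait coefficient of the trait genes, in
#'   per-SD-of-trait expression units (default 1).
#' @param eqtl_effect_distal Distal substitution effect on the interacting
#'   genes' expression (default 2 specific-noise SD, strong enough for a
#'   single-family eQTL scan at n = 45 to localize it).
#' @param eqtl_effect_proximal_given_distal_Q,eqtl_effect_proximal_given_distal_q
#'   Conditional proximal substitution effects on the interacting genes'
#'   expression (defaults 2 and 0).
#' @param n_hatches,n_dams Numbers of hatches and dams (defaults 4 and 8).
#' @param hatch_sd,dam_sd SDs of the injected hatch and dam effects on the
#'   trait (defaults 0.25 SD each).
#' @param body_weight_effect Trait shift per SD of body weight (default 0.2).
#' @param trait_scale Multiplier converting the unit-variance internal trait
#'   to output units (default 1; use 12.6 for grams).
#' @param seed Integer seed making the whole simulation reproducible.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_family()]
#' @export
#' @examples
#' cfg <- sim_config(n_offspring = 20, n_genes = 100, seed = 7)
#' cfg$qtl_distal_pos
sim_config <- function(n_offspring = 45,
                       chromosome_length = 200,
                       marker_positions = c(83, 100, 125, 151, 162, 166,
                                            175, 187, 190, 192),
                       dense_proximal_markers = FALSE,
                       qtl_proximal_pos = 85,
                       qtl_distal_pos = 168,
                       effect_distal = 1.03,
                       effect_proximal_given_distal_Q = 1.19,
                       effect_proximal_given_distal_q = -0.32,
                       h2_polygenic = 0.5,
                       n_genes = 2000,
                       n_factors = 6,
                       n_trait_genes = 50,
                       n_interacting_eqtl_genes = 4,
                       missing_marker_rate = 0.15,
                       factor_loading_sd = 0.5,
                       beta_trait = 1,
                       eqtl_effect_distal = 2,
                       eqtl_effect_proximal_given_distal_Q = 2,
                       eqtl_effect_proximal_given_distal_q = 0,
                       n_hatches = 4,
                       n_dams = 8,
                       hatch_sd = 0.25,
                       dam_sd = 0.25,
                       body_weight_effect = 0.2,
                       trait_scale = 1,
                       seed = 1L) {
  if (isTRUE(dense_proximal_markers)) {
    marker_positions <- sort(unique(c(marker_positions,
                                      c(67, 77, 80, 86, 89, 95))))
  }
  cfg <- list(
    n_offspring = as.integer(n_offspring),
    chromosome_length = chromosome_length,
    marker_positions = marker_positions,
    qtl_proximal_pos = qtl_proximal_pos,
    qtl_distal_pos = qtl_distal_pos,
    effect_distal = effect_distal,
    effect_proximal_given_distal_Q = effect_proximal_given_distal_Q,
    effect_proximal_given_distal_q = effect_proximal_given_distal_q,
    h2_polygenic = h2_polygenic,
    n_genes = as.integer(n_genes),
    n_factors = as.integer(n_factors),
    n_trait_genes = as.integer(n_trait_genes),
    n_interacting_eqtl_genes = as.integer(n_interacting_eqtl_genes),
    missing_marker_rate = missing_marker_rate,
    factor_loading_sd = factor_loading_sd,
    beta_trait = beta_trait,
    eqtl_effect_distal = eqtl_effect_distal,
    eqtl_effect_proximal_given_distal_Q = eqtl_effect_proximal_given_distal_Q,
    eqtl_effect_proximal_given_distal_q = eqtl_effect_proximal_given_distal_q,
    n_hatches = as.integer(n_hatches),
    n_dams = as.integer(n_dams),
    hatch_sd = hatch_sd,
    dam_sd = dam_sd,
    body_weight_effect = body_weight_effect,
    trait_scale = trait_scale,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_offspring < 1L) stop("n_offspring must be >= 1", call. = FALSE)
  pos <- cfg$marker_positions
  if (length(pos) < 1L) stop("at least one marker is required", call. = FALSE)
  if (any(diff(pos) <= 0)) {
    stop("marker positions must be strictly increasing", call. = FALSE)
  }
  all_pos <- c(pos, cfg$qtl_proximal_pos, cfg$qtl_distal_pos)
  if (any(all_pos < 0 | all_pos > cfg$chromosome_length)) {
    stop("all positions must lie within [0, chromosome_length]", call. = FALSE)
  }
  if (cfg$h2_polygenic < 0 || cfg$h2_polygenic > 1) {
    stop("h2_polygenic must be in [0, 1]", call. = FALSE)
  }
  if (cfg$missing_marker_rate < 0 || cfg$missing_marker_rate > 1) {
    stop("missing_marker_rate must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_genes < cfg$n_trait_genes + cfg$n_interacting_eqtl_genes) {
    stop("n_genes must be >= n_trait_genes + n_interacting_eqtl_genes",
         call. = FALSE)
  }
  if (cfg$n_factors < 0L) stop("n_factors must be >= 0", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d offspring, %d markers on a %g cM chromosome\n",
              x$n_offspring, length(x$marker_positions), x$chromosome_length))
  cat(sprintf("  QTL at %g cM (proximal) and %g cM (distal)\n",
              x$qtl_proximal_pos, x$qtl_distal_pos))
  cat(sprintf("  conditional proximal effects: %+.2f SD | distal Q, %+.2f SD | distal q\n",
              x$effect_proximal_given_distal_Q,
              x$effect_proximal_given_distal_q))
  cat(sprintf("  %d genes, %d hidden factors, %d trait genes, %d interacting eQTL genes\n",
              x$n_genes, x$n_factors, x$n_trait_genes,
              x$n_interacting_eqtl_genes))
  invisible(x)
}

#' Default marker map of the simulated chromosome
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `marker`, `chrom`, `pos_cm`.
#' @export
sim_marker_map <- function(config) {
  pos <- config$marker_positions
  tibble::tibble(
    marker = sprintf("M%02d", seq_along(pos)),
    chrom = "chr1",
    pos_cm = pos
  )
}
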