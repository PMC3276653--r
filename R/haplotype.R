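#' Call paternal Q/q haplotypes in a QTL region
#'
#' Computes, for every animal, the probability of having received the sire's
#' Q-carrying homolog at the center of a QTL region, using only the markers
#' inside `[center - halfwidth, center + halfwidth]`, and calls `Q` when
#' `P(Q) > threshold`, `q` when `P(q) > threshold`, and `x` (undetermined)
#' otherwise. The default 0.99 threshold makes a determined call wrong less
#' than 1% of the time by construction.
#'
#' @inheritParams transmission_probabilities
#' @param region_center Region center in cM.
#' @param region_halfwidth Half-width in cM.
#' @param threshold Posterior probability required for a determined call
#'   (default 0.99).
#' @param at `"center"` (default) evaluates the posterior at the region
#'   center; `"max"` at the in-region marker position where the posterior is
#'   most extreme for each animal.
#' @return Tibble `animal`, `p_q` (posterior P(Q)), `call` (`Q`/`q`/`x`).
#' @export
#' @examples
#' inherit <- tibble::tibble(animal = c("A1", "A2"),
#'                           M1 = c(1L, 1L), M2 = c(1L, 2L))
#' map <- tibble::tibble(marker = c("M1", "M2"), chrom = "chr1",
#'                       pos_cm = c(95, 105))
#' call_haplotype(inherit, map, region_center = 100, region_halfwidth = 20)
call_haplotype <- function(inherit, map, region_center, region_halfwidth,
                           threshold = 0.99, sire_phase = 1L,
                           at = c("center", "max")) {
  at <- match.arg(at)
  lo <- region_center - region_halfwidth
  hi <- region_center + region_halfwidth
  marker_cols <- intersect(names(inherit), map$marker)
  in_region <- map$marker[map$marker %in% marker_cols &
                            map$pos_cm >= lo & map$pos_cm <= hi]
  if (length(in_region) == 0) {
    warning(sprintf("no marker in region %g +/- %g cM: all calls are 'x'",
                    region_center, region_halfwidth), call. = FALSE)
    return(tibble::tibble(animal = inherit$animal, p_q = 0.5, call = "x"))
  }
  sub <- inherit[, c("animal", in_region)]
  grid <- sort(unique(c(region_center,
                        map$pos_cm[map$marker %in% in_region])))
  prof <- transmission_probabilities(sub, map, sire_phase = sire_phase,
                                     grid = grid)
  if (at == "center") {
    p_q <- prof$pi[, match(region_center, grid)]
  } else {
    p_q <- apply(prof$pi, 1L, function(p) p[which.max(abs(p - 0.5))])
  }
  call <- ifelse(p_q > threshold, "Q", ifelse(1 - p_q > threshold, "q", "x"))
  tibble::tibble(animal = inherit$animal, p_q = unname(p_q), call = unname(call))
}

#' Two-region haplotype table
#'
#' Combines per-animal proximal and distal calls into the standard summary
#' table: one row per animal with its subgroup, both single-locus calls, and
#' the joint call (`Q-Q`, `Q-q`, `q-Q`, `q-q`, or `X` when either locus is
#' undetermined), plus the determined-animal counts.
#'
#' @param calls_proximal,calls_distal Tibbles with `animal` and `call`
#'   columns (from [call_haplotype()]), over the same animal set.
#' @param subtypes Optional tibble `animal`, `subtype`.
#' @return Tibble of class `haplotype_table` with columns `animal`,
#'   `subgroup`, `proximal`, `distal`, `both`; counts in attribute `counts`
#'   (`n_proximal_determined`, `n_distal_determined`, `n_both_determined`)
#'   and via [glance.haplotype_table()].
#' @export
haplotype_table <- function(calls_proximal, calls_distal, subtypes = NULL) {
  if (!setequal(calls_proximal$animal, calls_distal$animal)) {
    stop("proximal and distal calls cover different animal sets",
         call. = FALSE)
  }
  distal <- calls_distal$call[match(calls_proximal$animal,
                                    calls_distal$animal)]
  out <- tibble::tibble(
    animal = calls_proximal$animal,
    subgroup = NA_character_,
    proximal = calls_proximal$call,
    distal = distal,
    both = ifelse(calls_proximal$call == "x" | distal == "x", "X",
                  paste(calls_proximal$call, distal, sep = "-"))
  )
  if (!is.null(subtypes)) {
    out$subgroup <- subtypes$subtype[match(out$animal, subtypes$animal)]
  }
  new_haplotype_table(out)
}

new_haplotype_table <- function(df) {
  stopifnot(all(c("animal", "subgroup", "proximal", "distal", "both")
                %in% names(df)))
  bad <- !(df$proximal %in% c("Q", "q", "x")) |
    !(df$distal %in% c("Q", "q", "x"))
  if (any(bad)) {
    stop("haplotype calls must be 'Q', 'q' or 'x'", call. = FALSE)
  }
  counts <- c(
    n_proximal_determined = sum(df$proximal != "x"),
    n_distal_determined = sum(df$distal != "x"),
    n_both_determined = sum(df$proximal != "x" & df$distal != "x")
  )
  attr(df, "counts") <- counts
  class(df) <- c("haplotype_table", class(df))
  df
}

#' @export
glance.haplotype_table <- function(x, ...) {
  counts <- attr(x, "counts")
  tibble::tibble(
    n_animals = nrow(x),
    n_proximal_determined = unname(counts["n_proximal_determined"]),
    n_distal_determined = unname(counts["n_distal_determined"]),
    n_both_determined = unname(counts["n_both_determined"])
  )
}

#' Per-subgroup haplotype counts at one locus
#'
#' @param table A [haplotype_table()].
#' @param subgroup Subgroup name present in the table.
#' @param locus `"proximal"` or `"distal"`.
#' @return One-row tibble `subgroup`, `locus`, `n_in_group`, `n_determined`,
#'   `count_Q`, `count_q`.
#' @export
subtype_haplotype_summary <- function(table, subgroup,
                                      locus = c("proximal", "distal")) {
  locus <- match.arg(locus)
  known <- if (is.factor(table$subgroup)) {
    levels(table$subgroup)   # factors may carry empty (unused) subgroups
  } else {
    unique(stats::na.omit(table$subgroup))
  }
  if (!subgroup %in% known) {
    stop(sprintf("unknown subgroup '%s' (have: %s)", subgroup,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  calls <- table[[locus]][!is.na(table$subgroup) &
                            table$subgroup == subgroup]
  tibble::tibble(
    subgroup = subgroup, locus = locus,
    n_in_group = length(calls),
    n_determined = sum(calls != "x"),
    count_Q = sum(calls == "Q"),
    count_q = sum(calls == "q")
  )
}
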