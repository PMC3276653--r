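#' Fat / lean / intermediate status from the trait ranking
#'
#' Labels the `n_extreme` fattest animals `F`, the `n_extreme` leanest `L`,
#' and the remainder `I`, mirroring the usual extreme-group labeling of a
#' 45-offspring family (20 fattest, 20 leanest, 5 intermediates). For other
#' family sizes the default group size is `round(4 n / 9)`.
#'
#' @param pheno Phenotype tibble with `animal` and `trait` columns.
#' @param n_extreme Animals per extreme group; default `round(4 n / 9)`.
#' @return Tibble with columns `animal`, `trait`, `status` (factor F/I/L).
#' @export
trait_tertiles <- function(pheno, n_extreme = NULL) {
  stopifnot(all(c("animal", "trait") %in% names(pheno)))
  n <- nrow(pheno)
  if (is.null(n_extreme)) n_extreme <- round(4 * n / 9)
  if (2 * n_extreme > n) stop("2 * n_extreme must not exceed n", call. = FALSE)
  rk <- rank(pheno$trait, ties.method = "first")
  status <- rep("I", n)
  status[rk <= n_extreme] <- "L"
  status[rk > n - n_extreme] <- "F"
  tibble::tibble(animal = pheno$animal, trait = pheno$trait,
                 status = factor(status, levels = c("F", "I", "L")))
}

#' Hierarchical clustering of animals on a trait-associated gene list
#'
#' Standardizes each listed gene across animals, computes Euclidean distances
#' between animals, and cuts a Ward-linkage dendrogram (`ward.D2`) into `k`
#' groups. Distance and linkage are configurable (`"complete"`, `"average"`;
#' `distance = "correlation"` uses `1 - cor` between animal profiles). The
#' result is deterministic and invariant to gene order and per-gene affine
#' rescaling.
#'
#' @inheritParams correlation_test
#' @param genes Character vector of gene ids to cluster on (non-empty).
#' @param k Number of groups (1 <= k <= n animals). `k` is user-chosen; a
#'   silhouette-style suggestion is available via [suggest_k()], never
#'   auto-applied.
#' @param linkage `hclust` agglomeration method (default `"ward.D2"`).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return Object of class `subtype_assignment`: list with `assignment`
#'   (tibble `animal`, `cluster`), `hclust`, `k`, `height` (cut height),
#'   `genes`.
#' @export
cluster_animals <- function(expr, genes, k, linkage = "ward.D2",
                            distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  em <- expr_matrix(expr)
  if (length(genes) == 0) stop("the gene list is empty", call. = FALSE)
  missing <- setdiff(genes, rownames(em))
  if (length(missing) > 0) {
    stop("genes absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sub <- em[genes, , drop = FALSE]
  keep <- apply(sub, 1L, stats::sd) > 0
  sub <- t(scale(t(sub[keep, , drop = FALSE])))  # per-gene standardization
  n <- ncol(sub)
  if (k < 1 || k > n) stop("k must be in [1, n animals]", call. = FALSE)
  d <- if (distance == "euclidean") {
    stats::dist(t(sub))
  } else {
    stats::as.dist(1 - stats::cor(sub))
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  height <- if (k == 1 || k > length(hc$height)) {
    Inf
  } else {
    # Any cut strictly between these merge heights reproduces the partition.
    mean(sort(hc$height, decreasing = TRUE)[c(k - 1, k)])
  }
  structure(
    list(assignment = tibble::tibble(animal = colnames(em),
                                     cluster = unname(cl)),
         hclust = hc, k = k, height = height, genes = genes[keep]),
    class = "subtype_assignment"
  )
}

#' Silhouette-style suggestion for the number of subgroups
#'
#' Mean silhouette width (computed from the same distance used for
#' clustering) for each candidate `k`; returned for inspection only.
#'
#' @inheritParams cluster_animals
#' @param k_range Candidate values of `k` (default 2:8).
#' @return Tibble with `k` and `mean_silhouette`.
#' @export
suggest_k <- function(expr, genes, k_range = 2:8, linkage = "ward.D2",
                      distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  em <- expr_matrix(expr)
  sub <- em[genes, , drop = FALSE]
  keep <- apply(sub, 1L, stats::sd) > 0
  sub <- t(scale(t(sub[keep, , drop = FALSE])))
  d <- if (distance == "euclidean") stats::dist(t(sub)) else
    stats::as.dist(1 - stats::cor(sub))
  dm <- as.matrix(d)
  hc <- stats::hclust(d, method = linkage)
  purrr::map_dfr(k_range[k_range < ncol(sub)], function(k) {
    cl <- stats::cutree(hc, k = k)
    sil <- vapply(seq_along(cl), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(dm[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(g) mean(dm[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    tibble::tibble(k = k, mean_silhouette = mean(sil))
  })
}

#' Name subgroups by their dominant trait status
#'
#' Subgroups with a strict majority of fat (`F`) animals are named `fat1`,
#' `fat2`, ... in decreasing size order; lean-majority groups `lean1`,
#' `lean2`, ...; all others `mixed` (`mixed2`, ... if several). Size ties are
#' broken by mean trait value (fatter first among fat groups, leaner first
#' among lean groups).
#'
#' @param assignment A [cluster_animals()] result.
#' @param tertiles A [trait_tertiles()] tibble for the same animals.
#' @return Tibble `animal`, `cluster`, `subtype`, `status`, `trait`.
#' @export
label_subtypes <- function(assignment, tertiles) {
  stopifnot(inherits(assignment, "subtype_assignment"))
  df <- dplyr::left_join(assignment$assignment, tertiles, by = "animal")
  if (anyNA(df$status)) {
    stop("trait status missing for some clustered animals", call. = FALSE)
  }
  summ <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_fat = sum(.data$status == "F"),
      n_lean = sum(.data$status == "L"),
      mean_trait = mean(.data$trait),
      .groups = "drop"
    ) |>
    dplyr::mutate(kind = dplyr::case_when(
      .data$n_fat > .data$n / 2 ~ "fat",
      .data$n_lean > .data$n / 2 ~ "lean",
      TRUE ~ "mixed"
    ))
  label_one_kind <- function(s, kind) {
    s <- s[s$kind == kind, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    ord <- order(-s$n, if (kind == "lean") s$mean_trait else -s$mean_trait)
    s <- s[ord, ]
    s$subtype <- if (kind == "mixed" && nrow(s) == 1) {
      "mixed"
    } else {
      paste0(kind, seq_len(nrow(s)))
    }
    s
  }
  labeled <- dplyr::bind_rows(
    label_one_kind(summ, "fat"),
    label_one_kind(summ, "lean"),
    label_one_kind(summ, "mixed")
  )
  dplyr::left_join(df, dplyr::select(labeled, "cluster", "subtype"),
                   by = "cluster") |>
    dplyr::select("animal", "cluster", "subtype", "status", "trait")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment: %d animals in %d groups (%d genes)>\n",
              nrow(x$assignment), x$k, length(x$genes)))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' @export
tidy.subtype_assignment <- function(x, ...) x$assignment

#' @export
autoplot.subtype_assignment <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # Segment representation of the dendrogram.
  xy <- dendrogram_segments(dend)
  labs <- tibble::tibble(
    label = hc$labels[hc$order],
    x = seq_along(hc$order)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = xy,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(xy$y),
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 2.6) +
    ggplot2::geom_hline(yintercept = object$height, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.15, 0.05))) +
    ggplot2::labs(x = NULL, y = "merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

dendrogram_segments <- function(dend) {
  segs <- list()
  walk <- function(node) {
    if (is.leaf(node)) {
      return(c(x = attr(node, "midpoint_abs"), y = 0))
    }
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    h <- attr(node, "height")
    xs <- vapply(kids, `[[`, numeric(1), "x")
    ys <- vapply(kids, `[[`, numeric(1), "y")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1L]] <<- tibble::tibble(
        x = xs[i], y = ys[i], xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      x = min(xs), y = h, xend = max(xs), yend = h)
    c(x = mean(range(xs)), y = h)
  }
  # Assign absolute leaf positions first.
  counter <- 0L
  assign_pos <- function(node) {
    if (is.leaf(node)) {
      counter <<- counter + 1L
      attr(node, "midpoint_abs") <- counter
      return(node)
    }
    for (i in seq_along(node)) node[[i]] <- assign_pos(node[[i]])
    node
  }
  dend <- assign_pos(dend)
  walk(dend)
  dplyr::bind_rows(segs)
}
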