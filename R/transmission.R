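#' Paternal transmission probabilities along a chromosome
#'
#' Computes, for every offspring and every position of a cM grid, the
#' posterior probability that the sire's Q-carrying homolog was transmitted,
#' given the observed paternal origins at informative markers. Transmission is
#' modeled as a two-state hidden Markov chain along the chromosome (fair prior
#' at the first position, Haldane switch probabilities between adjacent
#' positions, no interference); posteriors are obtained by the
#' forward--backward algorithm, with grid positions between markers handled
#' exactly by conditioning on the flanking forward and backward quantities.
#' Markers with unknown origin contribute nothing.
#'
#' Apparent double recombinants over short intervals (a switch between
#' adjacent informative markers closer than `flag_cm`) are flagged in the
#' `flagged` attribute but never dropped: under the Haldane model they are
#' improbable, not impossible. Two conflicting observations at zero distance
#' have probability zero and raise an error.
#'
#' @param inherit Wide inheritance tibble: column `animal` plus one column per
#'   marker holding the observed sire homolog (1 or 2) or `NA`.
#' @param map Marker map tibble (`marker`, `chrom`, `pos_cm`), markers ordered
#'   by position; every non-`animal` column of `inherit` must appear in it.
#' @param sire_phase Which homolog label carries Q (default 1).
#' @param grid Numeric vector of positions to evaluate; default a regular grid
#'   from the first to the last marker at `step` cM.
#' @param step Grid step in cM (default 1).
#' @param flag_cm Flag observed switches spanning less than this distance
#'   (default 2 cM).
#' @return An object of class `transmission_profile`: list with `grid`,
#'   `pi` (animals x grid matrix of P(Q transmitted)), `animals`, `map`, and
#'   a `flagged` tibble of suspicious double recombinants.
#' @export
#' @examples
#' inherit <- tibble::tibble(animal = "A1", M1 = 1L, M2 = 1L)
#' map <- tibble::tibble(marker = c("M1", "M2"), chrom = "chr1",
#'                       pos_cm = c(0, 10))
#' pr <- transmission_probabilities(inherit, map, grid = 5)
#' pr$pi  # ~0.9975 at the midpoint of two concordant markers
transmission_probabilities <- function(inherit, map, sire_phase = 1L,
                                       grid = NULL, step = 1,
                                       flag_cm = 2) {
  marker_cols <- setdiff(names(inherit), "animal")
  missing_markers <- setdiff(marker_cols, map$marker)
  if (length(missing_markers) > 0) {
    stop("markers absent from the map: ",
         paste(missing_markers, collapse = ", "), call. = FALSE)
  }
  map_used <- map[map$marker %in% marker_cols, , drop = FALSE]
  if (any(diff(map_used$pos_cm) < 0)) {
    stop("map positions must be sorted in increasing order", call. = FALSE)
  }
  pos <- map_used$pos_cm
  obs <- as.matrix(inherit[, map_used$marker, drop = FALSE])
  storage.mode(obs) <- "integer"
  if (any(!is.na(obs) & !(obs %in% c(1L, 2L)))) {
    stop("inheritance entries must be 1, 2 or NA", call. = FALSE)
  }
  if (!sire_phase %in% c(1L, 2L)) {
    stop("sire_phase must be 1 or 2", call. = FALSE)
  }
  if (sire_phase == 2L) obs <- ifelse(is.na(obs), obs, 3L - obs)

  if (is.null(grid)) grid <- seq(pos[1L], pos[length(pos)], by = step)
  n <- nrow(obs)
  J <- length(pos)

  # Emission "probabilities": 1 when compatible with the observation.
  em1 <- ifelse(is.na(obs) | obs == 1L, 1, 0)  # state Q (homolog carrying Q)
  em2 <- ifelse(is.na(obs) | obs == 2L, 1, 0)
  cc <- if (J > 1L) haldane_c(diff(pos)) else numeric(0)

  # Forward/backward over markers, vectorized across animals; each pass keeps
  # per-step normalization so nothing underflows.
  a1 <- matrix(0, n, J); a2 <- matrix(0, n, J)
  a1[, 1L] <- 0.5 * em1[, 1L]; a2[, 1L] <- 0.5 * em2[, 1L]
  norm_pair <- function(x1, x2, where) {
    s <- x1 + x2
    if (any(s <= 0)) {
      bad <- which(s <= 0)[1L]
      stop(sprintf(
        "marker observations for animal '%s' have probability zero near %s",
        inherit$animal[bad], where), call. = FALSE)
    }
    list(x1 / s, x2 / s)
  }
  nz <- norm_pair(a1[, 1L], a2[, 1L], map_used$marker[1L])
  a1[, 1L] <- nz[[1L]]; a2[, 1L] <- nz[[2L]]
  if (J > 1L) {
    for (j in 2L:J) {
      c_j <- cc[j - 1L]
      f1 <- a1[, j - 1L] * (1 - c_j) + a2[, j - 1L] * c_j
      f2 <- a1[, j - 1L] * c_j + a2[, j - 1L] * (1 - c_j)
      nz <- norm_pair(em1[, j] * f1, em2[, j] * f2, map_used$marker[j])
      a1[, j] <- nz[[1L]]; a2[, j] <- nz[[2L]]
    }
  }
  b1 <- matrix(1, n, J); b2 <- matrix(1, n, J)
  if (J > 1L) {
    for (j in (J - 1L):1L) {
      c_j <- cc[j]
      g1 <- em1[, j + 1L] * b1[, j + 1L]
      g2 <- em2[, j + 1L] * b2[, j + 1L]
      h1 <- (1 - c_j) * g1 + c_j * g2
      h2 <- c_j * g1 + (1 - c_j) * g2
      s <- h1 + h2
      b1[, j] <- h1 / s; b2[, j] <- h2 / s
    }
  }

  pi_mat <- matrix(NA_real_, n, length(grid),
                   dimnames = list(inherit$animal, format_pos(grid)))
  for (gidx in seq_along(grid)) {
    x <- grid[gidx]
    if (x <= pos[1L]) {
      cx <- haldane_c(pos[1L] - x)
      g1 <- em1[, 1L] * b1[, 1L]; g2 <- em2[, 1L] * b2[, 1L]
      h1 <- (1 - cx) * g1 + cx * g2
      h2 <- cx * g1 + (1 - cx) * g2
    } else if (x >= pos[J]) {
      cx <- haldane_c(x - pos[J])
      h1 <- a1[, J] * (1 - cx) + a2[, J] * cx
      h2 <- a1[, J] * cx + a2[, J] * (1 - cx)
    } else {
      j <- findInterval(x, pos)
      cl <- haldane_c(x - pos[j]); cr <- haldane_c(pos[j + 1L] - x)
      left1 <- a1[, j] * (1 - cl) + a2[, j] * cl
      left2 <- a1[, j] * cl + a2[, j] * (1 - cl)
      g1 <- em1[, j + 1L] * b1[, j + 1L]
      g2 <- em2[, j + 1L] * b2[, j + 1L]
      right1 <- (1 - cr) * g1 + cr * g2
      right2 <- cr * g1 + (1 - cr) * g2
      h1 <- left1 * right1
      h2 <- left2 * right2
    }
    pi_mat[, gidx] <- h1 / (h1 + h2)
  }

  flagged <- flag_tight_recombinants(inherit$animal, obs, map_used, flag_cm)
  structure(
    list(grid = grid, pi = pi_mat, animals = inherit$animal,
         map = map_used, flagged = flagged, sire_phase = as.integer(sire_phase)),
    class = "transmission_profile"
  )
}

# A switch between adjacent informative markers closer than flag_cm is
# recorded (possible genotyping error; kept in the data regardless).
flag_tight_recombinants <- function(animals, obs, map_used, flag_cm) {
  out <- list()
  for (i in seq_len(nrow(obs))) {
    inf <- which(!is.na(obs[i, ]))
    if (length(inf) < 2L) next
    sw <- which(diff(obs[i, inf]) != 0L)
    for (s in sw) {
      d <- map_used$pos_cm[inf[s + 1L]] - map_used$pos_cm[inf[s]]
      if (d < flag_cm) {
        out[[length(out) + 1L]] <- tibble::tibble(
          animal = animals[i],
          left_marker = map_used$marker[inf[s]],
          right_marker = map_used$marker[inf[s + 1L]],
          d_cm = d
        )
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(animal = character(), left_marker = character(),
                   right_marker = character(), d_cm = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}

#' @export
print.transmission_profile <- function(x, ...) {
  cat("<transmission_profile>\n")
  cat(sprintf("  %d animals, grid %g..%g cM (%d positions), %d markers\n",
              length(x$animals), min(x$grid), max(x$grid), length(x$grid),
              nrow(x$map)))
  if (nrow(x$flagged) > 0) {
    cat(sprintf("  %d tight double-recombinant observation(s) flagged\n",
                nrow(x$flagged)))
  }
  invisible(x)
}

#' @describeIn transmission_probabilities Long-format view of a profile:
#'   one row per animal x position with the probability of having received
#'   the Q-carrying homolog.
#' @param x A `transmission_profile`.
#' @param ... Unused.
#' @export
tidy.transmission_profile <- function(x, ...) {
  tibble::tibble(
    animal = rep(x$animals, times = length(x$grid)),
    pos_cm = rep(x$grid, each = length(x$animals)),
    p_q = as.vector(x$pi)
  )
}

#' @export
autoplot.transmission_profile <- function(object, ...) {
  df <- tidy.transmission_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cm, y = .data$animal,
                                   fill = .data$p_q)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166ac",
                                  mid = "grey90", high = "#b2182b",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "position (cM)", y = NULL,
                  fill = "P(Q transmitted)") +
    ggplot2::theme_minimal()
}
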