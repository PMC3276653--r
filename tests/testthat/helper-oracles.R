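# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, closed form, permutation) kept separate from
# the package's own code paths.

# Posterior P(state 1 at position x) by brute-force enumeration of all 2^M
# origin vectors over the markers, for one animal.
brute_force_posterior <- function(obs, pos, x) {
  M <- length(pos)
  stopifnot(length(obs) == M)
  all_pos <- sort(unique(c(pos, x)))
  K <- length(all_pos)
  marker_idx <- match(pos, all_pos)
  x_idx <- match(x, all_pos)
  haldane <- function(d) (1 - exp(-2 * d / 100)) / 2
  states <- as.matrix(expand.grid(rep(list(c(1L, 2L)), K)))
  num1 <- 0; total <- 0
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    if (!all(is.na(obs) | obs == s[marker_idx])) next
    p <- 0.5
    if (K > 1) {
      for (j in 2:K) {
        cc <- haldane(all_pos[j] - all_pos[j - 1])
        p <- p * if (s[j] == s[j - 1]) 1 - cc else cc
      }
    }
    total <- total + p
    if (s[x_idx] == 1L) num1 <- num1 + p
  }
  num1 / total
}

# Step-up BH by explicit enumeration of every rank cutoff (lists <= 10).
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(ord == i)  # rank of element i
    adj[i] <- min(1, min(p[ord[k:m]] * m / (k:m)))
  }
  adj
}

# Two-way ANOVA with Type-II sums of squares for a 2x2 design, from scratch:
# each effect's SS is the RSS drop from adding that term to the model holding
# the other main effect (and for the interaction, both main effects).
anova2_typeII_oracle <- function(y, a, b) {
  rss <- function(form) sum(resid(lm(form))^2)
  r_ab <- rss(y ~ a + b)
  r_a <- rss(y ~ a)
  r_b <- rss(y ~ b)
  r_full <- rss(y ~ a * b)
  ss_a <- r_b - r_ab
  ss_b <- r_a - r_ab
  ss_ab <- r_ab - r_full
  df_res <- length(y) - 4
  ms_res <- r_full / df_res
  data.frame(
    term = c("a", "b", "a:b"),
    F = c(ss_a, ss_b, ss_ab) / ms_res,
    p = pf(c(ss_a, ss_b, ss_ab) / ms_res, 1, df_res, lower.tail = FALSE)
  )
}

# Principal angles (degrees) between the column spans of A and B.
principal_angles_deg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_i * sum_j / comb2(n)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "subtypeqtl", mustWork = TRUE)
}
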