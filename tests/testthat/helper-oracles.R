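# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: enumeration and closed forms only.

# Exact two-sided Mann-Whitney p by full enumeration of rank arrangements
# (no ties). The null distribution of U is symmetric about n1*n2/2.
oracle_mw_exact <- function(g1, g2) {
  n1 <- length(g1)
  all_vals <- c(g1, g2)
  r <- rank(all_vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(g2) / 2
  combs <- utils::combn(length(all_vals), n1)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher exact p for a 2x2 table: sum of hypergeometric
# probabilities not exceeding that of the observed table.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1L, ])
  n <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

# Exhaustive k-medoid search: the global optimum PAM approximates.
oracle_pam <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  best_m <- NULL
  for (m in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(d[, m, drop = FALSE], 1L, min))
    if (obj < best - 1e-12) {
      best <- obj
      best_m <- m
    }
  }
  list(medoids = best_m, objective = best)
}

# Two-group log-rank statistic from the O-E table accumulated at each
# distinct event time.
oracle_logrank_2g <- function(time, event, group) {
  group <- as.integer(factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1L]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d_tot <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & group == 1L)
    o_minus_e <- o_minus_e + d1 - d_tot * n1 / n_tot
    if (n_tot > 1L) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1L)
    }
  }
  o_minus_e^2 / v
}

# Euclidean distance matrix of 1-D points, with point labels as names.
dist1d <- function(x) {
  d <- as.matrix(stats::dist(matrix(x, ncol = 1L)))
  dimnames(d) <- list(as.character(seq_along(x)), as.character(seq_along(x)))
  d
}

# A small deterministic expression matrix with two planted blocks:
# genes 1..half up in group A / down in group B, the rest mirrored.
planted_expression <- function(n_genes = 10L, n_per_group = 8L, sep = 6,
                               seed = 42L) {
  withr::with_seed(seed, {
    n <- 2L * n_per_group
    labels <- rep(1:2, each = n_per_group)
    half <- n_genes %/% 2L
    signs <- c(rep(1, half), rep(-1, n_genes - half))
    delta <- outer(signs, ifelse(labels == 1L, 1, -1)) * sep / 2
    m <- 2^(matrix(rnorm(n_genes * n, 6, 1), n_genes, n) + delta)
    dimnames(m) <- list(sprintf("G%02d", seq_len(n_genes)),
                        sprintf("S%02d", seq_len(n)))
    list(expr = m, labels = stats::setNames(labels, colnames(m)))
  })
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
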