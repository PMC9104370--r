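test_that("rank transform ranks genes across samples with average ties", {
  m <- rbind(G1 = c(5, 1, 3), G2 = c(2, 2, 7), G3 = c(4, 4, 4))
  colnames(m) <- c("s1", "s2", "s3")
  r <- rank_transform(m)
  expect_equal(unname(r["G1", ]), c(3, 1, 2))
  expect_equal(unname(r["G2", ]), c(1.5, 1.5, 3))
  expect_equal(unname(r["G3", ]), c(2, 2, 2))
  expect_equal(attr(r, "zero_variance"), "G3")
})

test_that("log transform is log2(x + pseudocount) and rejects negatives", {
  m <- matrix(c(0, 7, 0, 0), 2, 2)
  expect_equal(log_transform(m, 1)[1, 1], 0)
  expect_equal(log_transform(m, 1)[2, 1], 3)
  expect_equal(log_transform(matrix(0, 2, 2), 1),
               matrix(0, 2, 2))
  expect_error(log_transform(matrix(-1, 1, 1), 1), "negative")
})

test_that("Spearman distance matches hand-computed rank correlations", {
  # columns: s1 increasing, s2 swapped pairs, s3 reversed
  m <- cbind(s1 = c(1, 2, 3, 4), s2 = c(2, 1, 4, 3), s3 = c(4, 3, 2, 1))
  rownames(m) <- paste0("G", 1:4)
  d <- spearman_distance(m)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["s1", "s2"], 1 - 0.6)   # rho = cov/var of the rank vectors
  expect_equal(d["s1", "s3"], 2)         # exactly reversed ranks
  expect_equal(d["s2", "s3"], 1 + 0.6)
  expect_equal(d, t(d))

  ident <- cbind(s1 = c(1, 5, 2), s2 = c(10, 50, 20))
  rownames(ident) <- paste0("G", 1:3)
  expect_equal(spearman_distance(ident)["s1", "s2"], 0)
})

test_that("Spearman distance flags unusable gene sets and bad samples", {
  m <- rbind(G1 = c(1, 1, 1), G2 = c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  expect_error(spearman_distance(m), class = "metaboclust_unusable")
  flat <- rbind(G1 = c(1, 2, 3), G2 = c(5, 2, 6), G3 = c(9, 2, 4))
  colnames(flat) <- c("sA", "sBAD", "sC")
  expect_error(spearman_distance(flat), "sBAD")
})

test_that("Duda-Hart separates far blobs and rejects degenerate input", {
  withr::with_seed(1, {
    pts <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                 matrix(rnorm(40, 100, 0.1), 20, 2))
    split <- rep(1:2, each = 20)
    dh <- duda_hart_test(pts, split)
    expect_lt(dh$statistic, 0.01)
    expect_lt(dh$p_value, 1e-6)
    # the statistic matches the explicit sum-of-squares ratio
    je1 <- sum(sweep(pts, 2, colMeans(pts))^2)
    je2 <- sum(sweep(pts[1:20, ], 2, colMeans(pts[1:20, ]))^2) +
      sum(sweep(pts[21:40, ], 2, colMeans(pts[21:40, ]))^2)
    expect_equal(dh$statistic, je2 / je1)
  })
  expect_error(duda_hart_test(matrix(1, 5, 3), rep(1:2, c(2, 3))),
               "identical")
  expect_error(duda_hart_test(matrix(rnorm(15), 5, 3), rep(1, 5)),
               "two non-empty parts")
})

test_that("PAM recovers the brute-force optimum on the 1-D blob example", {
  x <- c(0, 1, 2, 10, 11, 12)
  d <- dist1d(x)
  fit <- pam_cluster(d, 2)
  expect_equal(fit$medoids, c("2", "5"))   # points 1 and 11
  expect_equal(unname(fit$assignments), c(1, 1, 1, 2, 2, 2))
  opt <- oracle_pam(d, 2)
  expect_equal(fit$objective, opt$objective)

  # k = n - 1: only the closest pair shares a cluster
  y <- c(0, 3, 7, 7.5, 20)
  dy <- dist1d(y)
  fit2 <- pam_cluster(dy, 4)
  expect_equal(fit2$objective, min(dy[upper.tri(dy)]))
  expect_equal(length(unique(fit2$assignments)), 4L)
})

test_that("PAM is deterministic and breaks duplicate-point ties by index", {
  x <- c(0, 0, 0, 5, 5, 5)
  d <- dist1d(x)
  fit1 <- pam_cluster(d, 2)
  fit2 <- pam_cluster(d, 2)
  expect_identical(fit1, fit2)
  expect_equal(fit1$medoids, c("1", "4"))  # lowest index among duplicates
  expect_true(all(tabulate(fit1$assignments) > 0))
})

test_that("PAM agrees with the independent reference on separated data", {
  withr::with_seed(7, {
    x <- c(rnorm(10, 0), rnorm(10, 30), rnorm(10, 60))
    d <- dist1d(x)
    fit <- pam_cluster(d, 3)
    ref <- cluster::pam(stats::as.dist(d), 3)
    obj <- function(m) sum(apply(d[, m, drop = FALSE], 1L, min))
    expect_equal(fit$objective, obj(ref$id.med))
    expect_equal(nmi(fit$assignments,
                     stats::setNames(ref$clustering, names(fit$assignments))),
                 1)
  })
})

test_that("silhouette widths match the hand formula and conventions", {
  d <- dist1d(c(0, 0.1, 10, 10.1))
  s <- silhouette_width(d, c(1, 1, 2, 2))
  exp_outer <- (10.05 - 0.1) / 10.05    # points 0 and 10.1
  exp_inner <- (9.95 - 0.1) / 9.95      # points 0.1 and 10
  expect_equal(unname(s$per_sample),
               c(exp_outer, exp_inner, exp_inner, exp_outer))
  expect_equal(s$average, mean(c(exp_outer, exp_inner)))

  # degenerate conventions: identical points and singleton clusters -> 0
  d0 <- matrix(0, 4, 4)
  expect_equal(silhouette_width(d0, c(1, 1, 2, 2))$average, 0)
  d2 <- dist1d(c(0, 5))
  expect_equal(silhouette_width(d2, c(1, 2))$average, 0)

  ref <- cluster::silhouette(c(1, 1, 2, 2), stats::as.dist(d))
  expect_equal(unname(s$per_sample), unname(ref[, "sil_width"]))
})

test_that("silhouette values stay in [-1, 1] on random partitions", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(6:15, 1)
      d <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
      cl <- sample(1:3, n, replace = TRUE)
      if (length(unique(cl)) < 2) next
      s <- silhouette_width(d, cl)
      expect_true(all(s$per_sample >= -1 & s$per_sample <= 1))
      expect_true(s$average >= -1 && s$average <= 1)
    }
  })
})

test_that("select_k picks the planted number of blobs, ties toward 2", {
  withr::with_seed(3, {
    x3 <- c(rnorm(10, 0, 0.3), rnorm(10, 50, 0.3), rnorm(10, 100, 0.3))
    expect_equal(select_k(dist1d(x3))$k, 3L)
    x2 <- c(rnorm(10, 0, 0.3), rnorm(10, 50, 0.3))
    expect_equal(select_k(dist1d(x2))$k, 2L)
  })
  # equidistant points: every k has ASW = 0, tie resolves to k = 2
  d <- matrix(1, 5, 5) - diag(5)
  dimnames(d) <- list(1:5, 1:5)
  expect_equal(select_k(d)$k, 2L)
  expect_error(select_k(dist1d(c(0, 1))), "at least 3")
})

test_that("NMI matches direct entropy arithmetic and its conventions", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)  # zero entropy -> 0
  # joint counts (2,0 / 1,1): hand-computed mutual information
  mi <- 1 / 2 * log((1 / 2) / (3 / 8)) + 1 / 4 * log((1 / 4) / (3 / 8)) +
    1 / 4 * log((1 / 4) / (1 / 8))
  hb <- -(3 / 4 * log(3 / 4) + 1 / 4 * log(1 / 4))
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 1, 2)), mi / sqrt(log(2) * hb))
})

test_that("NMI is symmetric and invariant to label permutations", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      a <- sample(1:3, 30, replace = TRUE)
      b <- sample(1:4, 30, replace = TRUE)
      expect_equal(nmi(a, b), nmi(b, a))
      perm <- sample(4)
      expect_equal(nmi(a, perm[b]), nmi(a, b))
      if (length(unique(a)) >= 2) expect_equal(nmi(a, a), 1)
    }
  })
  expect_error(nmi(stats::setNames(1:2, c("a", "b")),
                   stats::setNames(1:2, c("a", "c"))), "sample")
})

test_that("differential genes are ranked by Kruskal-Wallis p-value", {
  pe <- planted_expression(n_genes = 8, n_per_group = 10)
  res <- differential_genes(pe$expr, pe$labels, top_n = 20)
  expect_equal(nrow(res), 8L)  # top_n larger than gene count: all returned
  # perfect 10 vs 10 separation: closed-form KW statistic and p
  h <- 12 / (20 * 21) * (10 * (5.5 - 10.5)^2 + 10 * (15.5 - 10.5)^2)
  expect_equal(res$statistic[1], h)
  expect_equal(res$p_value[1], stats::pchisq(h, 1, lower.tail = FALSE))

  m <- rbind(FLAT = rep(1, 20), pe$expr)
  res2 <- differential_genes(m, pe$labels, top_n = 9)
  expect_equal(res2$p_value[res2$gene == "FLAT"], 1)
})

test_that("the full pair procedure recovers planted labels and gates nulls", {
  pe <- planted_expression(n_genes = 12, n_per_group = 12, sep = 6)
  sol <- cluster_gene_set(pe$expr, rownames(pe$expr), gene_set = "SET",
                          tumor_type = "T")
  expect_true(sol$passed_gate)
  expect_equal(sol$k, 2L)
  expect_equal(nmi(sol$assignments, pe$labels), 1)
  expect_true(all(sol$medoids %in% names(sol$assignments)))
  g <- glance(sol)
  expect_equal(g$k, 2L)
  td <- tidy(sol)
  expect_equal(nrow(td), 24L)

  # an i.i.d. matrix carries no structure: gated out at alpha = 0.001
  withr::with_seed(8, {
    noise <- matrix(2^rnorm(12 * 40, 6, 1), 12, 40,
                    dimnames = list(rownames(pe$expr),
                                    sprintf("N%02d", 1:40)))
    nul <- cluster_gene_set(noise, rownames(noise))
    expect_false(nul$passed_gate)
    expect_equal(nul$reason, "gated_out")
  })

  # one usable gene only: unusable, distinct from gated out
  un <- cluster_gene_set(pe$expr, "G01")
  expect_false(un$passed_gate)
  expect_equal(un$reason, "unusable")
})

test_that("clustering a pair twice gives byte-identical results", {
  pe <- planted_expression()
  s1 <- cluster_gene_set(pe$expr, rownames(pe$expr))
  s2 <- cluster_gene_set(pe$expr, rownames(pe$expr))
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})
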