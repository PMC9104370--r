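named <- function(x, n = length(x)) stats::setNames(x, paste0("s", seq_len(n)))

test_that("continuous tests: exact Mann-Whitney matches enumeration", {
  cl <- named(c(1, 1, 2, 2))
  res <- test_continuous(named(c(1, 2, 3, 4)), cl)
  expect_equal(res$test, "mann_whitney")
  expect_equal(res$p_value, 1 / 3)  # 2 of 6 rank arrangements as extreme
  expect_true(res$valid)

  withr::with_seed(10, {
    for (rep in 1:10) {
      n1 <- sample(3:6, 1)
      n2 <- sample(3:6, 1)
      vals <- sample(100, n1 + n2)   # distinct: no ties
      cl2 <- stats::setNames(rep(1:2, c(n1, n2)),
                             paste0("s", seq_len(n1 + n2)))
      res <- test_continuous(stats::setNames(vals, names(cl2)), cl2)
      expect_equal(res$p_value,
                   oracle_mw_exact(vals[seq_len(n1)], vals[-seq_len(n1)]))
    }
  })
})

test_that("continuous tests: constants, missing clusters, k > 2 dispatch", {
  cl <- named(c(1, 1, 2, 2))
  expect_equal(test_continuous(named(rep(7, 4)), cl)$p_value, 1)
  res <- test_continuous(named(c(1, 2, NA, NA)), cl)
  expect_false(res$valid)
  expect_equal(res$reason, "cluster_without_values")
  cl3 <- named(c(1, 1, 2, 2, 3, 3))
  res3 <- test_continuous(named(c(5, 3, 8, 9, 1, 2), 6), cl3)
  expect_equal(res3$test, "kruskal_wallis")
  kw <- stats::kruskal.test(c(5, 3, 8, 9, 1, 2), factor(rep(1:3, each = 2)))
  expect_equal(res3$p_value, kw$p.value)
})

test_that("categorical tests: Fisher matches hypergeometric enumeration", {
  labels <- named(rep(c("x", "y"), c(4, 4)), 8)
  cl <- named(c(1, 1, 1, 2, 1, 2, 2, 2), 8)  # table [[3,1],[1,3]]
  res <- test_categorical(labels, cl, min_expected = 0)
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$p_value, 34 / 70)
  expect_equal(res$p_value,
               oracle_fisher_2x2(matrix(c(3, 1, 1, 3), 2)))

  balanced <- test_categorical(
    named(rep(c("x", "y", "x", "y"), each = 5), 20),
    named(rep(c(1, 1, 2, 2), each = 5), 20), min_expected = 0)
  expect_equal(balanced$p_value, 1)  # perfect independence
})

test_that("categorical tests: level removal, chi-square routing, validity", {
  # 3 levels; 'rare' has expected counts ~1 in each cluster: removed, and
  # the remaining 2x2 goes to Fisher
  labels <- named(c(rep("a", 20), rep("b", 20), rep("rare", 2)), 42)
  cl <- named(c(rep(1, 12), rep(2, 8), rep(1, 6), rep(2, 14), 1, 2), 42)
  res <- test_categorical(labels, cl)
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$n_used, 40L)
  expect_equal(res$p_value,
               oracle_fisher_2x2(matrix(c(12, 6, 8, 14), 2, byrow = TRUE)))

  # large 3x2 table: Pearson chi-square without continuity correction
  labels3 <- named(rep(c("a", "b", "c"), each = 20), 60)
  cl3 <- named(rep(rep(1:2, c(12, 8)), 3), 60)
  res3 <- test_categorical(labels3, cl3)
  expect_equal(res3$test, "chi_square")
  ref <- stats::chisq.test(table(labels3, cl3), correct = FALSE)
  expect_equal(res3$p_value, ref$p.value)

  # all levels removed but one: invalid
  one <- test_categorical(named(c("a", "a", "a", "b"), 4),
                          named(c(1, 2, 1, 2), 4))
  expect_false(one$valid)
})

test_that("log-rank matches the O-E oracle and applies the validity rule", {
  time <- named(c(1, 2, 3, 1, 2, 4), 6)
  event <- named(c(0, 1, 1, 1, 1, 1), 6)
  cl <- named(c(1, 1, 1, 2, 2, 2), 6)
  res <- test_survival(time, event, cl)
  expect_equal(res$test, "log_rank")
  expect_equal(res$statistic,
               oracle_logrank_2g(unname(time), unname(event), unname(cl)))
  expect_false(res$valid)  # tiny groups: expected events below 5
  expect_equal(res$reason, "expected_events_below_minimum")

  flipped <- test_survival(time, event, named(c(2, 2, 2, 1, 1, 1), 6))
  expect_equal(flipped$statistic, res$statistic)

  # identical survival experience: statistic 0, p 1
  t2 <- named(c(1, 2, 3, 1, 2, 3), 6)
  e2 <- named(c(1, 1, 0, 1, 1, 0), 6)
  same <- test_survival(t2, e2, cl)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  none <- test_survival(t2, named(rep(0, 6), 6), cl)
  expect_false(none$valid)
  expect_equal(none$reason, "no_events")
  expect_error(test_survival(named(c(-1, 1, 1, 1, 1, 1), 6), event, cl),
               "positive")
})

test_that("log-rank validity reflects survdiff expected events at scale", {
  withr::with_seed(21, {
    n <- 120
    cl <- stats::setNames(rep(1:2, each = n / 2), paste0("s", 1:n))
    time <- stats::setNames(rexp(n, rate = ifelse(cl == 1, 1, 3) / 100),
                            names(cl))
    event <- stats::setNames(rep(1L, n), names(cl))
    res <- test_survival(time, event, cl)
    expect_true(res$valid)
    expect_equal(sum(res$expected_events), sum(event))
    expect_lt(res$p_value, 0.001)
  })
})

test_that("Bonferroni families count valid tests per class", {
  mk <- function(class, p, valid = TRUE, n = 1) {
    tibble::tibble(tumor_type = "T", gene_set = "S", collection = "c",
                   variable_class = class,
                   feature = paste0(class, "_f", seq_len(n)),
                   test = "t", statistic = 1,
                   p_value = ifelse(valid, p, NA_real_), valid = valid,
                   reason = NA_character_, n_used = 10L)
  }
  res <- dplyr::bind_rows(
    mk("mirna", 4e-5, n = 1),
    mk("mirna", 0.5, n = 999)[-1, ] |>
      dplyr::mutate(feature = paste0("null", 1:998)),
    mk("clinical", 0.01, n = 1))
  corr <- bonferroni_families(res, alpha = 0.05)
  fam <- corr$families
  expect_equal(fam$m[fam$variable_class == "mirna"], 999L)
  hit <- corr$results[corr$results$p_value == 4e-5 &
                        !is.na(corr$results$p_value), ]
  expect_true(hit$significant)      # threshold 0.05/999 > 4e-5
  expect_equal(hit$m_family, 999L)
  clin <- corr$results[corr$results$variable_class == "clinical", ]
  expect_true(clin$significant)     # own family of size 1

  # with 2000 tests in the family the same p is no longer significant
  res2 <- dplyr::bind_rows(res, mk("mirna", 0.5, n = 1001)[-1, ] |>
                             dplyr::mutate(feature = paste0("x", 1:1000)))
  corr2 <- bonferroni_families(res2)
  hit2 <- corr2$results[corr2$results$p_value == 4e-5 &
                          !is.na(corr2$results$p_value), ]
  expect_false(hit2$significant)

  # invalid tests never enter m unless explicitly requested
  res3 <- dplyr::bind_rows(mk("mirna", 0.02, n = 2),
                           mk("mirna", NA, valid = FALSE, n = 3) |>
                             dplyr::mutate(feature = paste0("i", 1:3)))
  expect_equal(bonferroni_families(res3)$families$m, 2L)
  expect_equal(bonferroni_families(res3, count_invalid = TRUE)$families$m,
               5L)
})

test_that("lowering alpha never increases the significant count", {
  withr::with_seed(31, {
    res <- tibble::tibble(
      tumor_type = "T", gene_set = "S", collection = "c",
      variable_class = sample(c("mirna", "clinical"), 50, replace = TRUE),
      feature = paste0("f", 1:50), test = "t", statistic = 1,
      p_value = runif(50)^2, valid = TRUE, reason = NA_character_,
      n_used = 10L)
    counts <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a) {
      sum(bonferroni_families(res, alpha = a)$results$significant)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("recurrence requires >1 non-composite tumor type", {
  mk <- function(tumor, sig = TRUE) {
    tibble::tibble(tumor_type = tumor, gene_set = "S",
                   variable_class = "mirna", feature = "MIR1",
                   significant = sig)
  }
  rec <- find_recurrent(dplyr::bind_rows(mk("BRCA"), mk("LUAD")))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_tumor_types, 2L)
  expect_equal(rec$tumor_types, "BRCA;LUAD")

  # LUNG is a union cohort: LUAD + LUNG alone is not recurrence
  rec2 <- find_recurrent(dplyr::bind_rows(mk("LUAD"), mk("LUNG")))
  expect_equal(nrow(rec2), 0L)

  rec3 <- find_recurrent(dplyr::bind_rows(mk("BRCA", sig = FALSE)))
  expect_equal(nrow(rec3), 0L)
})

test_that("feature dispatch routes classes to the right tests", {
  withr::with_seed(41, {
    n <- 60
    cl <- stats::setNames(rep(1:2, each = n / 2), paste0("s", 1:n))
    feats <- dplyr::bind_rows(
      metaboclust:::feature_continuous("mirna", "MIR1", names(cl), rnorm(n)),
      metaboclust:::feature_categorical("gene_mutation", "TP53", names(cl),
                                        sample(c("mut", "wt"), n, TRUE)),
      metaboclust:::feature_categorical("point_mutation", "TP53_p.R175H",
                                        names(cl),
                                        c("mut", rep("wt", n - 1))),
      metaboclust:::feature_survival("overall_survival", "OS", names(cl),
                                     rexp(n, 0.01), rbinom(n, 1, 0.7)))
    res <- associate_features(feats, cl, tumor_type = "T", gene_set = "S")
    expect_equal(nrow(res), 4L)
    by_class <- stats::setNames(res$test, res$variable_class)
    expect_equal(unname(by_class["mirna"]), "mann_whitney")
    expect_equal(unname(by_class["overall_survival"]), "log_rank")
    pm <- res[res$variable_class == "point_mutation", ]
    expect_false(pm$valid)  # a single mutated sample is untestable
    expect_equal(pm$reason, "too_few_mutated_samples")
  })
})
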