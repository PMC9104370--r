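association_row <- function(tumor_type, gene_set, collection,
                            variable_class, feature, test, statistic,
                            p_value, valid, reason, n_used) {
  tibble::tibble(tumor_type = tumor_type, gene_set = gene_set,
                 collection = collection, variable_class = variable_class,
                 feature = feature, test = test, statistic = statistic,
                 p_value = p_value, valid = valid, reason = reason,
                 n_used = as.integer(n_used))
}

invalid_result <- function(test, reason, n_used = 0L) {
  list(test = test, statistic = NA_real_, p_value = NA_real_,
       valid = FALSE, reason = reason, n_used = n_used)
}

#' Association test for a continuous feature
#'
#' Mann-Whitney U test for two subtypes (exact enumeration when both
#' groups have at most 8 samples and there are no ties, otherwise the
#' normal approximation with tie correction); Kruskal-Wallis with tie
#' correction for more than two subtypes. Samples missing the feature are
#' dropped pairwise; a subtype left without any value makes the test
#' invalid.
#'
#' @param values Named numeric vector (names = sample IDs) or plain vector
#'   aligned with `assignments`.
#' @param assignments Cluster labels (named integer vector).
#' @return List with `test`, `statistic`, `p_value`, `valid`, `reason`,
#'   `n_used`.
#' @export
test_continuous <- function(values, assignments) {
  if (!is.null(names(values))) {
    common <- intersect(names(values), names(assignments))
    values <- values[common]
    assignments <- assignments[common]
  }
  ok <- !is.na(values)
  values <- values[ok]
  cl <- factor(assignments[ok])
  k_all <- length(unique(assignments))
  test <- if (k_all == 2L) "mann_whitney" else "kruskal_wallis"
  if (nlevels(droplevels(cl)) < k_all || k_all < 2L) {
    return(invalid_result(test, "cluster_without_values", sum(ok)))
  }
  cl <- droplevels(cl)
  if (max(values) == min(values)) {
    # identical value in every sample: no discrimination possible
    return(list(test = test, statistic = 0, p_value = 1, valid = TRUE,
                reason = NA_character_, n_used = length(values)))
  }
  if (k_all == 2L) {
    g1 <- values[cl == levels(cl)[1L]]
    g2 <- values[cl == levels(cl)[2L]]
    exact <- length(g1) <= 8L && length(g2) <= 8L &&
      !any(duplicated(values))
    wt <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = exact, correct = FALSE))
    list(test = test, statistic = unname(wt$statistic),
         p_value = min(wt$p.value, 1), valid = TRUE, reason = NA_character_,
         n_used = length(values))
  } else {
    kw <- stats::kruskal.test(values, cl)
    list(test = test, statistic = unname(kw$statistic),
         p_value = kw$p.value, valid = TRUE, reason = NA_character_,
         n_used = length(values))
  }
}

#' Association test for a categorical feature
#'
#' Builds the levels-by-subtypes contingency table, then iteratively
#' removes the feature level with the smallest expected count while any
#' expected cell is below `min_expected` (expectations recomputed after
#' each removal). If fewer than two levels remain, the test is invalid.
#' A 2x2 table (possibly after removal) is tested with Fisher's exact test
#' (two-sided, sum of tables at most as probable as the observed one);
#' larger tables use Pearson's chi-square without continuity correction.
#'
#' @param labels Named character vector of category labels per sample.
#' @param assignments Cluster labels (named integer vector).
#' @param min_expected Expected-count threshold for level removal
#'   (default 5).
#' @return List as in [test_continuous()].
#' @export
test_categorical <- function(labels, assignments, min_expected = 5) {
  if (!is.null(names(labels))) {
    common <- intersect(names(labels), names(assignments))
    labels <- labels[common]
    assignments <- assignments[common]
  }
  ok <- !is.na(labels)
  labels <- as.character(labels[ok])
  cl <- assignments[ok]
  if (length(unique(labels)) < 2L) {
    return(invalid_result("fisher_exact", "fewer_than_2_levels",
                          length(labels)))
  }
  tab <- table(labels, cl)
  repeat {
    if (nrow(tab) < 2L) {
      return(invalid_result("fisher_exact", "fewer_than_2_levels_after_removal",
                            sum(tab)))
    }
    if (any(colSums(tab) == 0L)) {
      return(invalid_result("fisher_exact", "empty_cluster", sum(tab)))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    row_min <- apply(expected, 1L, min)
    if (all(row_min >= min_expected)) break
    tab <- tab[-which.min(row_min), , drop = FALSE]
  }
  n_used <- sum(tab)
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- stats::fisher.test(tab)
    list(test = "fisher_exact", statistic = unname(ft$estimate),
         p_value = ft$p.value, valid = TRUE, reason = NA_character_,
         n_used = n_used)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "chi_square", statistic = unname(ct$statistic),
         p_value = ct$p.value, valid = TRUE, reason = NA_character_,
         n_used = n_used)
  }
}

#' Association test for a survival endpoint
#'
#' Log-rank test of the survival curves across subtypes (chi-square with
#' k-1 degrees of freedom). The result is valid only when the expected
#' number of events in every subtype is at least `min_expected_events`;
#' with fewer expected events the test statistic is unstable and the
#' result is flagged invalid regardless of its p-value.
#'
#' @param time Named vector of positive survival times.
#' @param event Event indicators (0 = censored, 1 = event), aligned with
#'   `time`.
#' @param assignments Cluster labels (named integer vector).
#' @param min_expected_events Validity threshold (default 5).
#' @return List as in [test_continuous()], plus `expected_events`.
#' @export
test_survival <- function(time, event, assignments,
                          min_expected_events = 5) {
  if (!is.null(names(time))) {
    common <- intersect(names(time), names(assignments))
    time <- time[common]
    event <- event[common]
    assignments <- assignments[common]
  }
  ok <- !is.na(time) & !is.na(event)
  time <- time[ok]
  event <- as.integer(event[ok])
  cl <- factor(assignments[ok])
  if (any(time <= 0)) stop("test_survival: times must be positive")
  if (!all(event %in% c(0L, 1L))) {
    stop("test_survival: events must be 0 or 1")
  }
  if (nlevels(droplevels(cl)) < 2L) {
    return(invalid_result("log_rank", "fewer_than_2_groups", length(time)))
  }
  cl <- droplevels(cl)
  if (sum(event) == 0L) {
    res <- invalid_result("log_rank", "no_events", length(time))
    res$expected_events <- stats::setNames(rep(0, nlevels(cl)), levels(cl))
    return(res)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ cl)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  expected <- sd$exp
  valid <- min(expected) >= min_expected_events
  list(test = "log_rank", statistic = unname(sd$chisq), p_value = p,
       valid = valid,
       reason = if (valid) NA_character_ else "expected_events_below_minimum",
       n_used = length(time),
       expected_events = stats::setNames(as.numeric(expected), levels(cl)))
}

#' Test every feature of a feature table against one subtype partition
#'
#' Dispatches each feature to the test appropriate for its type
#' (continuous, categorical or survival) and collects the results in a
#' tidy table. Point-mutation features with fewer than
#' `min_mutated_samples` mutated samples overall are skipped as
#' untestable (degenerate Fisher margins).
#'
#' @param features Long feature tibble (see [load_clinical()] and
#'   friends).
#' @param subtypes A `metab_subtypes` object that passed the gate, or a
#'   named assignment vector.
#' @param tumor_type,gene_set,collection Labels for the result rows
#'   (taken from `subtypes` when it is a `metab_subtypes` object).
#' @param min_expected Expected-count threshold for categorical tests.
#' @param min_expected_events Expected-event threshold for log-rank
#'   validity.
#' @param min_mutated_samples Minimum mutated samples for point-mutation
#'   features (default 3).
#' @return Tibble of association results, one row per feature, columns
#'   `tumor_type`, `gene_set`, `collection`, `variable_class`, `feature`,
#'   `test`, `statistic`, `p_value`, `valid`, `reason`, `n_used`.
#' @export
associate_features <- function(features, subtypes,
                               tumor_type = "cohort",
                               gene_set = "gene_set",
                               collection = "user",
                               min_expected = 5,
                               min_expected_events = 5,
                               min_mutated_samples = 3L) {
  if (inherits(subtypes, "metab_subtypes")) {
    if (!isTRUE(subtypes$passed_gate)) {
      stop("subtypes did not pass the cluster-structure gate")
    }
    tumor_type <- subtypes$tumor_type
    gene_set <- subtypes$gene_set
    assignments <- subtypes$assignments
  } else {
    assignments <- subtypes
  }
  feats <- dplyr::group_split(
    dplyr::group_by(features, .data$variable_class, .data$feature))
  rows <- purrr::map(feats, function(f) {
    cls <- f$variable_class[1L]
    nm <- f$feature[1L]
    if (cls %in% c("overall_survival", "recurrence_free_survival")) {
      res <- test_survival(stats::setNames(f$time, f$sample),
                           stats::setNames(f$event, f$sample),
                           assignments,
                           min_expected_events = min_expected_events)
    } else if (!all(is.na(f$level))) {
      if (cls == "point_mutation" &&
          sum(f$level == "mut", na.rm = TRUE) < min_mutated_samples) {
        res <- invalid_result("fisher_exact", "too_few_mutated_samples",
                              sum(!is.na(f$level)))
      } else {
        res <- test_categorical(stats::setNames(f$level, f$sample),
                                assignments, min_expected = min_expected)
      }
    } else {
      res <- test_continuous(stats::setNames(f$value, f$sample),
                             assignments)
    }
    association_row(tumor_type, gene_set, collection, cls, nm, res$test,
                    res$statistic, res$p_value, res$valid, res$reason,
                    res$n_used)
  })
  dplyr::bind_rows(rows)
}

#' Per-class Bonferroni correction across tumor types
#'
#' Groups all association results into one correction family per variable
#' class (pooling tumor types and gene sets), sets the family size `m` to
#' the number of valid tests in the class, and flags results with
#' `p_value < alpha / m` as significant. Classes hold very different
#' numbers of variables (hundreds of miRNAs versus a single overall
#' survival endpoint), so a single overall correction would unduly
#' penalize the small classes.
#'
#' @param results Association tibble from [associate_features()]
#'   (typically row-bound over tumors and gene sets).
#' @param alpha Family-wise error level (default 0.05).
#' @param count_invalid Count invalid (p-value-less) tests in `m` as well
#'   (default `FALSE`: a test that produced no p-value never entered the
#'   family).
#' @return List with `results` (input plus `m_family`, `threshold`,
#'   `significant`, rows ordered by class, tumor, gene set, feature) and
#'   `families` (per-class summary tibble).
#' @export
bonferroni_families <- function(results, alpha = 0.05,
                                count_invalid = FALSE) {
  fam <- dplyr::summarise(
    dplyr::group_by(results, .data$variable_class),
    m = if (count_invalid) dplyr::n() else sum(.data$valid),
    .groups = "drop")
  fam$alpha <- alpha
  fam$threshold <- ifelse(fam$m > 0, alpha / fam$m, NA_real_)
  out <- dplyr::left_join(results,
                          fam[, c("variable_class", "m", "threshold")],
                          by = "variable_class")
  out <- dplyr::rename(out, m_family = "m")
  out$significant <- out$valid & !is.na(out$p_value) &
    out$p_value < out$threshold
  out <- dplyr::arrange(out, .data$variable_class, .data$tumor_type,
                        .data$gene_set, .data$feature)
  list(results = out, families = fam)
}

#' Recurrent associations across tumor types
#'
#' A (gene set, variable class, feature) association is recurrent when it
#' is significant in more than one tumor type, not counting tumor types
#' that are unions of narrower ones (e.g. LUNG = LUAD + LUSC), whose
#' significance would double-count their constituents.
#'
#' @param results Corrected association tibble (with `significant`).
#' @param composite_types Tumor types excluded from recurrence counting.
#'   The default covers the usual composite cohorts; adjust to your cohort
#'   naming.
#' @return Tibble with `gene_set`, `variable_class`, `feature`,
#'   `n_tumor_types`, `tumor_types` (semicolon-joined), sorted by
#'   descending recurrence then name.
#' @export
find_recurrent <- function(results,
                           composite_types = c("LUNG", "KIPAN", "GBMLGG",
                                               "COADREAD", "STES")) {
  sig <- dplyr::filter(results, .data$significant,
                       !(.data$tumor_type %in% composite_types))
  rec <- dplyr::summarise(
    dplyr::group_by(sig, .data$gene_set, .data$variable_class,
                    .data$feature),
    n_tumor_types = dplyr::n_distinct(.data$tumor_type),
    tumor_types = paste(sort(unique(.data$tumor_type)), collapse = ";"),
    .groups = "drop")
  rec <- dplyr::filter(rec, .data$n_tumor_types >= 2L)
  dplyr::arrange(rec, dplyr::desc(.data$n_tumor_types), .data$gene_set,
                 .data$variable_class, .data$feature)
}

#' Significance overview per variable class
#'
#' @param corrected Output of [bonferroni_families()].
#' @return ggplot of -log10 p-values by variable class with the per-class
#'   Bonferroni threshold marked.
#' @export
plot_association_overview <- function(corrected) {
  res <- corrected$results
  res <- dplyr::filter(res, .data$valid)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$variable_class,
                                    y = -log10(.data$p_value),
                                    color = .data$significant)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.6) +
    ggplot2::geom_point(
      data = dplyr::mutate(corrected$families,
                           y = -log10(.data$threshold)),
      ggplot2::aes(x = .data$variable_class, y = .data$y),
      inherit.aes = FALSE, shape = 95, size = 8) +
    ggplot2::labs(x = "variable class", y = "-log10 p",
                  color = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
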