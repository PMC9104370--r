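#' Derive the full per-sample feature table of a cohort
#'
#' Runs every feature derivation on a cohort bundle (in-memory
#' `synthetic_cohort` or the list returned by [read_cohort()]): SGOL
#' copy-number region scores, global methylation, tie-randomized miRNA
#' ranks, gene- and point-mutation calls, RPPA pass-through (if present)
#' and the clinical / survival classes.
#'
#' @param cohort Cohort bundle with slots `expression`, `mirna`,
#'   `methylation`, `seg`, `gene_coords`, `regions`, `calls`, `clinical`
#'   (and optionally `rppa`).
#' @param seed Seed for the miRNA tie randomization.
#' @param sgol_mode Passed to [region_sgol_scores()].
#' @return Long feature tibble covering all available variable classes.
#' @export
derive_all_features <- function(cohort, seed = 1L,
                                sgol_mode = "per_sample") {
  samples <- colnames(cohort$expression)
  out <- list()
  if (!is.null(cohort$seg)) {
    gene_cn <- suppressWarnings(
      gene_level_copy_number(cohort$seg, cohort$gene_coords))
    out$cn <- region_sgol_scores(gene_cn, cohort$regions, mode = sgol_mode)
  }
  if (!is.null(cohort$methylation)) {
    out$meth <- global_methylation(cohort$methylation)
  }
  if (!is.null(cohort$mirna)) {
    out$mirna <- mirna_rank_feature(cohort$mirna, seed = seed)
  }
  if (!is.null(cohort$calls)) {
    out$mut <- gene_level_mutation_matrix(cohort$calls, samples)
  }
  if (!is.null(cohort$rppa)) {
    out$rppa <- matrix_features(cohort$rppa, "protein_rppa")
  }
  if (!is.null(cohort$clinical)) {
    out$clin <- load_clinical(cohort$clinical)
  }
  dplyr::bind_rows(out)
}

#' Pairwise NMI between the partitions of one tumor type
#'
#' @param solutions List of `metab_subtypes` objects (gated-out pairs are
#'   skipped).
#' @return Symmetric matrix of normalized mutual information values with
#'   gene-set names as dimnames, or `NULL` if fewer than two partitions
#'   passed the gate.
#' @export
nmi_matrix <- function(solutions) {
  passed <- Filter(function(s) isTRUE(s$passed_gate), solutions)
  if (length(passed) < 2L) return(NULL)
  nms <- vapply(passed, function(s) s$gene_set, character(1))
  m <- diag(1, length(passed))
  dimnames(m) <- list(nms, nms)
  for (i in seq_along(passed)) {
    for (j in seq_len(i - 1L)) {
      v <- nmi(passed[[i]]$assignments, passed[[j]]$assignments)
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Run the full subtype-association pipeline
#'
#' For every (tumor type, gene set) pair: restrict the set to the
#' expression matrix, gate on cluster separation, cluster the samples and
#' test every derived feature against the partition; then apply the
#' per-class Bonferroni correction pooling all tumor types and extract
#' recurrent associations.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{cohorts}{named list of cohort bundles or directories written
#'       by [write_cohort()]; names are the tumor-type labels}
#'     \item{gene_sets}{optional `geneset_collection` or GMT path shared
#'       by all cohorts (default: each cohort's own `gene_sets` slot)}
#'     \item{metabolic_filter}{apply [filter_metabolic()] to the
#'       collection (default `FALSE`)}
#'     \item{gate_alpha}{Duda-Hart gate level (default 0.001)}
#'     \item{k_max}{maximum number of clusters (default 10)}
#'     \item{alpha}{family-wise error level (default 0.05)}
#'     \item{seed}{seed for the miRNA tie randomization (default 1)}
#'     \item{composite_types}{tumor types excluded from recurrence
#'       counting}
#'     \item{sgol_mode}{`"per_sample"` or `"cohort_sum"`}
#'     \item{count_invalid}{count invalid tests in the Bonferroni family
#'       size (default `FALSE`)}
#'     \item{out_dir}{optional output directory for the TSV reports}
#'   }
#' @return A `metab_run` list: `solutions` (per tumor, per gene set),
#'   `clusters` (per-sample tibble), `solution_summary` (glance rows),
#'   `associations` (corrected tibble), `families`, `recurrent`, `nmi`
#'   (per tumor), `log` (per-pair status with reason codes), `counts`
#'   (run bookkeeping) and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(gene_sets = NULL, metabolic_filter = FALSE,
                   gate_alpha = 0.001, k_max = 10L, alpha = 0.05,
                   seed = 1L,
                   composite_types = c("LUNG", "KIPAN", "GBMLGG",
                                       "COADREAD", "STES"),
                   sgol_mode = "per_sample", count_invalid = FALSE,
                   out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$cohorts) || length(config$cohorts) == 0L) {
    stop("config$cohorts must name at least one cohort")
  }
  shared_sets <- config$gene_sets
  if (is.character(shared_sets)) shared_sets <- read_gmt(shared_sets)

  solutions <- list()
  log_rows <- list()
  assoc_raw <- list()
  cluster_rows <- list()
  glance_rows <- list()
  nmi_list <- list()

  for (tumor in names(config$cohorts)) {
    cohort <- config$cohorts[[tumor]]
    if (is.character(cohort)) cohort <- read_cohort(cohort)
    expr <- cohort$expression
    clin_samples <- if (!is.null(cohort$clinical)) {
      cohort$clinical$sample
    } else colnames(expr)
    samples <- intersect(colnames(expr), clin_samples)
    if (length(samples) == 0L) {
      stop("empty sample intersection for tumor type '", tumor, "'")
    }
    expr <- expr[, samples, drop = FALSE]
    sets <- shared_sets %||% cohort$gene_sets
    if (is.null(sets)) stop("no gene sets available for '", tumor, "'")
    if (isTRUE(config$metabolic_filter)) sets <- filter_metabolic(sets)
    if (nrow(sets) == 0L) stop("no usable gene sets after filtering")
    sets <- restrict_to_matrix(sets, rownames(expr))
    features <- derive_all_features(cohort, seed = config$seed,
                                    sgol_mode = config$sgol_mode)

    tumor_solutions <- list()
    for (i in seq_len(nrow(sets))) {
      set_name <- sets$set[i]
      if (!sets$usable[i]) {
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          tumor_type = tumor, gene_set = set_name, status = "unusable",
          reason = "fewer_than_2_matrix_genes")
        next
      }
      sol <- cluster_gene_set(expr, sets$matrix_genes[[i]],
                              gene_set = set_name, tumor_type = tumor,
                              gate_alpha = config$gate_alpha,
                              k_max = config$k_max)
      tumor_solutions[[set_name]] <- sol
      status <- if (isTRUE(sol$passed_gate)) "clustered" else sol$reason
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        tumor_type = tumor, gene_set = set_name, status = status,
        reason = sol$reason %||% NA_character_)
      glance_rows[[length(glance_rows) + 1L]] <- glance(sol)
      if (isTRUE(sol$passed_gate)) {
        cluster_rows[[length(cluster_rows) + 1L]] <- tidy(sol)
        assoc_raw[[length(assoc_raw) + 1L]] <- associate_features(
          features, sol, collection = sets$collection[i])
      }
    }
    solutions[[tumor]] <- tumor_solutions
    nm <- nmi_matrix(tumor_solutions)
    if (!is.null(nm)) nmi_list[[tumor]] <- nm
  }

  raw <- dplyr::bind_rows(assoc_raw)
  if (nrow(raw) > 0L) {
    corrected <- bonferroni_families(raw, alpha = config$alpha,
                                     count_invalid = config$count_invalid)
    recurrent <- find_recurrent(corrected$results,
                                composite_types = config$composite_types)
  } else {
    corrected <- list(results = raw, families = tibble::tibble())
    recurrent <- tibble::tibble()
  }
  log_tbl <- dplyr::bind_rows(log_rows)
  summary_tbl <- dplyr::bind_rows(glance_rows)
  counts <- list(
    pairs_total = nrow(log_tbl),
    pairs_unusable = sum(log_tbl$status == "unusable"),
    pairs_gated_in = sum(log_tbl$status == "clustered"),
    k_histogram = table(summary_tbl$k[summary_tbl$passed_gate]),
    tests_run = nrow(raw),
    tests_valid = sum(raw$valid),
    significant_by_class = if (nrow(raw)) {
      tapply(corrected$results$significant,
             corrected$results$variable_class, sum)
    } else NULL)

  run <- list(solutions = solutions,
              clusters = dplyr::bind_rows(cluster_rows),
              solution_summary = summary_tbl,
              associations = corrected$results,
              families = corrected$families, recurrent = recurrent,
              nmi = nmi_list, log = log_tbl, counts = counts,
              config = config[setdiff(names(config), "cohorts")])
  class(run) <- "metab_run"
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  readr::write_tsv(run$clusters, fp("clusters.tsv"), progress = FALSE)
  readr::write_tsv(run$solution_summary, fp("solutions.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$associations, fp("associations.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$recurrent, fp("recurrent.tsv"), progress = FALSE)
  readr::write_tsv(run$log, fp("run_log.tsv"), progress = FALSE)
  for (tumor in names(run$nmi)) {
    tbl <- tibble::as_tibble(run$nmi[[tumor]], rownames = "gene_set")
    readr::write_tsv(tbl, fp(paste0("nmi_", tumor, ".tsv")),
                     progress = FALSE)
  }
  cfg <- run$config
  cfg$out_dir <- NULL
  cfg$composite_types <- paste(cfg$composite_types, collapse = ";")
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  readr::write_tsv(
    tibble::tibble(key = names(cfg),
                   value = vapply(cfg, function(x)
                     paste(format(x), collapse = ";"), character(1))),
    fp("run_config.tsv"), progress = FALSE)
  invisible(dir)
}

#' Summarize a pipeline run
#'
#' Counts significant associations per tumor type and per gene set and
#' reports the Spearman correlation between a tumor type's sample count
#' and its number of significant associations (larger cohorts have more
#' power, so a positive correlation is expected).
#'
#' @param run A `metab_run` object or a directory written by
#'   [run_pipeline()].
#' @return List with `by_tumor` (tibble: tumor_type, n_samples,
#'   n_significant), `by_gene_set` (tibble: gene_set, n_significant) and
#'   `sample_count_correlation` (Spearman rho, `NA` with fewer than 3
#'   tumor types).
#' @export
summarize_run <- function(run) {
  if (is.character(run)) {
    if (!file.exists(file.path(run, "associations.tsv"))) {
      stop("'", run, "' does not contain pipeline outputs")
    }
    assoc <- readr::read_tsv(file.path(run, "associations.tsv"),
                             col_types = readr::cols(), progress = FALSE)
    sols <- readr::read_tsv(file.path(run, "solutions.tsv"),
                            col_types = readr::cols(), progress = FALSE)
  } else {
    assoc <- run$associations
    sols <- run$solution_summary
  }
  n_samples <- dplyr::summarise(
    dplyr::group_by(sols, .data$tumor_type),
    n_samples = max(.data$n_samples), .groups = "drop")
  by_tumor <- dplyr::summarise(
    dplyr::group_by(assoc, .data$tumor_type),
    n_significant = sum(.data$significant), .groups = "drop")
  by_tumor <- dplyr::left_join(n_samples, by_tumor, by = "tumor_type")
  by_tumor$n_significant[is.na(by_tumor$n_significant)] <- 0L
  by_set <- dplyr::summarise(
    dplyr::group_by(assoc, .data$gene_set),
    n_significant = sum(.data$significant), .groups = "drop")
  rho <- if (nrow(by_tumor) >= 3L &&
             stats::sd(by_tumor$n_samples) > 0 &&
             stats::sd(by_tumor$n_significant) > 0) {
    stats::cor(by_tumor$n_samples, by_tumor$n_significant,
               method = "spearman")
  } else NA_real_
  list(by_tumor = by_tumor, by_gene_set = dplyr::arrange(
    by_set, dplyr::desc(.data$n_significant), .data$gene_set),
    sample_count_correlation = rho)
}

#' Histogram of the selected number of clusters
#'
#' @param run A `metab_run` object.
#' @return ggplot bar chart of `k` over all gated-in (tumor type, gene
#'   set) pairs.
#' @export
plot_k_histogram <- function(run) {
  df <- dplyr::filter(run$solution_summary, .data$passed_gate)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "selected number of clusters k", y = "pairs") +
    ggplot2::theme_minimal()
}
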