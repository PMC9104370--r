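#' @title Per-sample feature tables
#' @description Derived features are kept in one long tibble with columns
#' `variable_class`, `feature`, `sample` and the value columns appropriate
#' to the feature's type: `value` (continuous), `level` (categorical) or
#' `time`/`event` (survival). Nine variable classes are recognized: six
#' molecular (`copy_number`, `methylation_global`, `mirna`,
#' `point_mutation`, `gene_mutation`, `protein_rppa`) and three phenotypic
#' (`clinical`, `overall_survival`, `recurrence_free_survival`).
#' @name feature-tables
NULL

VARIABLE_CLASSES <- c("copy_number", "methylation_global", "mirna",
                      "point_mutation", "gene_mutation", "protein_rppa",
                      "clinical", "overall_survival",
                      "recurrence_free_survival")

empty_features <- function() {
  tibble::tibble(variable_class = character(), feature = character(),
                 sample = character(), value = double(),
                 level = character(), time = double(), event = integer())
}

feature_continuous <- function(variable_class, feature, samples, values) {
  tibble::tibble(variable_class = variable_class, feature = feature,
                 sample = samples, value = as.numeric(values),
                 level = NA_character_, time = NA_real_, event = NA_integer_)
}

feature_categorical <- function(variable_class, feature, samples, levels) {
  tibble::tibble(variable_class = variable_class, feature = feature,
                 sample = samples, value = NA_real_,
                 level = as.character(levels), time = NA_real_,
                 event = NA_integer_)
}

feature_survival <- function(variable_class, feature, samples, time, event) {
  tibble::tibble(variable_class = variable_class, feature = feature,
                 sample = samples, value = NA_real_, level = NA_character_,
                 time = as.numeric(time), event = as.integer(event))
}

#' Gene-level copy number from segmented data
#'
#' Assigns every gene the segment mean of the segment overlapping it; a
#' gene spanning several segments gets the length-weighted mean of their
#' segment means over the overlapped bases. Genes not covered by any
#' segment in a sample get 0 (with a coverage warning).
#'
#' @param seg Segment tibble from [read_seg()].
#' @param gene_coords Gene coordinate tibble from [read_bed_genes()]
#'   (1-based inclusive, same genome build as `seg`).
#' @return Numeric genes-by-samples matrix of (weighted) segment means.
#' @export
gene_level_copy_number <- function(seg, gene_coords) {
  if (any(seg$start > seg$end)) stop("malformed segment: start > end")
  genes_gr <- GenomicRanges::GRanges(
    gene_coords$chrom,
    IRanges::IRanges(gene_coords$start, gene_coords$end))
  seg_gr <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start, seg$end))
  samples <- unique(seg$sample)
  n_genes <- nrow(gene_coords)
  out <- matrix(0, nrow = n_genes, ncol = length(samples),
                dimnames = list(gene_coords$gene, samples))
  hits <- GenomicRanges::findOverlaps(genes_gr, seg_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi)) {
    # overlapped bases per (gene, segment) hit; 1-based inclusive both
    w <- pmin(gene_coords$end[qi], seg$end[si]) -
      pmax(gene_coords$start[qi], seg$start[si]) + 1
    key <- (match(seg$sample[si], samples) - 1L) * n_genes + qi
    num <- rowsum(w * seg$seg_mean[si], key)
    den <- rowsum(w, key)
    cells <- as.integer(rownames(num))
    out[cells] <- num[, 1L] / den[, 1L]
  } else {
    cells <- integer()
  }
  n_uncovered <- length(out) - length(cells)
  if (n_uncovered > 0L) {
    warning(n_uncovered,
            " gene/sample pairs had no overlapping segment; set to 0")
  }
  out
}

#' SGOL copy-number scores per region
#'
#' Segment-gain-or-loss scoring of positional regions: per gene and sample,
#' a copy-number value is retained only beyond the thresholds (`> pos` or
#' `< neg`, default +/-0.5, log2-ratio scale) and is otherwise set to 0;
#' the region score of a sample is the mean of these thresholded values
#' over the region's genes. The `"cohort_sum"` mode instead sums the
#' thresholded values across samples per gene before averaging over region
#' genes, yielding one gain and loss pair per region for the whole cohort
#' (a GISTIC-like summary that cannot enter per-sample tests; kept for
#' comparison).
#'
#' @param gene_cn Genes-by-samples matrix from [gene_level_copy_number()].
#' @param regions A `geneset_collection` tibble mapping region names to
#'   gene symbols (e.g. positional gene sets read with [read_gmt()]).
#' @param pos_threshold,neg_threshold Dead-zone bounds; must satisfy
#'   `neg_threshold < 0 < pos_threshold`.
#' @param mode `"per_sample"` (default) or `"cohort_sum"`.
#' @return `"per_sample"`: a feature tibble (class `copy_number`, one
#'   continuous feature per region). `"cohort_sum"`: a tibble with columns
#'   `region`, `gain`, `loss`.
#' @export
region_sgol_scores <- function(gene_cn, regions, pos_threshold = 0.5,
                               neg_threshold = -0.5,
                               mode = c("per_sample", "cohort_sum")) {
  mode <- match.arg(mode)
  if (!(neg_threshold < 0 && 0 < pos_threshold)) {
    stop("thresholds must satisfy neg_threshold < 0 < pos_threshold")
  }
  thr <- gene_cn
  thr[thr <= pos_threshold & thr >= neg_threshold] <- 0
  res <- purrr::map2(regions$set, regions$genes, function(nm, g) {
    g <- intersect(toupper(g), rownames(thr))
    if (length(g) == 0L) {
      warning("region '", nm, "' has no genes in the copy-number matrix; ",
              "dropped")
      return(NULL)
    }
    block <- thr[g, , drop = FALSE]
    if (mode == "per_sample") {
      feature_continuous("copy_number", nm, colnames(block),
                         colMeans(block))
    } else {
      tibble::tibble(region = nm,
                     gain = mean(rowSums(pmax(block, 0))),
                     loss = mean(rowSums(pmin(block, 0))))
    }
  })
  dplyr::bind_rows(res)
}

#' Global DNA methylation per sample
#'
#' Sums gene-level methylation values over all genes to give one global
#' methylation value per sample. Missing gene values are ignored (count
#' reported via message); a sample with no non-missing values gets no
#' feature row.
#'
#' @param meth Genes-by-samples matrix of gene-level methylation values.
#' @return Feature tibble (class `methylation_global`, feature
#'   `"global_methylation"`).
#' @export
global_methylation <- function(meth) {
  n_missing <- sum(is.na(meth))
  if (n_missing > 0L) {
    message("global_methylation: ignoring ", n_missing, " missing values")
  }
  ok <- colSums(!is.na(meth)) > 0L
  sums <- colSums(meth[, ok, drop = FALSE], na.rm = TRUE)
  feature_continuous("methylation_global", "global_methylation",
                     colnames(meth)[ok], sums)
}

#' Default non-synonymous variant classifications
#'
#' The MAF `Variant_Classification` values retained when collapsing point
#' mutations to gene level.
#' @export
NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
  "Nonstop_Mutation", "Translation_Start_Site")

#' Mutation features from somatic calls
#'
#' Filters calls to non-synonymous classifications and emits two
#' categorical feature classes: `gene_mutation` (a sample is mutated in a
#' gene if it carries one or more retained calls for it) and
#' `point_mutation` (one feature per distinct gene / protein-change pair).
#' Levels are `"mut"` / `"wt"`.
#'
#' @param calls Call tibble from [read_maf()].
#' @param samples Character vector of all cohort samples (samples without
#'   calls are wild-type everywhere).
#' @param nonsynonymous_classes Classifications retained; see
#'   [NONSYNONYMOUS_CLASSES].
#' @return Feature tibble covering both mutation classes.
#' @export
gene_level_mutation_matrix <- function(calls, samples,
                                       nonsynonymous_classes =
                                         NONSYNONYMOUS_CLASSES) {
  keep <- calls[calls$variant_classification %in% nonsynonymous_classes, ]
  keep <- dplyr::distinct(keep, .data$gene, .data$sample,
                          .data$protein_change)
  gene_feats <- purrr::map(sort(unique(keep$gene)), function(g) {
    mut <- unique(keep$sample[keep$gene == g])
    feature_categorical("gene_mutation", g, samples,
                        ifelse(samples %in% mut, "mut", "wt"))
  })
  pt <- dplyr::distinct(keep, .data$gene, .data$protein_change)
  pt <- dplyr::arrange(pt, .data$gene, .data$protein_change)
  point_feats <- purrr::map2(pt$gene, pt$protein_change, function(g, pc) {
    mut <- keep$sample[keep$gene == g & keep$protein_change == pc]
    feature_categorical("point_mutation", paste0(g, "_", pc), samples,
                        ifelse(samples %in% mut, "mut", "wt"))
  })
  dplyr::bind_rows(c(gene_feats, point_feats))
}

#' miRNA features as tie-randomized ranks
#'
#' Rank-transforms each miRNA across samples, resolving ties in an order
#' drawn uniformly at random within each tie group. Motivated by the large
#' number of zero-expression miRNAs, which would otherwise produce massive
#' tie groups; randomized ranks make the null distribution of the
#' downstream rank tests exact. Deterministic given (matrix, seed).
#'
#' @param mirna miRNAs-by-samples non-negative matrix.
#' @param seed Integer seed controlling tie resolution.
#' @return Feature tibble (class `mirna`, one continuous rank feature per
#'   miRNA).
#' @export
mirna_rank_feature <- function(mirna, seed) {
  ranked <- withr::with_seed(seed, {
    t(apply(mirna, 1L, rank, ties.method = "random"))
  })
  if (nrow(mirna) == 1L) {
    ranked <- matrix(ranked, nrow = 1L)
  }
  dimnames(ranked) <- dimnames(mirna)
  dplyr::bind_rows(purrr::map(rownames(ranked), function(m) {
    feature_continuous("mirna", m, colnames(ranked), ranked[m, ])
  }))
}

#' Continuous features from a measurement matrix
#'
#' Melts a features-by-samples matrix (e.g. RPPA protein abundance) into
#' continuous feature rows; values are passed through unchanged (the rank
#' tests applied downstream use ordinary average ranks for ties).
#'
#' @param m Features-by-samples numeric matrix.
#' @param variable_class Feature class tag (default `"protein_rppa"`).
#' @return Feature tibble.
#' @export
matrix_features <- function(m, variable_class = "protein_rppa") {
  dplyr::bind_rows(purrr::map(rownames(m), function(f) {
    feature_continuous(variable_class, f, colnames(m), m[f, ])
  }))
}

#' Clinical, overall-survival and recurrence-free-survival features
#'
#' Splits a clinical table into the three phenotypic feature classes.
#' Survival endpoints are read from `os_time`/`os_event` and
#' `rfs_time`/`rfs_event` pairs (days; event 0 = censored, 1 = event);
#' records with non-positive times are dropped with a warning, and events
#' outside \{0, 1\} are an error. Remaining numeric columns become
#' continuous clinical features; character columns become categorical
#' features unless they exceed `max_levels` distinct values (a guard
#' against free text), in which case they are rejected with a warning.
#'
#' @param clinical Tibble from [read_clinical()].
#' @param max_levels Maximum number of levels for a categorical clinical
#'   column (default 10).
#' @return Feature tibble covering the `clinical`, `overall_survival` and
#'   `recurrence_free_survival` classes.
#' @export
load_clinical <- function(clinical, max_levels = 10L) {
  out <- list()
  surv_specs <- list(
    overall_survival = c("os_time", "os_event", "OS"),
    recurrence_free_survival = c("rfs_time", "rfs_event", "RFS"))
  used <- "sample"
  for (cls in names(surv_specs)) {
    sp <- surv_specs[[cls]]
    if (all(sp[1:2] %in% names(clinical))) {
      used <- c(used, sp[1:2])
      time <- clinical[[sp[1L]]]
      event <- clinical[[sp[2L]]]
      keep <- !is.na(time) & !is.na(event)
      if (!all(event[keep] %in% c(0, 1))) {
        stop("survival event indicator must be 0 or 1 (", sp[2L], ")")
      }
      neg <- keep & time <= 0
      if (any(neg)) {
        warning(sum(neg), " record(s) with non-positive ", sp[1L],
                " dropped")
        keep <- keep & !neg
      }
      out[[cls]] <- feature_survival(cls, sp[3L], clinical$sample[keep],
                                     time[keep], event[keep])
    }
  }
  for (col in setdiff(names(clinical), used)) {
    x <- clinical[[col]]
    ok <- !is.na(x)
    if (is.numeric(x)) {
      out[[col]] <- feature_continuous("clinical", col,
                                       clinical$sample[ok], x[ok])
    } else {
      n_lev <- length(unique(x[ok]))
      if (n_lev > max_levels) {
        warning("clinical column '", col, "' has ", n_lev,
                " levels (> ", max_levels, "); rejected as free text")
      } else {
        out[[col]] <- feature_categorical("clinical", col,
                                          clinical$sample[ok],
                                          as.character(x[ok]))
      }
    }
  }
  if (length(out) == 0L) return(empty_features())
  dplyr::bind_rows(out)
}
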