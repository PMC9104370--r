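#' Specification of a synthetic multi-omic cohort
#'
#' Describes a cohort with known ground truth: subtype structure planted in
#' the expression of chosen gene sets, plus planted (and null) feature
#' effects conditioned on the subtypes of the *first* planted gene set.
#' All cluster-indexed parameters (`prob`, `shift`, hazard ratios, ...)
#' must have length `true_k` of that first set.
#'
#' Expression is log-normal: gene values are drawn on the log2 scale with
#' unit noise standard deviation and exported as TPM-like `2^x`, so
#' `separation` is the log2-scale mean offset applied to a planted set's
#' genes — a fraction `fraction_up` of them upward, the rest downward, with
#' an independent up/down pattern per cluster (each cluster then shows both
#' up- and downregulated genes, the structure a plain set-level
#' differential-expression score would miss).
#'
#' @param n_samples Cohort size.
#' @param planted_sets Tibble with columns `gene_set`, `n_genes`, `true_k`,
#'   `separation`, `fraction_up` (one row per planted set; `true_k = 1`
#'   plants no structure).
#' @param null_sets Tibble with columns `gene_set`, `n_genes`: gene sets
#'   whose genes are i.i.d. background.
#' @param n_background_genes Genes outside any set.
#' @param mutation_effects Tibble `gene`, `prob` (list column of
#'   per-cluster mutation probabilities).
#' @param n_null_mutation_genes,null_mutation_rate Cluster-independent
#'   mutation genes and their rate.
#' @param mirna_effects Tibble `name`, `shift` (list column of per-cluster
#'   log2 shifts).
#' @param n_null_mirnas,mirna_zero_inflation Null miRNA count and the
#'   zero-inflation probability applied to every miRNA.
#' @param n_methylation_genes Methylation matrix size.
#' @param methylation_shift Per-cluster logit shift of each sample's
#'   methylation level (all zero = null).
#' @param survival_hazard_ratios Per-cluster hazard ratios (all 1 = null).
#' @param baseline_hazard Event hazard of cluster 1 (per day).
#' @param censoring_rate Target fraction of censored samples; 1 censors
#'   everything.
#' @param histology_probs Levels-by-clusters matrix of histology level
#'   probabilities (rownames = level labels), or `NULL` for a
#'   cluster-independent 3-level histology.
#' @param cn_region_delta Per-cluster segment-mean shift of the planted
#'   copy-number region (all zero = null).
#' @param seed Integer seed; the cohort is a pure function of
#'   (spec, seed).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(
    n_samples = 200L,
    planted_sets = tibble::tibble(
      gene_set = "PLANTED_GLUCOSE_METABOLISM", n_genes = 30L, true_k = 2L,
      separation = 3, fraction_up = 0.5),
    null_sets = tibble::tibble(
      gene_set = "NULL_CONTROL_METABOLISM", n_genes = 30L),
    n_background_genes = 40L,
    mutation_effects = tibble::tibble(
      gene = "TP53", prob = list(c(0.25, 0.04))),
    n_null_mutation_genes = 3L,
    null_mutation_rate = 0.08,
    mirna_effects = tibble::tibble(
      name = "HSA-MIR-222", shift = list(c(2, 0))),
    n_null_mirnas = 10L,
    mirna_zero_inflation = 0.3,
    n_methylation_genes = 40L,
    methylation_shift = c(0, 0),
    survival_hazard_ratios = c(1, 3),
    baseline_hazard = 1 / 500,
    censoring_rate = 0.3,
    histology_probs = NULL,
    cn_region_delta = c(1, 0),
    seed = 1L) {
  spec <- list(
    n_samples = as.integer(n_samples), planted_sets = planted_sets,
    null_sets = null_sets,
    n_background_genes = as.integer(n_background_genes),
    mutation_effects = mutation_effects,
    n_null_mutation_genes = as.integer(n_null_mutation_genes),
    null_mutation_rate = null_mutation_rate,
    mirna_effects = mirna_effects,
    n_null_mirnas = as.integer(n_null_mirnas),
    mirna_zero_inflation = mirna_zero_inflation,
    n_methylation_genes = as.integer(n_methylation_genes),
    methylation_shift = methylation_shift,
    survival_hazard_ratios = survival_hazard_ratios,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    histology_probs = histology_probs, cn_region_delta = cn_region_delta,
    seed = as.integer(seed))
  stopifnot(spec$n_samples >= 4L, nrow(planted_sets) >= 1L,
            all(planted_sets$true_k >= 1L),
            all(planted_sets$separation >= 0),
            all(planted_sets$fraction_up >= 0 &
                  planted_sets$fraction_up <= 1),
            mirna_zero_inflation >= 0, mirna_zero_inflation <= 1,
            all(survival_hazard_ratios > 0),
            censoring_rate >= 0, censoring_rate <= 1)
  k1 <- planted_sets$true_k[1L]
  for (p in spec$mutation_effects$prob) {
    stopifnot(length(p) == k1, all(p >= 0 & p <= 1))
  }
  for (s in spec$mirna_effects$shift) stopifnot(length(s) == k1)
  stopifnot(length(survival_hazard_ratios) == k1,
            length(spec$methylation_shift) == k1,
            length(spec$cn_region_delta) == k1)
  class(spec) <- "cohort_spec"
  spec
}

#' Preset cohort specifications
#'
#' `"demo"`: a cohort with moderate subtype separation and every planted
#' effect class switched on. `"null"`: no planted structure and no
#' effects anywhere (global null). `"strong"`: well-separated subtypes
#' (log2 separation 4) for parameter-recovery studies.
#'
#' @param preset One of `"demo"`, `"null"`, `"strong"`.
#' @param n_samples,seed Passed to [cohort_spec()].
#' @param true_k Planted number of subtypes (`"strong"` only).
#' @return A `cohort_spec`.
#' @export
cohort_preset <- function(preset = c("demo", "null", "strong"),
                          n_samples = 200L, seed = 1L, true_k = 2L) {
  preset <- match.arg(preset)
  switch(preset,
    demo = cohort_spec(
      n_samples = n_samples, seed = seed,
      histology_probs = matrix(c(0.7, 0.2, 0.1,
                                 0.2, 0.3, 0.5), ncol = 2,
                               dimnames = list(c("a", "b", "c"), NULL))),
    null = cohort_spec(
      n_samples = n_samples, seed = seed,
      planted_sets = tibble::tibble(
        gene_set = "NULL_PRIMARY_METABOLISM", n_genes = 30L, true_k = 2L,
        separation = 0, fraction_up = 0.5),
      mutation_effects = tibble::tibble(
        gene = "TP53", prob = list(c(0.08, 0.08))),
      mirna_effects = tibble::tibble(
        name = "HSA-MIR-222", shift = list(c(0, 0))),
      survival_hazard_ratios = c(1, 1),
      methylation_shift = c(0, 0),
      cn_region_delta = c(0, 0),
      histology_probs = NULL),
    strong = {
      k <- as.integer(true_k)
      cohort_spec(
        n_samples = n_samples, seed = seed,
        planted_sets = tibble::tibble(
          gene_set = "PLANTED_GLUCOSE_METABOLISM", n_genes = 30L,
          true_k = k, separation = 4, fraction_up = 0.5),
        mutation_effects = tibble::tibble(
          gene = "TP53", prob = list(rep(0.1, k))),
        mirna_effects = tibble::tibble(
          name = "HSA-MIR-222", shift = list(rep(0, k))),
        survival_hazard_ratios = rep(1, k),
        methylation_shift = rep(0, k),
        cn_region_delta = rep(0, k))
    })
}

sample_ids <- function(n) sprintf("S%03d", seq_len(n))

balanced_assignments <- function(n, k) {
  stats::setNames(sample(rep(seq_len(k), length.out = n)), sample_ids(n))
}

#' Generate the expression matrix with planted subtype structure
#'
#' @param spec A `cohort_spec`.
#' @return List with `expression` (TPM-like genes-by-samples matrix),
#'   `gene_sets` (a `geneset_collection` of the planted and null sets) and
#'   `truth` (named list of per-set true assignments; sets with
#'   `true_k = 1` have none).
#' @export
generate_expression <- function(spec) {
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_samples
    samples <- sample_ids(n)
    sets <- list()
    truth <- list()
    blocks <- list()
    for (i in seq_len(nrow(spec$planted_sets))) {
      ps <- spec$planted_sets[i, ]
      genes <- sprintf("%s_G%02d", ps$gene_set, seq_len(ps$n_genes))
      sets[[ps$gene_set]] <- genes
      mu <- rnorm(ps$n_genes, mean = 6, sd = 1.5)
      x <- matrix(rnorm(ps$n_genes * n, mean = mu, sd = 1),
                  nrow = ps$n_genes, ncol = n,
                  dimnames = list(genes, samples))
      if (ps$true_k >= 2L) {
        assign <- balanced_assignments(n, ps$true_k)
        truth[[ps$gene_set]] <- assign
        signs <- matrix(
          ifelse(runif(ps$n_genes * ps$true_k) < ps$fraction_up, 1, -1),
          nrow = ps$n_genes)
        x <- x + ps$separation * signs[, assign[samples]]
      }
      blocks[[ps$gene_set]] <- x
    }
    for (i in seq_len(nrow(spec$null_sets))) {
      ns <- spec$null_sets[i, ]
      genes <- sprintf("%s_G%02d", ns$gene_set, seq_len(ns$n_genes))
      sets[[ns$gene_set]] <- genes
      mu <- rnorm(ns$n_genes, mean = 6, sd = 1.5)
      blocks[[ns$gene_set]] <- matrix(
        rnorm(ns$n_genes * n, mean = mu, sd = 1), nrow = ns$n_genes,
        dimnames = list(genes, samples))
    }
    if (spec$n_background_genes > 0L) {
      genes <- sprintf("BG_G%03d", seq_len(spec$n_background_genes))
      mu <- rnorm(spec$n_background_genes, mean = 6, sd = 1.5)
      blocks[["__background__"]] <- matrix(
        rnorm(spec$n_background_genes * n, mean = mu, sd = 1),
        nrow = spec$n_background_genes, dimnames = list(genes, samples))
    }
    expr <- 2^do.call(rbind, unname(blocks))
    collection <- new_geneset_collection(tibble::tibble(
      set = names(sets), collection = "synthetic", genes = unname(sets)))
    list(expression = expr, gene_sets = collection, truth = truth)
  })
}

conditioning_truth <- function(spec, truth) {
  primary <- spec$planted_sets$gene_set[1L]
  k <- spec$planted_sets$true_k[1L]
  if (k >= 2L) {
    truth[[primary]]
  } else {
    stats::setNames(rep(1L, spec$n_samples), sample_ids(spec$n_samples))
  }
}

#' Generate somatic mutation calls
#'
#' Planted genes are mutated with cluster-specific probabilities; null
#' genes at a cluster-independent rate. Every mutated sample receives one
#' non-synonymous call with a classification drawn from
#' [NONSYNONYMOUS_CLASSES] and a synthetic protein change.
#'
#' @param spec A `cohort_spec`.
#' @param truth Per-sample cluster assignment of the conditioning gene set.
#' @return MAF-like call tibble (as from [read_maf()]).
#' @export
generate_mutations <- function(spec, truth) {
  withr::with_seed(spec$seed + 2L, {
    samples <- names(truth)
    rows <- list()
    emit <- function(gene, p_by_sample) {
      mut <- samples[runif(length(samples)) < p_by_sample]
      if (length(mut) == 0L) return(NULL)
      tibble::tibble(
        gene = gene, sample = mut,
        variant_classification = sample(NONSYNONYMOUS_CLASSES,
                                        length(mut), replace = TRUE),
        protein_change = sprintf("p.A%dT", sample(1000L, length(mut),
                                                  replace = TRUE)))
    }
    for (i in seq_len(nrow(spec$mutation_effects))) {
      me <- spec$mutation_effects[i, ]
      rows[[me$gene]] <- emit(me$gene, me$prob[[1L]][truth])
    }
    for (j in seq_len(spec$n_null_mutation_genes)) {
      g <- sprintf("NULLMUT%02d", j)
      rows[[g]] <- emit(g, rep(spec$null_mutation_rate, length(samples)))
    }
    calls <- dplyr::bind_rows(rows)
    if (nrow(calls) == 0L) {
      calls <- tibble::tibble(gene = character(), sample = character(),
                              variant_classification = character(),
                              protein_change = character())
    }
    calls
  })
}

#' Generate survival endpoints
#'
#' Event times are exponential with a cluster-specific hazard
#' (`baseline_hazard * hazard_ratio[cluster]`); censoring times are
#' independent exponentials with the rate tuned so the expected censored
#' fraction matches `censoring_rate`. OS and RFS are drawn independently
#' from the same model.
#'
#' @param spec A `cohort_spec`.
#' @param truth Conditioning cluster assignment.
#' @return Tibble `sample`, `os_time`, `os_event`, `rfs_time`,
#'   `rfs_event`.
#' @export
generate_survival <- function(spec, truth) {
  withr::with_seed(spec$seed + 3L, {
    n <- length(truth)
    hz <- spec$baseline_hazard * spec$survival_hazard_ratios[truth]
    draw <- function() {
      t_event <- rexp(n, rate = hz)
      if (spec$censoring_rate >= 1) {
        list(time = rexp(n, rate = mean(hz)), event = rep(0L, n))
      } else if (spec$censoring_rate <= 0) {
        list(time = t_event, event = rep(1L, n))
      } else {
        cens_rate <- mean(hz) * spec$censoring_rate /
          (1 - spec$censoring_rate)
        t_cens <- rexp(n, rate = cens_rate)
        list(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
      }
    }
    os <- draw()
    rfs <- draw()
    tibble::tibble(sample = names(truth), os_time = os$time,
                   os_event = os$event, rfs_time = rfs$time,
                   rfs_event = rfs$event)
  })
}

TOY_GENOME <- list(chroms = c(chr1 = 1e7, chr2 = 1e7),
                   genes_per_chrom = 50L, gene_width = 1e5,
                   gene_spacing = 2e5, segment_width = 1e6)

toy_gene_coords <- function() {
  g <- TOY_GENOME
  dplyr::bind_rows(lapply(names(g$chroms), function(chr) {
    start <- (seq_len(g$genes_per_chrom) - 1L) * g$gene_spacing + 1
    tibble::tibble(
      gene = sprintf("%s_CN_G%02d", toupper(chr),
                     seq_len(g$genes_per_chrom)),
      chrom = chr, start = start, end = start + g$gene_width - 1)
  }))
}

toy_regions <- function() {
  coords <- toy_gene_coords()
  in_window <- function(chr) {
    coords$gene[coords$chrom == chr & coords$start >= 2e6 + 1 &
                  coords$end <= 5e6]
  }
  new_geneset_collection(tibble::tibble(
    set = c("REGION_PLANTED", "REGION_NULL"),
    collection = "positional",
    genes = list(in_window("chr1"), in_window("chr2"))))
}

#' Generate segmented copy-number data on a toy genome
#'
#' The toy genome has 2 chromosomes of 10 Mb with 50 genes each on a
#' regular grid. Per sample, each chromosome is cut into 1 Mb segments
#' with baseline segment means drawn from Normal(0, 0.05); the segments
#' under the planted region (chr1, 2-5 Mb) are shifted by the
#' cluster-specific `cn_region_delta`. Neighboring segments with equal
#' means are merged into single records.
#'
#' @param spec A `cohort_spec`.
#' @param truth Conditioning cluster assignment.
#' @return List with `seg` (tibble as from [read_seg()]), `gene_coords`
#'   (as from [read_bed_genes()]) and `regions` (positional
#'   `geneset_collection`).
#' @export
generate_cn_segments <- function(spec, truth) {
  withr::with_seed(spec$seed + 4L, {
    g <- TOY_GENOME
    n_seg <- as.integer(g$chroms[1L] / g$segment_width)
    starts <- (seq_len(n_seg) - 1L) * g$segment_width + 1
    ends <- starts + g$segment_width - 1
    planted <- starts >= 2e6 + 1 & ends <= 5e6
    rows <- lapply(names(truth), function(s) {
      delta <- spec$cn_region_delta[truth[[s]]]
      per_chrom <- lapply(names(g$chroms), function(chr) {
        means <- rnorm(n_seg, 0, 0.05)
        if (chr == "chr1") means[planted] <- means[planted] + delta
        tibble::tibble(sample = s, chrom = chr, start = starts,
                       end = ends,
                       num_mark = as.integer(g$segment_width / 1e4),
                       seg_mean = means)
      })
      dplyr::bind_rows(per_chrom)
    })
    seg <- merge_equal_segments(dplyr::bind_rows(rows))
    list(seg = seg, gene_coords = toy_gene_coords(),
         regions = toy_regions())
  })
}

merge_equal_segments <- function(seg) {
  seg <- dplyr::arrange(seg, .data$sample, .data$chrom, .data$start)
  n <- nrow(seg)
  if (n == 0L) return(seg)
  new_run <- c(TRUE, seg$sample[-1L] != seg$sample[-n] |
                 seg$chrom[-1L] != seg$chrom[-n] |
                 seg$seg_mean[-1L] != seg$seg_mean[-n])
  seg$run <- cumsum(new_run)
  out <- dplyr::summarise(
    dplyr::group_by(seg, .data$sample, .data$chrom, .data$run),
    start = min(.data$start), end = max(.data$end),
    num_mark = sum(.data$num_mark), seg_mean = .data$seg_mean[1L],
    .groups = "drop")
  out <- dplyr::arrange(out, .data$sample, .data$chrom, .data$start)
  out[, c("sample", "chrom", "start", "end", "num_mark", "seg_mean")]
}

#' Generate miRNA and methylation matrices
#'
#' miRNA values are zero-inflated log-normal: zero with probability
#' `mirna_zero_inflation`, else `2^Normal(4 + shift[cluster], 1)` for
#' planted miRNAs (shift 0 for null miRNAs). Methylation is
#' Beta-distributed per gene, with each sample's values shifted on the
#' logit scale by the cluster-specific `methylation_shift`.
#'
#' @param spec A `cohort_spec`.
#' @param truth Conditioning cluster assignment.
#' @return List with `mirna` and `methylation` matrices.
#' @export
generate_mirna_methylation <- function(spec, truth) {
  withr::with_seed(spec$seed + 5L, {
    samples <- names(truth)
    n <- length(samples)
    draw_mirna <- function(shift_by_cluster) {
      x <- 2^rnorm(n, mean = 4 + shift_by_cluster[truth], sd = 1)
      x[runif(n) < spec$mirna_zero_inflation] <- 0
      x
    }
    planted <- lapply(seq_len(nrow(spec$mirna_effects)), function(i) {
      draw_mirna(spec$mirna_effects$shift[[i]])
    })
    names(planted) <- spec$mirna_effects$name
    nulls <- lapply(seq_len(spec$n_null_mirnas), function(i) {
      draw_mirna(rep(0, max(truth)))
    })
    names(nulls) <- sprintf("HSA-MIR-NULL%02d", seq_len(spec$n_null_mirnas))
    mirna <- do.call(rbind, c(planted, nulls))
    colnames(mirna) <- samples

    base <- matrix(rbeta(spec$n_methylation_genes * n, 2, 5),
                   nrow = spec$n_methylation_genes,
                   dimnames = list(
                     sprintf("METH_G%03d", seq_len(spec$n_methylation_genes)),
                     samples))
    shift <- spec$methylation_shift[truth]
    meth <- stats::plogis(stats::qlogis(base) +
                            matrix(shift, nrow = nrow(base), ncol = n,
                                   byrow = TRUE))
    list(mirna = mirna, methylation = meth)
  })
}

generate_clinical <- function(spec, truth) {
  withr::with_seed(spec$seed + 6L, {
    samples <- names(truth)
    n <- length(samples)
    surv <- generate_survival(spec, truth)
    probs <- spec$histology_probs
    if (is.null(probs)) {
      k <- max(truth)
      probs <- matrix(rep(c(0.5, 0.3, 0.2), k), ncol = k,
                      dimnames = list(c("a", "b", "c"), NULL))
    }
    histology <- vapply(seq_len(n), function(i) {
      sample(rownames(probs), 1L, prob = probs[, truth[[i]]])
    }, character(1))
    tibble::tibble(sample = samples, os_time = surv$os_time,
                   os_event = surv$os_event, rfs_time = surv$rfs_time,
                   rfs_event = surv$rfs_event, histology = histology,
                   age = round(rnorm(n, 62, 10), 1))
  })
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates every generator under a single seed and optionally writes
#' all external-interface files plus a JSON truth sidecar. The sidecar
#' records the true assignments per planted gene set and every planted
#' effect, so recovered partitions can be scored (e.g. by adjusted Rand
#' index) without re-running the generator.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory (created if needed), or `NULL` for an
#'   in-memory cohort only.
#' @return A `synthetic_cohort` list: `expression`, `mirna`,
#'   `methylation`, `seg`, `calls`, `clinical`, `gene_coords`, `regions`,
#'   `gene_sets`, `truth`, `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  ex <- generate_expression(spec)
  truth <- conditioning_truth(spec, ex$truth)
  cn <- generate_cn_segments(spec, truth)
  mm <- generate_mirna_methylation(spec, truth)
  cohort <- list(
    expression = ex$expression, gene_sets = ex$gene_sets,
    mirna = mm$mirna, methylation = mm$methylation,
    seg = cn$seg, gene_coords = cn$gene_coords, regions = cn$regions,
    calls = generate_mutations(spec, truth),
    clinical = generate_clinical(spec, truth),
    truth = list(assignments = ex$truth,
                 conditioning_set = spec$planted_sets$gene_set[1L],
                 effects = list(
                   mutation = spec$mutation_effects,
                   mirna = spec$mirna_effects,
                   survival_hazard_ratios = spec$survival_hazard_ratios,
                   methylation_shift = spec$methylation_shift,
                   cn_region_delta = spec$cn_region_delta)),
    spec = spec)
  class(cohort) <- "synthetic_cohort"
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Writes every reader format consumed by the pipeline: expression.tsv,
#' mirna.tsv, methylation.tsv, cn.seg, mutations.maf.tsv, clinical.tsv,
#' genes.bed, regions.gmt, gene_sets.gmt and truth.json.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_matrix_tsv(cohort$expression, fp("expression.tsv"))
  write_matrix_tsv(cohort$mirna, fp("mirna.tsv"), id_col = "mirna")
  write_matrix_tsv(round(cohort$methylation, 6), fp("methylation.tsv"))
  write_seg(cohort$seg, fp("cn.seg"))
  maf <- tibble::tibble(Hugo_Symbol = cohort$calls$gene,
                        Tumor_Sample_Barcode = cohort$calls$sample,
                        Variant_Classification =
                          cohort$calls$variant_classification,
                        Protein_Change = cohort$calls$protein_change)
  readr::write_tsv(maf, fp("mutations.maf.tsv"), progress = FALSE)
  readr::write_tsv(cohort$clinical, fp("clinical.tsv"), progress = FALSE)
  write_bed_genes(cohort$gene_coords, fp("genes.bed"))
  write_gmt(cohort$regions, fp("regions.gmt"))
  write_gmt(cohort$gene_sets, fp("gene_sets.gmt"))
  truth <- cohort$truth
  truth$assignments <- lapply(truth$assignments, function(a) {
    as.list(stats::setNames(as.integer(a), names(a)))
  })
  truth$effects <- list(
    mutation = as.list(stats::setNames(truth$effects$mutation$prob,
                                       truth$effects$mutation$gene)),
    mirna = as.list(stats::setNames(truth$effects$mirna$shift,
                                    truth$effects$mirna$name)),
    survival_hazard_ratios = truth$effects$survival_hazard_ratios,
    methylation_shift = truth$effects$methylation_shift,
    cn_region_delta = truth$effects$cn_region_delta)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a written cohort directory back into memory
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with the same data slots as a `synthetic_cohort`
#'   (without `spec`).
#' @export
read_cohort <- function(dir) {
  fp <- function(x) file.path(dir, x)
  truth <- jsonlite::read_json(fp("truth.json"))
  truth$assignments <- lapply(truth$assignments, function(a) {
    stats::setNames(as.integer(unlist(a)), names(a))
  })
  list(expression = read_matrix_tsv(fp("expression.tsv")),
       mirna = read_matrix_tsv(fp("mirna.tsv")),
       methylation = read_matrix_tsv(fp("methylation.tsv")),
       seg = read_seg(fp("cn.seg")),
       calls = read_maf(fp("mutations.maf.tsv")),
       clinical = read_clinical(fp("clinical.tsv")),
       gene_coords = read_bed_genes(fp("genes.bed")),
       regions = read_gmt(fp("regions.gmt"), collection = "positional"),
       gene_sets = read_gmt(fp("gene_sets.gmt"), collection = "synthetic"),
       truth = truth)
}
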