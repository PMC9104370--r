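#' Rank-transform an expression matrix gene-wise
#'
#' Replaces each gene row by the ranks of its values across samples (average
#' ranks for ties). Ranking per gene preserves the up/down block structure
#' that distinguishes metabolic subtypes while discarding scale, which makes
#' the downstream cluster-separation gate conservative with respect to heavy
#' tails.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @return Matrix of the same shape holding ranks `1..n` per row; genes with
#'   zero variance become constant rows and are flagged in the
#'   `"zero_variance"` attribute (character vector of gene names).
#' @export
rank_transform <- function(expr) {
  out <- t(apply(expr, 1L, rank, ties.method = "average"))
  dimnames(out) <- dimnames(expr)
  zv <- rownames(expr)[apply(expr, 1L, function(x) max(x) == min(x))]
  attr(out, "zero_variance") <- zv %||% character()
  out
}

#' Log-transform an expression matrix
#'
#' Elementwise `log2(value + pseudocount)`. Provided for the alternative
#' input space of the cluster-separation gate; the pipeline default is the
#' rank transform, which proved the more conservative choice.
#'
#' @param expr Non-negative numeric matrix.
#' @param pseudocount Added before taking logs.
#' @return Transformed matrix.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (any(expr < 0)) stop("log_transform: negative input values")
  out <- log2(expr + pseudocount)
  dimnames(out) <- dimnames(expr)
  out
}

unusable_error <- function(msg) {
  structure(class = c("metaboclust_unusable", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Spearman correlation distance between samples
#'
#' For every sample pair, computes the Spearman rank correlation of their
#' expression profiles over the genes of one gene set and returns
#' `d = 1 - rho` (range 0 to 2). Genes with zero variance across samples are
#' dropped first; fewer than two usable genes raises an "unusable" condition
#' that the pipeline records and skips.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param genes Optional character vector restricting the genes used
#'   (default: all rows).
#' @return Symmetric samples-by-samples distance matrix with zero diagonal.
#' @export
spearman_distance <- function(expr, genes = NULL) {
  if (!is.null(genes)) {
    expr <- expr[intersect(toupper(genes), rownames(expr)), , drop = FALSE]
  }
  keep <- apply(expr, 1L, function(x) max(x) > min(x))
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) < 2L) {
    stop(unusable_error("fewer than 2 usable (non-constant) genes"))
  }
  sample_sd <- apply(expr, 2L, stats::sd)
  if (any(sample_sd == 0)) {
    stop("sample '", colnames(expr)[sample_sd == 0][1L],
         "' has zero variance across the gene subset")
  }
  rho <- stats::cor(expr, method = "spearman")
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Duda-Hart test of cluster separation
#'
#' Tests the one-cluster null hypothesis for a candidate 2-split of `n`
#' points in `p` dimensions. The statistic is `H = Je(2)/Je(1)`, the ratio
#' of the within-group sum of squares of the split to the total sum of
#' squares of the unsplit data; small `H` means the split explains much of
#' the spread. The p-value uses the normal approximation
#' `z = (1 - 2/(pi*p) - H) * sqrt(n*p / (2*(1 - 8/(pi^2*p))))`,
#' `p_value = 1 - pnorm(z)`.
#'
#' @param points Numeric `n x p` matrix (rows are samples).
#' @param split Length-`n` vector with exactly two distinct values giving
#'   the candidate partition.
#' @return List with `statistic` (H), `z` and `p_value`.
#' @export
duda_hart_test <- function(points, split) {
  points <- as.matrix(points)
  n <- nrow(points)
  p <- ncol(points)
  if (n < 3L) stop("duda_hart_test: need at least 3 points")
  split <- as.integer(factor(split))
  if (length(split) != n) stop("split length must match number of points")
  if (length(unique(split)) != 2L) {
    stop("split must have exactly two non-empty parts")
  }
  wss <- function(x) sum(sweep(x, 2L, colMeans(x))^2)
  je1 <- wss(points)
  if (je1 <= 0) stop("degenerate input: all points identical (Je(1) = 0)")
  je2 <- wss(points[split == 1L, , drop = FALSE]) +
    wss(points[split == 2L, , drop = FALSE])
  h <- je2 / je1
  z <- (1 - 2 / (pi * p) - h) *
    sqrt(n * p / (2 * (1 - 8 / (pi^2 * p))))
  list(statistic = h, z = z, p_value = 1 - stats::pnorm(z))
}

#' Partitioning around medoids (BUILD + SWAP)
#'
#' Classic PAM on a precomputed distance matrix. BUILD greedily selects `k`
#' medoids minimizing the total distance of every point to its nearest
#' medoid; SWAP repeatedly applies the best strictly improving
#' (medoid, non-medoid) exchange until none exists. All ties (initial
#' medoid, added medoid, improving swap, nearest-medoid assignment) are
#' broken toward the lowest sample index, so the output is deterministic.
#'
#' @param d Symmetric distance matrix (column names become sample IDs).
#' @param k Number of clusters, `2 <= k < n`.
#' @return List with `medoids` (sample IDs, ascending index order),
#'   `assignments` (named integer vector of cluster labels `1..k`) and
#'   `objective` (total distance to nearest medoid).
#' @export
pam_cluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  k <- as.integer(k)
  if (k < 2L || k >= n) stop("pam_cluster: need 2 <= k < n")
  ids <- colnames(d) %||% as.character(seq_len(n))

  ## BUILD
  medoids <- which.min(colSums(d))
  dnear <- d[, medoids]
  while (length(medoids) < k) {
    gains <- colSums(pmax(dnear - d, 0))
    gains[medoids] <- -Inf
    j <- which.max(gains)
    medoids <- c(medoids, j)
    dnear <- pmin(dnear, d[, j])
  }

  ## SWAP
  eps <- 1e-12
  repeat {
    dm <- d[, medoids, drop = FALSE]
    near <- max.col(-dm, ties.method = "first")
    d1 <- dm[cbind(seq_len(n), near)]
    dm[cbind(seq_len(n), near)] <- Inf
    d2 <- apply(dm, 1L, min)
    objective <- sum(d1)
    best_delta <- 0
    best <- NULL
    non_medoids <- setdiff(seq_len(n), medoids)
    for (h in sort(non_medoids)) {
      dh <- d[, h]
      for (mi in seq_along(medoids)) {
        cand <- pmin(d1, dh)
        owns <- near == mi
        cand[owns] <- pmin(d2[owns], dh[owns])
        delta <- sum(cand) - objective
        if (delta < best_delta - eps) {
          best_delta <- delta
          best <- c(mi, h)
        }
      }
    }
    if (is.null(best)) break
    medoids[best[1L]] <- best[2L]
  }

  medoids <- sort(medoids)
  dm <- d[, medoids, drop = FALSE]
  assignments <- max.col(-dm, ties.method = "first")
  assignments[medoids] <- seq_len(k)  # a medoid always anchors its own cluster
  names(assignments) <- ids
  list(medoids = ids[medoids], assignments = assignments,
       objective = sum(dm[cbind(seq_len(n), assignments)]))
}

#' Silhouette widths of a partition
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance of
#' sample `i` to its own cluster (excluding itself) and `b(i)` the smallest
#' mean distance to another cluster. Samples in singleton clusters get
#' `s(i) = 0`, as does the degenerate case `a = b = 0`.
#'
#' @param d Distance matrix.
#' @param assignments Integer cluster labels (1..k), all clusters non-empty.
#' @return List with `per_sample` (numeric vector) and `average`.
#' @export
silhouette_width <- function(d, assignments) {
  d <- as.matrix(d)
  n <- nrow(d)
  cl <- as.integer(factor(assignments))
  k <- length(unique(cl))
  if (k < 2L) stop("silhouette_width: need at least 2 clusters")
  sizes <- tabulate(cl, nbins = k)
  sums <- t(rowsum(d, cl))              # n x k: total distance to each cluster
  mean_to <- sweep(sums, 2L, sizes, "/")
  own <- cbind(seq_len(n), cl)
  a <- sums[own] / pmax(sizes[cl] - 1L, 1L)
  other <- mean_to
  other[own] <- Inf
  b <- apply(other, 1L, min)
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  s[sizes[cl] == 1L] <- 0
  names(s) <- colnames(d)
  list(per_sample = s, average = mean(s))
}

#' Choose the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for `k = 2..k_max` (clamped to `n - 1`) and keeps
#' the `k` maximizing the average silhouette width; exact ties go to the
#' smaller `k`.
#'
#' @param d Distance matrix over at least 3 samples.
#' @param k_max Largest `k` considered (default 10).
#' @return List with `k`, `medoids`, `assignments`, `avg_silhouette`,
#'   `per_sample` silhouettes and `asw_by_k` (tibble of the profile).
#' @export
select_k <- function(d, k_max = 10L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("select_k: need at least 3 samples")
  ks <- 2L:min(as.integer(k_max), n - 1L)
  fits <- lapply(ks, function(k) {
    fit <- pam_cluster(d, k)
    fit$sil <- silhouette_width(d, fit$assignments)
    fit
  })
  asw <- vapply(fits, function(f) f$sil$average, numeric(1))
  best <- which.max(asw)               # first max: ties toward smaller k
  fit <- fits[[best]]
  list(k = ks[best], medoids = fit$medoids, assignments = fit$assignments,
       avg_silhouette = fit$sil$average, per_sample = fit$sil$per_sample,
       asw_by_k = tibble::tibble(k = ks, avg_silhouette = asw))
}

#' Cluster one tumor cohort with one metabolic gene set
#'
#' The full subtype procedure for a (tumor type, gene set) pair:
#' \enumerate{
#'   \item restrict the expression matrix to the set's genes, dropping
#'     zero-variance genes (fewer than 2 usable genes: the pair is recorded
#'     as unusable);
#'   \item compute the Spearman distance between samples and a candidate
#'     2-split with PAM;
#'   \item gate on the Duda-Hart test evaluated on the rank-transformed
#'     coordinates with that split: `p >= gate_alpha` means no detectable
#'     cluster structure and the pair is gated out;
#'   \item otherwise select `k` on the same distance by average silhouette
#'     width.
#' }
#'
#' @param expr Genes-by-samples TPM-like matrix.
#' @param genes Character vector of gene symbols (one gene set).
#' @param gene_set,tumor_type Labels stored in the result.
#' @param gate_alpha Significance gate for the Duda-Hart p-value
#'   (default 0.001).
#' @param k_max Largest number of clusters considered (default 10).
#' @return A `metab_subtypes` object; see [tidy.metab_subtypes()] and
#'   [glance.metab_subtypes()].
#' @export
cluster_gene_set <- function(expr, genes, gene_set = "gene_set",
                             tumor_type = "cohort", gate_alpha = 0.001,
                             k_max = 10L) {
  genes <- toupper(genes)
  sub <- expr[intersect(genes, rownames(expr)), , drop = FALSE]
  keep <- apply(sub, 1L, function(x) length(x) && max(x) > min(x))
  sub <- sub[keep, , drop = FALSE]
  base <- list(tumor_type = tumor_type, gene_set = gene_set,
               n_samples = ncol(expr), n_genes = nrow(sub),
               gate_alpha = gate_alpha)
  if (nrow(sub) < 2L) {
    return(new_metab_subtypes(c(base, list(
      passed_gate = FALSE, reason = "unusable", duda_hart_p = NA_real_))))
  }
  d <- spearman_distance(sub)
  gate_split <- pam_cluster(d, 2L)$assignments
  dh <- duda_hart_test(t(rank_transform(sub)), gate_split)
  if (dh$p_value >= gate_alpha) {
    return(new_metab_subtypes(c(base, list(
      passed_gate = FALSE, reason = "gated_out",
      duda_hart_p = dh$p_value, duda_hart_h = dh$statistic))))
  }
  sel <- select_k(d, k_max = k_max)
  new_metab_subtypes(c(base, list(
    passed_gate = TRUE, reason = NA_character_,
    duda_hart_p = dh$p_value, duda_hart_h = dh$statistic,
    k = sel$k, medoids = sel$medoids, assignments = sel$assignments,
    avg_silhouette = sel$avg_silhouette, per_sample = sel$per_sample,
    asw_by_k = sel$asw_by_k)))
}

new_metab_subtypes <- function(x) {
  x$k <- x$k %||% NA_integer_
  x$avg_silhouette <- x$avg_silhouette %||% NA_real_
  structure(x, class = "metab_subtypes")
}

#' @export
print.metab_subtypes <- function(x, ...) {
  cat("Metabolic subtypes:", x$tumor_type, "/", x$gene_set, "\n")
  cat("  samples:", x$n_samples, " genes used:", x$n_genes, "\n")
  if (isTRUE(x$passed_gate)) {
    cat(sprintf("  Duda-Hart p = %.3g (gate alpha = %g): clustered\n",
                x$duda_hart_p, x$gate_alpha))
    cat(sprintf("  k = %d, average silhouette width = %.3f\n",
                x$k, x$avg_silhouette))
  } else {
    cat("  no subtypes:", x$reason,
        if (!is.na(x$duda_hart_p)) {
          sprintf("(Duda-Hart p = %.3g)", x$duda_hart_p)
        } else "", "\n")
  }
  invisible(x)
}

#' Per-sample view of a subtype solution
#'
#' @param x A `metab_subtypes` object.
#' @param ... Unused.
#' @return Tibble with columns `tumor_type`, `gene_set`, `sample`,
#'   `cluster`, `silhouette` (empty for gated-out / unusable pairs).
#' @export
tidy.metab_subtypes <- function(x, ...) {
  if (!isTRUE(x$passed_gate)) {
    return(tibble::tibble(tumor_type = character(), gene_set = character(),
                          sample = character(), cluster = integer(),
                          silhouette = double()))
  }
  tibble::tibble(tumor_type = x$tumor_type, gene_set = x$gene_set,
                 sample = names(x$assignments),
                 cluster = as.integer(x$assignments),
                 silhouette = unname(x$per_sample))
}

#' One-row summary of a subtype solution
#'
#' @param x A `metab_subtypes` object.
#' @param ... Unused.
#' @return One-row tibble: `tumor_type`, `gene_set`, `n_samples`,
#'   `n_genes`, `passed_gate`, `reason`, `duda_hart_p`, `k`,
#'   `avg_silhouette`.
#' @export
glance.metab_subtypes <- function(x, ...) {
  tibble::tibble(tumor_type = x$tumor_type, gene_set = x$gene_set,
                 n_samples = x$n_samples, n_genes = x$n_genes,
                 passed_gate = isTRUE(x$passed_gate),
                 reason = x$reason %||% NA_character_,
                 duda_hart_p = x$duda_hart_p,
                 k = x$k, avg_silhouette = x$avg_silhouette)
}

#' Silhouette plot of a subtype solution
#'
#' @param object A `metab_subtypes` object that passed the gate.
#' @param ... Unused.
#' @return A ggplot: per-sample silhouette widths grouped by cluster, with
#'   the average marked.
#' @export
autoplot.metab_subtypes <- function(object, ...) {
  if (!isTRUE(object$passed_gate)) {
    stop("no subtypes to plot (pair was ", object$reason, ")")
  }
  df <- tidy(object)
  df <- dplyr::arrange(df, .data$cluster, dplyr::desc(.data$silhouette))
  df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$silhouette,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$avg_silhouette,
                        linetype = "dashed") +
    ggplot2::labs(x = "sample", y = "silhouette width", fill = "cluster",
                  title = sprintf("%s / %s (k = %d, ASW = %.3f)",
                                  object$tumor_type, object$gene_set,
                                  object$k, object$avg_silhouette)) +
    ggplot2::theme_minimal()
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the empirical joint distribution of labels,
#' normalized by the geometric mean of the two entropies:
#' `NMI = I(A;B) / sqrt(H(A) * H(B))`. A partition with a single cluster
#' has zero entropy and the NMI is defined as 0.
#'
#' @param a,b Cluster label vectors over the same samples (if both are
#'   named, they are aligned by name).
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("nmi: partitions are over different sample sets")
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("nmi: partitions have different lengths")
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- ent(pa)
  hb <- ent(pb)
  if (ha == 0 || hb == 0) return(0)
  outer_p <- outer(pa, pb)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  min(max(mi / sqrt(ha * hb), 0), 1)
}

#' Genes most differentially expressed between subtypes
#'
#' Kruskal-Wallis test of each gene's expression against the cluster
#' labels; genes constant across samples are untestable and assigned
#' `p = 1`. These are the genes shown in subtype heatmaps.
#'
#' @param expr Genes-by-samples matrix (typically restricted to the
#'   clustered gene set).
#' @param assignments Cluster labels, named by sample or aligned with the
#'   matrix columns.
#' @param genes Optional character vector restricting the genes tested.
#' @param top_n Number of genes returned (default 20); ties in p-value are
#'   broken by gene name.
#' @return Tibble with columns `gene`, `statistic`, `p_value`, sorted by
#'   ascending p-value, at most `top_n` rows.
#' @export
differential_genes <- function(expr, assignments, genes = NULL,
                               top_n = 20L) {
  if (!is.null(genes)) {
    expr <- expr[intersect(toupper(genes), rownames(expr)), , drop = FALSE]
  }
  if (!is.null(names(assignments))) {
    expr <- expr[, names(assignments), drop = FALSE]
  }
  cl <- factor(assignments)
  if (nlevels(cl) < 2L) stop("differential_genes: need at least 2 clusters")
  res <- purrr::map(rownames(expr), function(g) {
    x <- expr[g, ]
    if (max(x) == min(x)) {
      return(tibble::tibble(gene = g, statistic = NA_real_, p_value = 1))
    }
    kw <- stats::kruskal.test(x, cl)
    tibble::tibble(gene = g, statistic = unname(kw$statistic),
                   p_value = kw$p.value)
  })
  res <- dplyr::bind_rows(res)
  res <- dplyr::arrange(res, .data$p_value, .data$gene)
  utils::head(res, top_n)
}
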