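#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format (one set per line: name, description,
#' then gene symbols; no header) used by MSigDB-style collections. The
#' description field is discarded, gene symbols are uppercased, and duplicate
#' symbols within a line are removed.
#'
#' @param path Path to a GMT file.
#' @param collection Label stored in the `collection` column (defaults to the
#'   file name without extension).
#' @return A `geneset_collection`: a tibble with one row per set and columns
#'   `set` (character), `collection` (character) and `genes` (list of
#'   character vectors), in file order.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("SETA\tdesc\tg1\tG2\tG2", gmt)
#' read_gmt(gmt, collection = "demo")
#' @export
read_gmt <- function(path, collection = NULL) {
  stopifnot(file.exists(path))
  if (is.null(collection)) {
    collection <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_geneset_collection(
      tibble::tibble(set = character(), collection = character(),
                     genes = list()),
      source_path = path
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    bad <- which(n_fields < 3L)[1L]
    stop("malformed GMT line ", bad, " in '", path,
         "': expected >= 3 tab-separated fields, found ", n_fields[bad])
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    dup <- names_[duplicated(names_)][1L]
    stop("duplicate gene-set name '", dup, "' in '", path, "'")
  }
  genes <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  new_geneset_collection(
    tibble::tibble(set = names_, collection = collection, genes = genes),
    source_path = path
  )
}

new_geneset_collection <- function(tbl, source_path = NA_character_) {
  attr(tbl, "source_path") <- source_path
  class(tbl) <- c("geneset_collection", class(tbl))
  tbl
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]; the description column is written as `"na"`.
#'
#' @param sets A `geneset_collection` (or any tibble with `set` and `genes`
#'   columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::map2_chr(sets$set, sets$genes, function(nm, g) {
    paste(c(nm, "na", g), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Keep gene sets describing metabolic pathways themselves
#'
#' Retains sets whose name contains the substring `include`
#' (case-insensitively) and does not contain `exclude`. With the defaults
#' this keeps pathways of metabolism proper while dropping sets about the
#' *regulation* of metabolic processes, whose genes are signalling rather
#' than enzymatic.
#'
#' @param sets A `geneset_collection` tibble.
#' @param include,exclude Substrings matched case-insensitively against the
#'   set name (fixed strings, not regular expressions).
#' @return The filtered collection, input order preserved.
#' @examples
#' tbl <- tibble::tibble(
#'   set = c("KEGG_PYRUVATE_METABOLISM",
#'           "GOBP_REGULATION_OF_LIPID_METABOLIC_PROCESS"),
#'   collection = "demo", genes = list("A", "B"))
#' filter_metabolic(tbl)$set
#' @export
filter_metabolic <- function(sets, include = "metabol", exclude = "regul") {
  nm <- tolower(sets$set)
  keep <- grepl(include, nm, fixed = TRUE) & !grepl(exclude, nm, fixed = TRUE)
  dplyr::filter(sets, keep)
}

#' Restrict gene sets to the genes present in an expression matrix
#'
#' Intersects each set with the matrix row names (exact match after
#' uppercasing) and flags sets whose intersection is too small to define a
#' correlation distance between samples.
#'
#' @param sets A `geneset_collection` tibble.
#' @param gene_ids Character vector of (unique) matrix gene symbols.
#' @param min_genes Minimum usable intersection size; sets below it are
#'   flagged `usable = FALSE` and skipped by downstream clustering.
#' @param verbose Emit one message per set with its coverage fraction.
#' @return The collection with added columns `matrix_genes` (list),
#'   `n_matched`, `coverage` and `usable`.
#' @export
restrict_to_matrix <- function(sets, gene_ids, min_genes = 2L,
                               verbose = FALSE) {
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  gene_ids <- toupper(gene_ids)
  out <- dplyr::mutate(
    sets,
    matrix_genes = purrr::map(.data$genes, ~ intersect(.x, gene_ids)),
    n_matched = lengths(.data$matrix_genes),
    coverage = .data$n_matched / lengths(.data$genes),
    usable = .data$n_matched >= min_genes
  )
  if (verbose) {
    purrr::pwalk(list(out$set, out$coverage, out$usable),
                 function(s, cov, ok) {
      message(sprintf("gene set %s: coverage %.3f%s", s, cov,
                      if (ok) "" else " [unusable]"))
    })
  }
  out
}
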