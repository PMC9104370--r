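#' Read a genes-by-samples numeric matrix from TSV
#'
#' Expected dialect: first column holds gene (or miRNA / protein) symbols,
#' the header row holds sample IDs, and the body is numeric. Used for
#' expression (TPM-like), miRNA, methylation and RPPA matrices. Missing or
#' non-numeric cells are rejected: clustering and rank transforms assume a
#' complete matrix.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene symbols (uppercased) as row names and
#'   sample IDs as column names.
#' @export
read_matrix_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  ids <- toupper(tbl[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row IDs in '", path, "'")
  body <- tbl[, -1L, drop = FALSE]
  suppressWarnings(m <- vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(body)))
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in '", path, "'")
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop("missing value in '", path, "', row '", ids[bad], "'")
  }
  rownames(m) <- ids
  m
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  tbl <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read segmented copy-number data (SEG format)
#'
#' SEG is tab-separated with a header and columns ID, chrom, loc.start,
#' loc.end, num.mark, seg.mean; coordinates are 1-based inclusive and
#' segment means are on the log2-ratio scale.
#'
#' @param path Path to a SEG file.
#' @return Tibble with columns `sample`, `chrom`, `start`, `end`,
#'   `num_mark`, `seg_mean`.
#' @export
read_seg <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ccddid", progress = FALSE)
  names(tbl) <- c("sample", "chrom", "start", "end", "num_mark", "seg_mean")
  if (any(tbl$start > tbl$end)) {
    bad <- which(tbl$start > tbl$end)[1L]
    stop("malformed segment (start > end) at data row ", bad, " of '",
         path, "'")
  }
  tbl
}

#' Write segments in SEG format
#'
#' @param seg Tibble as returned by [read_seg()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  out <- seg
  names(out) <- c("ID", "chrom", "loc.start", "loc.end", "num.mark",
                  "seg.mean")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read somatic mutation calls (MAF-like TSV)
#'
#' Requires the columns Hugo_Symbol, Tumor_Sample_Barcode,
#' Variant_Classification and Protein_Change; a full MAF is accepted and
#' extra columns are ignored.
#'
#' @param path Path to the file.
#' @return Tibble with columns `gene`, `sample`, `variant_classification`,
#'   `protein_change`.
#' @export
read_maf <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
            "Protein_Change")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("'", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  tibble::tibble(
    gene = toupper(tbl$Hugo_Symbol),
    sample = tbl$Tumor_Sample_Barcode,
    variant_classification = tbl$Variant_Classification,
    protein_change = tbl$Protein_Change
  )
}

#' Read gene coordinates from a BED-like file
#'
#' Four tab-separated columns without header: chrom, start, end, gene.
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' inclusive convention used internally (and by SEG), i.e. `start + 1`.
#'
#' @param path Path to the BED file.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_bed_genes <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene"),
                         col_types = "cddc", progress = FALSE)
  tibble::tibble(
    gene = toupper(tbl$gene),
    chrom = tbl$chrom,
    start = tbl$start + 1,
    end = tbl$end
  )
}

#' Write gene coordinates as BED (0-based half-open)
#'
#' @param genes Tibble with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive, as from [read_bed_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_genes <- function(genes, path) {
  out <- tibble::tibble(chrom = genes$chrom, start = genes$start - 1,
                        end = genes$end, gene = genes$gene)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with header; a `sample` column plus survival columns
#' (`os_time`, `os_event`, `rfs_time`, `rfs_event`, any subset) and
#' arbitrary clinical covariates (categorical or continuous).
#'
#' @param path Path to the file.
#' @return Tibble, one row per sample.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         guess_max = 100000)
  if (!"sample" %in% names(tbl)) stop("'", path, "' lacks a 'sample' column")
  tbl
}
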