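#' Construct an expression matrix
#'
#' The package's core container: a numeric genes-by-samples matrix tagged with
#' its expression unit. TPM matrices must have columns summing to 1e6; FPKM and
#' TPM values must be non-negative and finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene identifiers) and colnames (sample identifiers).
#' @param unit one of \code{"FPKM"}, \code{"TPM"}, \code{"LOG2TPM"}.
#' @param cohort optional character vector (length = number of samples) giving
#'   a provenance label per sample, kept through merges.
#' @return an object of class \code{expr_matrix}: the matrix with attributes
#'   \code{unit} and \code{cohort}.
#' @export
expr_matrix <- function(values, unit = c("TPM", "FPKM", "LOG2TPM"),
                        cohort = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (unit %in% c("FPKM", "TPM") && any(values < 0))
    stop("negative values are not allowed for unit ", unit)
  if (unit == "TPM") {
    cs <- colSums(values)
    bad <- abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad))
      stop("TPM columns must sum to 1e6; offending samples: ",
           paste(utils::head(colnames(values)[bad], 5), collapse = ", "))
  }
  if (is.null(cohort)) cohort <- rep(NA_character_, ncol(values))
  if (length(cohort) != ncol(values))
    stop("`cohort` must have one entry per sample")
  structure(values, unit = unit, cohort = cohort, class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Subset an expression matrix, preserving unit and cohort labels
#' @param x an \code{expr_matrix}
#' @param i,j row (gene) and column (sample) indices
#' @param ... ignored
#' @param drop ignored; dimensions are always kept
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  unit <- attr(x, "unit"); cohort <- attr(x, "cohort")
  m <- unclass(x)
  attr(m, "unit") <- NULL; attr(m, "cohort") <- NULL
  if (missing(j)) {
    out <- m[i, , drop = FALSE]
  } else {
    if (is.character(j)) j <- match(j, colnames(m))
    cohort <- cohort[seq_len(ncol(m))[j]]
    out <- if (missing(i)) m[, j, drop = FALSE] else m[i, j, drop = FALSE]
  }
  # subsetting genes of a TPM matrix breaks the column-sum invariant, so the
  # result is returned as a plain tagged matrix without re-validation
  structure(out, unit = unit, cohort = cohort, class = "expr_matrix")
}

#' Expression unit of a matrix
#' @param x an \code{expr_matrix}
#' @return the unit tag string
#' @export
expr_unit <- function(x) attr(x, "unit")

#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Duplicate gene rows are collapsed by their mean (an
#' order-independent rule). Non-numeric cells and duplicated sample ids are
#' errors.
#'
#' @param path path to a tab-separated file.
#' @param unit declared unit of the stored values.
#' @return an \code{expr_matrix}.
#' @export
read_expression <- function(path, unit = c("TPM", "FPKM", "LOG2TPM")) {
  unit <- match.arg(unit)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) stop("expression TSV needs a gene column plus >= 1 sample")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1]], genes[bad[1]], samples[j]))
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(vals) <- unique(genes)
  } else {
    rownames(vals) <- genes
  }
  expr_matrix(vals, unit = unit)
}

#' Write an expression matrix as TSV
#' @param x an \code{expr_matrix}
#' @param path output path
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample j, \eqn{TPM_{ij} = FPKM_{ij} / \sum_i FPKM_{ij} \times 10^6},
#' so every column sums to one million.
#'
#' @param x an \code{expr_matrix} with unit FPKM.
#' @return an \code{expr_matrix} with unit TPM.
#' @export
fpkm_to_tpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_unit(x) != "FPKM") stop("input unit must be FPKM")
  cs <- colSums(x)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  vals <- sweep(unclass(x), 2, cs, "/") * 1e6
  expr_matrix(vals, unit = "TPM", cohort = attr(x, "cohort"))
}

#' Merge expression cohorts on their common genes
#'
#' Samples are concatenated; the gene set is the intersection across all
#' cohorts. Sample identifiers must be pairwise disjoint. Each sample keeps a
#' cohort provenance label (cohort names or positional labels).
#'
#' @param cohorts a named or unnamed list of \code{expr_matrix} objects, all
#'   with the same unit.
#' @param rescale if \code{TRUE}, gene-wise z-scale within each cohort before
#'   merging (off by default; the merged values then carry unit
#'   \code{"LOG2TPM"}-agnostic z-scores and the unit tag is kept from the
#'   inputs for bookkeeping only).
#' @return an \code{expr_matrix} whose \code{cohort} attribute records each
#'   sample's source.
#' @export
merge_cohorts <- function(cohorts, rescale = FALSE) {
  if (!is.list(cohorts) || length(cohorts) < 2)
    stop("need a list of >= 2 cohorts")
  units <- vapply(cohorts, expr_unit, "")
  if (length(unique(units)) != 1) stop("all cohorts must share one unit")
  labels <- names(cohorts)
  if (is.null(labels)) labels <- paste0("cohort", seq_along(cohorts))
  genes <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(genes) == 0) stop("cohorts share no genes")
  ids <- unlist(lapply(cohorts, colnames), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("sample id collision across cohorts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mats <- lapply(seq_along(cohorts), function(i) {
    m <- unclass(cohorts[[i]])[genes, , drop = FALSE]
    if (rescale) m <- t(scale(t(m)))
    m
  })
  merged <- do.call(cbind, mats)
  cohort <- rep(labels, vapply(cohorts, ncol, 0L))
  # merged panels (and z-scaling) void the per-column TPM sum, so construct
  # without TPM validation
  structure(merged, unit = if (rescale) "LOG2TPM" else units[1],
            cohort = cohort, class = "expr_matrix")
}
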