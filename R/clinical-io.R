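#' Standard MAF variant-classification vocabulary accepted by the package
#'
#' The usual somatic classes plus the non-coding ones; unknown strings are
#' rejected at read time so that downstream nonsynonymous filters are safe.
#' @format character vector
#' @export
maf_vocabulary <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site",
  "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA"
)

#' Variant classes counted as nonsynonymous for mutational burden
#' @format character vector
#' @export
nonsynonymous_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site"
)

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then tab-separated member genes.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line with fewer than 3 fields: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-like mutation table
#'
#' Requires at minimum the columns Hugo_Symbol, Tumor_Sample_Barcode and
#' Variant_Classification; classifications outside the standard vocabulary
#' are rejected.
#'
#' @param path tab-separated MAF file (comment lines starting with '#' are
#'   skipped).
#' @return a \code{data.frame} with columns \code{gene}, \code{sample_id},
#'   \code{variant_classification}.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE, sep = "\t",
                          colClasses = "character")
  needed <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stop("MAF is missing mandatory column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(gene = df$Hugo_Symbol,
                    sample_id = df$Tumor_Sample_Barcode,
                    variant_classification = df$Variant_Classification,
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(out$variant_classification), maf_vocabulary)
  if (length(unknown))
    stop("unknown Variant_Classification value(s): ",
         paste(unknown, collapse = ", "))
  out
}

#' Write a mutation table in MAF layout
#' @param m mutation table as returned by \code{\link{read_maf}}
#' @param path output path
#' @export
write_maf <- function(m, path) {
  df <- data.frame(Hugo_Symbol = m$gene,
                   Tumor_Sample_Barcode = m$sample_id,
                   Variant_Classification = m$variant_classification)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a per-sample clinical table
#'
#' Enforces the cohort-table contract: positive survival time, 0/1 event
#' indicator, positive age, sex in \{male, female\}, stage in
#' \{early, advanced\}, and Mandard tumor regression grade in 1..5 (or NA).
#'
#' @param df data.frame with columns sample_id, os_time, os_event, age, sex,
#'   stage, trg.
#' @return the validated data.frame (characters coerced to the declared
#'   types).
#' @export
validate_clinical <- function(df) {
  needed <- c("sample_id", "os_time", "os_event", "age", "sex", "stage", "trg")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.numeric(df$os_event)
  df$age <- as.numeric(df$age)
  df$trg <- suppressWarnings(as.integer(df$trg))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(!is.finite(df$os_time)) || any(df$os_time <= 0))
    stop("os_time must be positive")
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be positive")
  if (!all(df$sex %in% c("male", "female"))) stop("sex must be male/female")
  if (!all(df$stage %in% c("early", "advanced")))
    stop("stage must be early/advanced")
  bad <- !is.na(df$trg) & !(df$trg %in% 1:5)
  if (any(bad))
    stop("trg out of range 1..5 for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  df
}

#' Read a clinical TSV and validate it
#' @param path tab-separated clinical table
#' @return validated clinical \code{data.frame}
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  validate_clinical(df)
}

#' Write a clinical table as TSV
#' @param df clinical data.frame
#' @param path output path
#' @export
write_clinical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
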