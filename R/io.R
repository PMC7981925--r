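#' Normalize chromosome names to a single dialect
#'
#' Adds a leading "chr" where missing and unifies mitochondrial aliases
#' (MT, chrMT) to "chrM", so SV tables and BED files from different sources
#' agree.
#'
#' @param x Character vector of chromosome names.
#' @return Normalized character vector.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  has_prefix <- grepl("^chr", x, ignore.case = TRUE)
  x[has_prefix] <- sub("^chr", "chr", x[has_prefix], ignore.case = TRUE)
  x[!has_prefix] <- paste0("chr", x[!has_prefix])
  x[x %in% c("chrMT", "chrMt", "chrM")] <- "chrM"
  x
}

.stop_if_nonint <- function(x, what) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0) {
    stop(sprintf("non-integer %s at row %d: '%s'", what, bad[1], x[bad[1]]),
         call. = FALSE)
  }
  v
}

#' Coerce a caller-style data frame to the internal SV table
#'
#' Positions in the input are 1-based (SV caller convention) and converted to
#' the internal 0-based half-open system on read. SVs with both breakpoints at
#' identical coordinates carry no positional information and are dropped with
#' a warning. If no id column is mapped, sv_ids are assigned deterministically
#' in row order, so duplicated input rows yield distinct records.
#'
#' @param df Data frame with one row per SV.
#' @param column_mapping Named character vector mapping the required keys
#'   \code{sample, chrom1, pos1, chrom2, pos2} (and optional \code{sv_id},
#'   \code{sv_type}) to column names of \code{df}.
#' @param one_based Are input positions 1-based? Default TRUE.
#' @return Data frame with columns sv_id, sample_id, chrom1, pos1, chrom2,
#'   pos2, sv_type (0-based positions).
#' @export
as_sv_table <- function(df,
                        column_mapping = c(sample = "sample",
                                           chrom1 = "chrom1", pos1 = "pos1",
                                           chrom2 = "chrom2", pos2 = "pos2"),
                        one_based = TRUE) {
  req <- c("sample", "chrom1", "pos1", "chrom2", "pos2")
  miss_keys <- setdiff(req, names(column_mapping))
  if (length(miss_keys) > 0)
    stop("column_mapping lacks required keys: ", paste(miss_keys, collapse = ", "))
  for (k in names(column_mapping)) {
    col <- column_mapping[[k]]
    if (!col %in% names(df))
      stop(sprintf("mapped column '%s' (for '%s') not found in table", col, k),
           call. = FALSE)
  }
  pos1 <- .stop_if_nonint(df[[column_mapping[["pos1"]]]], "pos1")
  pos2 <- .stop_if_nonint(df[[column_mapping[["pos2"]]]], "pos2")
  off <- if (one_based) 1 else 0
  out <- data.frame(
    sv_id = if ("sv_id" %in% names(column_mapping))
      as.character(df[[column_mapping[["sv_id"]]]])
    else sprintf("sv%06d", seq_len(nrow(df))),
    sample_id = as.character(df[[column_mapping[["sample"]]]]),
    chrom1 = normalize_chrom(df[[column_mapping[["chrom1"]]]]),
    pos1 = pos1 - off,
    chrom2 = normalize_chrom(df[[column_mapping[["chrom2"]]]]),
    pos2 = pos2 - off,
    sv_type = if ("sv_type" %in% names(column_mapping))
      as.character(df[[column_mapping[["sv_type"]]]])
    else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(out$pos1 < 0) || any(out$pos2 < 0))
    stop("negative breakpoint position after coordinate conversion")
  degen <- out$chrom1 == out$chrom2 & out$pos1 == out$pos2
  if (any(degen)) {
    warning(sprintf("dropping %d degenerate SV(s) with identical breakpoints",
                    sum(degen)))
    out <- out[!degen, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a somatic SV table
#'
#' Delimited table with one row per SV (two breakpoints); adaptable from any
#' SV caller's output via \code{column_mapping}. Gzip-transparent.
#'
#' @inheritParams as_sv_table
#' @param path Path to a TSV (optionally gzipped).
#' @param sep Field separator (default tab).
#' @return See \code{\link{as_sv_table}}.
#' @export
read_sv_table <- function(path,
                          column_mapping = c(sample = "sample",
                                             chrom1 = "chrom1", pos1 = "pos1",
                                             chrom2 = "chrom2", pos2 = "pos2"),
                          one_based = TRUE, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  as_sv_table(df, column_mapping, one_based = one_based)
}

#' Breakpoints in long format
#'
#' Expands an SV table into one row per breakpoint (two per SV), with
#' \code{mate_index} 1 or 2.
#'
#' @param svs SV table from \code{\link{read_sv_table}}.
#' @return Data frame with sv_id, sample_id, mate_index, chrom, pos.
#' @export
sv_breakpoints <- function(svs) {
  data.frame(
    sv_id = rep(svs$sv_id, 2L),
    sample_id = rep(svs$sample_id, 2L),
    mate_index = rep(c(1L, 2L), each = nrow(svs)),
    chrom = c(svs$chrom1, svs$chrom2),
    pos = c(svs$pos1, svs$pos2),
    stringsAsFactors = FALSE
  )
}

#' Read a gene coordinate table
#'
#' BED-like TSV with columns gene_id, chrom, start, end, strand; coordinates
#' 0-based half-open. Gene ids must be unique, start < end, strand in {+,-}.
#'
#' @param path Path to the TSV.
#' @return Data frame of gene models.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  validate_genes(df[need])
}

#' @keywords internal
validate_genes <- function(genes) {
  genes$chrom <- normalize_chrom(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene table: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start >= genes$end))
    stop("gene with start >= end: ",
         genes$gene_id[which(genes$start >= genes$end)[1]])
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  genes
}

#' Read a gene-by-sample numeric matrix
#'
#' TSV with gene ids in the first column and sample ids in the header.
#' Ragged rows, duplicate gene or sample ids, and non-numeric cells are hard
#' errors. Gzip-transparent.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop(sprintf("ragged matrix file: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1]))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  gene_ids <- df[[1]]
  samples <- names(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in matrix header: ",
         samples[duplicated(samples)][1])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in matrix: ", gene_ids[duplicated(gene_ids)][1])
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
              dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1]]
    suppressWarnings(v <- as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & !(raw %in% c("NA", "")))
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                   gene_ids[bad[1]], samples[j], raw[bad[1]]))
    m[, j] <- v
  }
  m
}

#' Write a gene-by-sample matrix as TSV
#'
#' Inverse of \code{\link{read_matrix}}; round-trips values exactly at
#' default precision.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BED intervals
#'
#' 3+ column BED, interpreted as 0-based half-open per the BED standard; a
#' point at position end is not contained. start >= end is a hard error with
#' its line number. Gzip-transparent.
#'
#' @param path Path to a BED file.
#' @return Data frame with chrom, start, end, name.
#' @export
read_bed_intervals <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) stop("empty BED file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop(sprintf("BED line %d has fewer than 3 columns", which(ncols < 3)[1]))
  chrom <- normalize_chrom(vapply(parts, `[[`, "", 1L))
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end)))
    stop(sprintf("non-numeric BED coordinate at line %d",
                 which(is.na(start) | is.na(end))[1]))
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop(sprintf("BED interval with start >= end at line %d", bad[1]))
  name <- vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, "")
  name <- ifelse(is.na(name), paste0(chrom, ":", start, "-", end), name)
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

#' Read a sample-to-cancer-type table
#'
#' TSV with columns sample_id and cancer_type; sample ids must be unique.
#'
#' @param path Path to the TSV.
#' @return Data frame with sample_id, cancer_type.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "cancer_type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("sample annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotation: ",
         df$sample_id[duplicated(df$sample_id)][1])
  df[need]
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 0-based half-open intervals -> GRanges (1-based closed)
.gr_intervals <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# 0-based point positions -> width-1 GRanges
.gr_points <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1, width = 1))
}
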