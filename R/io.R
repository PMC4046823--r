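#' Read a peak file into a peak set
#'
#' Supports the formats peak callers commonly emit. All BED-family formats
#' are 0-based half-open; the MACS xls-style table is 1-based and converted
#' on read. The peak height is taken from the format's natural signal
#' field unless `height_column` overrides it:
#' \describe{
#'   \item{`bed3`}{chrom/start/end; height fixed at 1.}
#'   \item{`bed5`/`bed6`}{height = the `score` field (column 5).}
#'   \item{`narrowPeak`}{ENCODE narrowPeak; height = `signalValue`
#'     (column 7) by default; `height_column` may name `score`, `pValue`
#'     or `qValue` instead.}
#'   \item{`macs_xls`}{MACS tab table with `#` comment lines and a header
#'     row; height = the `pileup` column by default; starts converted
#'     1-based to 0-based.}
#' }
#'
#' @param path File path.
#' @param format One of `"auto"`, `"bed3"`, `"bed5"`, `"bed6"`,
#'   `"narrowPeak"`, `"macs_xls"`. `"auto"` decides from the extension
#'   (`.narrowPeak`, `.xls`) and otherwise from the column count.
#' @param height_column Optional column (name for `macs_xls`/`narrowPeak`,
#'   index for BED) supplying the height.
#' @param name Peak-set label; defaults to the file base name without
#'   extension.
#' @return A peak set (`GRanges` with `height`/`source`), unsorted peaks
#'   sorted; not normalized (see [normalize_peaks()]).
#' @export
read_peaks <- function(path, format = c("auto", "bed3", "bed5", "bed6",
                                        "narrowPeak", "macs_xls"),
                       height_column = NULL, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") format <- sniff_peak_format(path)
  if (format == "macs_xls") {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("chr", "start", "end")
    if (!all(need %in% names(tab))) {
      stop("MACS table must have columns chr/start/end: ", path)
    }
    hcol <- if (is.null(height_column)) "pileup" else height_column
    if (!hcol %in% names(tab)) {
      stop("height column '", hcol, "' not present in MACS table: ", path)
    }
    return(peak_set(tab$chr, tab$start - 1L, tab$end,
                    height = tab[[hcol]], name = name))
  }
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(
      path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer")
    )
    hcol <- if (is.null(height_column)) "signalValue" else height_column
    h <- S4Vectors::mcols(gr)[[hcol]]
    if (is.null(h)) stop("height column '", hcol, "' not in narrowPeak: ", path)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    h <- switch(format,
      bed3 = rep(1, length(gr)),
      {
        hc <- if (is.null(height_column)) "score" else height_column
        S4Vectors::mcols(gr)[[hc]]
      }
    )
    if (is.null(h)) {
      stop("declared format '", format, "' but no score field in: ", path)
    }
  }
  if (any(is.na(h))) stop("missing peak heights in: ", path)
  if (any(h < 0)) stop("negative peak heights in: ", path)
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           height = as.numeric(h), name = name)
}

sniff_peak_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (ext == "narrowpeak") return("narrowPeak")
  if (ext == "xls") return("macs_xls")
  first <- readLines(path, n = 50L)
  first <- first[nzchar(first) & !startsWith(first, "#")]
  if (!length(first)) stop("cannot detect format of empty file: ", path)
  nf <- length(strsplit(first[1], "\t", fixed = TRUE)[[1]])
  switch(as.character(nf),
    "3" = "bed3", "4" = "bed5", "5" = "bed5", "6" = "bed6",
    "10" = "narrowPeak",
    stop("cannot detect peak format (", nf, " columns): ", path)
  )
}

#' Write a peak set as BED6 with an exact-height sidecar
#'
#' The BED score field is the height rounded and clamped to the
#' conventional `[0, 1000]` range; because that is lossy, the exact
#' heights are also written to `<path>.heights.tsv` alongside the
#' coordinates.
#'
#' @param x A peak set.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(x, path) {
  df <- as_bed_df(x)
  bed <- data.frame(
    df$chrom, df$start, df$end,
    name = if (nrow(df)) df$source else character(0),
    score = pmin(pmax(round(df$height), 0), 1000),
    strand = rep(".", nrow(df))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(df, paste0(path, ".heights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TFBS catalog
#'
#' Accepts either a BED6 file whose name field is the matrix identifier,
#' or a UCSC `tfbsConsSites`-style dump (8 tab-separated columns:
#' bin, chrom, chromStart, chromEnd, name, score, strand, zScore). The
#' two are distinguished by column count.
#'
#' @param path File path.
#' @return A [tfbs_catalog()].
#' @export
read_tfbs <- function(path) {
  if (!file.exists(path)) stop("TFBS file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$matrix_id <- character(0)
    return(tfbs_catalog(gr))
  }
  nf <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  if (nf == 6L) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      tab[[1]], IRanges::IRanges(tab[[2]] + 1L, tab[[3]]),
      matrix_id = as.character(tab[[4]]),
      site_score = suppressWarnings(as.numeric(tab[[5]]))
    )
  } else if (nf == 8L) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      tab[[2]], IRanges::IRanges(tab[[3]] + 1L, tab[[4]]),
      matrix_id = as.character(tab[[5]]),
      site_score = suppressWarnings(as.numeric(tab[[8]]))
    )
  } else {
    stop("TFBS file must be BED6 (6 columns) or a tfbsConsSites dump ",
         "(8 columns); found ", nf, " columns: ", path)
  }
  tfbs_catalog(gr)
}

#' Read a TSS table
#'
#' Accepts a TSV with columns chrom, position (0-based), strand, gene_id
#' (header optional, detected from the first line), or a BED6 file of
#' 1 bp TSS features. For BED6 input the TSS is the feature's 5' end:
#' the start for `+` features, `end - 1` for `-` features. Duplicate
#' records are removed.
#'
#' @param path File path.
#' @return A `data.frame` with columns `chrom`, `position`, `strand`,
#'   `gene_id` suitable for [promoter_windows()].
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop("TSS file not found: ", path)
  lines <- readLines(path, n = 1L)
  if (!length(lines)) stop("empty TSS file: ", path)
  nf <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  header <- grepl("chrom", lines[1], fixed = TRUE)
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (nf == 6L && !header) {
    ## BED6: chrom start end name score strand
    strand <- as.character(tab[[6]])
    if (any(!strand %in% c("+", "-"))) {
      stop("TSS BED6 requires '+'/'-' strand on every record: ", path)
    }
    out <- data.frame(
      chrom = as.character(tab[[1]]),
      position = ifelse(strand == "+", tab[[2]], tab[[3]] - 1L),
      strand = strand,
      gene_id = as.character(tab[[4]]),
      stringsAsFactors = FALSE
    )
  } else if (nf == 4L) {
    names(tab) <- c("chrom", "position", "strand", "gene_id")
    tab$chrom <- as.character(tab$chrom)
    tab$gene_id <- as.character(tab$gene_id)
    out <- tab
  } else {
    stop("TSS file must be a 4-column TSV or BED6; found ", nf,
         " columns: ", path)
  }
  if (any(!out$strand %in% c("+", "-"))) {
    stop("missing or invalid strand in TSS table: ", path)
  }
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-TF candidate table or evaluation table as TSV
#'
#' @param x A `data.frame` (e.g. from [score_table()] or
#'   [evaluate_combinations()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
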