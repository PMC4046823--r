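#' Construct a peak set
#'
#' A peak set is a [GenomicRanges::GRanges] carrying one row per peak with a
#' numeric `height` metadata column (the peak caller's signal for the region)
#' and a `source` label. Coordinates supplied here follow the BED convention
#' (0-based start, half-open end) and are converted to the 1-based closed
#' representation that GRanges uses; all readers and writers in the package
#' perform the same conversion, so files round-trip exactly.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open (`start < end`,
#'   `start >= 0`).
#' @param height Non-negative numeric peak heights (recycled). ChIP-seq peak
#'   callers report this as pileup, signalValue or score depending on format.
#' @param name Label for the whole set (a caller tag such as `"M"`, or a
#'   fusion label such as `"M*C*T"`). Stored in `metadata(x)$name` and used
#'   as the default per-peak `source`.
#' @param source Optional per-peak source labels; defaults to `name`.
#'
#' @return A `GRanges` with metadata columns `height` and `source`, sorted by
#'   position.
#' @examples
#' ps <- peak_set("chr1", c(100, 250), c(300, 400), height = c(5, 9), name = "M")
#' normalize_peaks(ps)
#' @export
peak_set <- function(chrom, start, end, height = 1, name = "peaks",
                     source = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(start)
  if (n == 0L) {
    return(empty_peak_set(name))
  }
  if (length(end) != n) stop("start and end must have the same length")
  chrom <- rep_len(as.character(chrom), n)
  if (any(start < 0L)) {
    stop("peak start positions must be >= 0 (0-based coordinates)")
  }
  if (any(start >= end)) {
    stop("peak intervals must satisfy start < end (zero-length peaks rejected)")
  }
  height <- rep_len(as.numeric(height), n)
  if (any(!is.finite(height)) || any(height < 0)) {
    stop("peak heights must be finite and >= 0")
  }
  if (is.null(source)) source <- name
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    height = height,
    source = rep_len(as.character(source), n)
  )
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$name <- name
  gr
}

empty_peak_set <- function(name = "peaks") {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$height <- numeric(0)
  S4Vectors::mcols(gr)$source <- character(0)
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Name of a peak set
#' @param x A peak set `GRanges`.
#' @return The label stored at construction/fusion time (or `"peaks"`).
#' @export
peak_set_name <- function(x) {
  nm <- S4Vectors::metadata(x)$name
  if (is.null(nm)) "peaks" else nm
}

`peak_set_name<-` <- function(x, value) {
  S4Vectors::metadata(x)$name <- value
  x
}

#' Do two genomic intervals overlap?
#'
#' Overlap on the half-open convention: intervals that merely abut share no
#' base and do not overlap. Both arguments are length-1 `GRanges` (or
#' peak sets of length 1); strand is ignored.
#'
#' @param a,b Length-1 `GRanges`.
#' @return `TRUE` iff the two intervals share at least one base on the same
#'   chromosome.
#' @export
interval_overlaps <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b)) &&
    GenomicRanges::start(a) <= GenomicRanges::end(b) &&
    GenomicRanges::start(b) <= GenomicRanges::end(a)
}

#' Merge overlapping peaks within one set
#'
#' Peak callers can emit mutually overlapping peaks; downstream set algebra
#' (union/intersection fusion, annotation counting) assumes each set covers
#' every base at most once. `normalize_peaks` merges overlapping peaks into
#' single peaks spanning their union, leaving the set of covered bases
#' unchanged. Abutting peaks share no base and are left separate. The merged
#' peak's height is the maximum of the contributing heights by default
#' (strongest single-caller evidence; `"sum"` would double-count overlapping
#' signal but is available).
#'
#' @param x A peak set.
#' @param height_rule `"max"` (default) or `"sum"`: how heights of merged
#'   contributors combine.
#' @return A normalized peak set: sorted, no two peaks overlap, same covered
#'   bases as the input. Idempotent.
#' @export
normalize_peaks <- function(x, height_rule = c("max", "sum")) {
  height_rule <- match.arg(height_rule)
  if (length(x) == 0L) return(x)
  comb <- switch(height_rule, max = max, sum = sum)
  sq <- GenomicRanges::seqnames(x)
  m <- merge_intervals(
    rep.int(as.character(S4Vectors::runValue(sq)), S4Vectors::runLength(sq)),
    GenomicRanges::start(x), GenomicRanges::end(x), x$height,
    comb = comb, merge_abutting = FALSE
  )
  build_peak_set(m, GenomeInfoDb::seqinfo(x), peak_set_name(x))
}

## Merge overlapping (optionally also abutting) intervals given as plain
## 1-based closed coordinate vectors, aggregating heights with `comb`.
## Doing this on extracted vectors, with the result GRanges built exactly
## once, keeps the per-call cost low enough for the pipeline's many small
## fusion operations; correctness is pinned by the per-base oracle tests.
merge_intervals <- function(ch, s, e, h, comb, merge_abutting = FALSE) {
  o <- order(ch, s, e, method = "radix")
  ch <- ch[o]; s <- s[o]; e <- e[o]; h <- h[o]
  n <- length(s)
  ## running max end within each chromosome block
  cme <- e
  for (bl in split(seq_len(n), ch)) cme[bl] <- cummax(e[bl])
  prev_max <- c(-Inf, cme[-n])
  gap_ok <- if (merge_abutting) s > prev_max + 1 else s > prev_max
  new_grp <- c(TRUE, ch[-1] != ch[-n]) | gap_ok
  grp <- cumsum(new_grp)
  ends_at <- c(which(new_grp)[-1] - 1L, n)
  list(
    ch = ch[new_grp],
    s = s[new_grp],
    e = cme[ends_at],
    h = vapply(split(h, grp), comb, numeric(1), USE.NAMES = FALSE)
  )
}

build_peak_set <- function(m, seqinfo, name) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(m$ch, levels = GenomeInfoDb::seqlevels(seqinfo)),
    ranges = IRanges::IRanges(m$s, m$e),
    height = m$h,
    source = rep(name, length(m$s)),
    seqinfo = seqinfo
  )
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Total bases covered by a peak set
#' @param x A peak set.
#' @return Integer number of covered bases (bp), counting each base once.
#' @export
coverage_bases <- function(x) {
  if (length(x) == 0L) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(x, ignore.strand = TRUE)))
}

#' Convert a peak set to a BED-convention data frame
#'
#' @param x A peak set.
#' @return A `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (half-open), `height`, `source`.
#' @export
as_bed_df <- function(x) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    height = if (length(x)) x$height else numeric(0),
    source = if (length(x)) x$source else character(0),
    stringsAsFactors = FALSE
  )
}
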