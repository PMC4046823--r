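#' Combinatorial fusion of peak sets
#'
#' Two ways of combining peak sets from different callers, written `"+"`
#' (union) and `"*"` (intersection) in fusion labels:
#'
#' * **Union** keeps every base covered by either input. Peaks that overlap
#'   across the inputs merge into compound regions; peaks private to one
#'   caller keep their position. Union trades specificity for sensitivity.
#' * **Intersection** keeps only bases covered by both inputs, emitting each
#'   maximal jointly-covered fragment as one peak. Intersection demands
#'   agreement between callers and so filters caller-private (likely false
#'   positive) peaks.
#'
#' Both operate at coverage level, which makes them associative and
#' commutative: `M*C*T` means the bases all three callers agree on,
#' regardless of evaluation order.
#'
#' @param a,b Normalized peak sets (see [normalize_peaks()]).
#' @param height_rule How the fused peak's height combines the contributing
#'   peaks' heights. Union defaults to `"max"` (strongest single evidence);
#'   intersection defaults to `"min"` (conservative joint evidence, the
#'   weakest caller that still supports the fragment). A fragment spanning
#'   several peaks of one input combines over all overlapping contributors.
#' @return A normalized peak set labelled `"a+b"` / `"a*b"` from the input
#'   set names.
#' @examples
#' m <- peak_set("chr1", 100, 300, height = 5, name = "M")
#' c <- peak_set("chr1", 250, 400, height = 9, name = "C")
#' union_fuse(m, c)      # one compound peak [100,400), height 9
#' intersect_fuse(m, c)  # the agreed fragment [250,300), height 5
#' @name fusion
NULL

#' @rdname fusion
#' @export
union_fuse <- function(a, b, height_rule = c("max", "sum")) {
  height_rule <- match.arg(height_rule)
  comb <- switch(height_rule, max = max, sum = sum)
  label <- paste0(peak_set_name(a), "+", peak_set_name(b))
  ab <- align_seqlevels(a, b)
  a <- ab[[1]]; b <- ab[[2]]
  sqa <- GenomicRanges::seqnames(a)
  sqb <- GenomicRanges::seqnames(b)
  m <- merge_intervals(
    c(rep.int(as.character(S4Vectors::runValue(sqa)), S4Vectors::runLength(sqa)),
      rep.int(as.character(S4Vectors::runValue(sqb)), S4Vectors::runLength(sqb))),
    c(GenomicRanges::start(a), GenomicRanges::start(b)),
    c(GenomicRanges::end(a), GenomicRanges::end(b)),
    c(a$height, b$height),
    comb = comb, merge_abutting = FALSE
  )
  build_peak_set(m, GenomeInfoDb::seqinfo(a), label)
}

#' @rdname fusion
#' @export
intersect_fuse <- function(a, b, height_rule = c("min", "max")) {
  height_rule <- match.arg(height_rule)
  comb <- switch(height_rule, min = min, max = max)
  label <- paste0(peak_set_name(a), "*", peak_set_name(b))
  ab <- align_seqlevels(a, b)
  a <- ab[[1]]; b <- ab[[2]]
  ## coverage intersection: clip every overlapping pair, then merge the
  ## clips (abutting clips included) into maximal jointly-covered fragments.
  ## Every source peak overlapping a fragment contributes at least one of
  ## the fragment's clips, so aggregating the per-pair combined heights over
  ## a fragment's clips equals aggregating over all overlapping source peaks.
  ov <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  if (length(ov) == 0L) return(empty_peak_set(label))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  sqa <- GenomicRanges::seqnames(a)
  ch <- rep.int(as.character(S4Vectors::runValue(sqa)),
                S4Vectors::runLength(sqa))[qh]
  pair_h <- switch(height_rule,
    min = pmin(a$height[qh], b$height[sh]),
    max = pmax(a$height[qh], b$height[sh])
  )
  m <- merge_intervals(
    ch,
    pmax(GenomicRanges::start(a)[qh], GenomicRanges::start(b)[sh]),
    pmin(GenomicRanges::end(a)[qh], GenomicRanges::end(b)[sh]),
    pair_h,
    comb = comb, merge_abutting = TRUE
  )
  build_peak_set(m, GenomeInfoDb::seqinfo(a), label)
}

align_seqlevels <- function(a, b) {
  la <- GenomeInfoDb::seqlevels(a)
  lb <- GenomeInfoDb::seqlevels(b)
  if (identical(la, lb)) return(list(a, b))
  lev <- union(la, lb)
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a, b)
}

#' Parse a fusion expression label
#'
#' A fusion expression is a label such as `"M*C*T"` or `"M+C+T"`: at least
#' two peak-set names joined by a single operator, `"*"` for intersection or
#' `"+"` for union. Mixed expressions such as `"(M*C)+T"` are not parsed;
#' compose [union_fuse()] / [intersect_fuse()] calls directly for those.
#'
#' @param label Character scalar.
#' @return A list with elements `operator` (`"union"` or `"intersection"`),
#'   `operands` (character vector of set names) and `label`.
#' @export
fusion_expr <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  has_u <- grepl("+", label, fixed = TRUE)
  has_i <- grepl("*", label, fixed = TRUE)
  if (has_u && has_i) {
    stop("mixed fusion expressions are not supported: ", label,
         " (compose union_fuse()/intersect_fuse() calls instead)")
  }
  if (!has_u && !has_i) {
    stop("fusion expression needs at least two operands joined by '+' or '*': ",
         label)
  }
  op <- if (has_i) "intersection" else "union"
  operands <- strsplit(label, if (has_i) "*" else "+", fixed = TRUE)[[1]]
  operands <- trimws(operands)
  if (length(operands) < 2L || any(!nzchar(operands))) {
    stop("fusion expression needs at least two non-empty operands: ", label)
  }
  list(operator = op, operands = operands, label = label)
}

#' Evaluate a fusion expression over named peak sets
#'
#' Left-fold of the binary operator over the operands; because both
#' operators are associative and commutative at coverage level the operand
#' order does not affect the covered bases.
#'
#' @param expr A label string or the result of [fusion_expr()].
#' @param sets Named list of normalized peak sets.
#' @param union_height,intersect_height Height rules passed through to
#'   [union_fuse()] / [intersect_fuse()].
#' @return The fused, normalized peak set, named with the canonical label.
#' @examples
#' sets <- list(
#'   M = peak_set("chr1", 100, 300, height = 5, name = "M"),
#'   C = peak_set("chr1", 250, 400, height = 9, name = "C")
#' )
#' fuse("M*C", sets)
#' @export
fuse <- function(expr, sets, union_height = "max", intersect_height = "min") {
  if (is.character(expr)) expr <- fusion_expr(expr)
  missing <- setdiff(expr$operands, names(sets))
  if (length(missing)) {
    stop("unknown peak set(s) in fusion expression '", expr$label, "': ",
         paste(missing, collapse = ", "))
  }
  f <- switch(expr$operator,
    union = function(a, b) union_fuse(a, b, height_rule = union_height),
    intersection = function(a, b) intersect_fuse(a, b, height_rule = intersect_height)
  )
  out <- Reduce(f, sets[expr$operands])
  peak_set_name(out) <- expr$label
  if (length(out)) out$source <- rep(expr$label, length(out))
  out
}
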