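#' Precision indices from annotation counts
#'
#' Four percentage indices summarize how enriched a peak set is for
#' plausibly functional regions, computed from the six counts of
#' [count_summary()]:
#'
#' * `f_prom`  — promoter peaks / all peaks: fraction of peaks in promoter
#'   windows;
#' * `f_tfbs`  — TFBS peaks / all peaks: fraction of peaks overlapping at
#'   least one binding site;
#' * `f_tp_p`  — TFBS promoter peaks / promoter peaks;
#' * `f_tp_t`  — TFBS promoter peaks / TFBS peaks;
#'
#' and `ap`, their arithmetic mean ("average precision" in the
#' caller-comparison sense, not the information-retrieval quantity). All
#' five are percentages in `[0, 100]`; `ap` is computed on the unrounded
#' indices. For display, values are conventionally rounded
#' half-away-from-zero to 1 decimal ([round_half_up()]); `ap` can differ
#' by 0.1 from the mean of the pre-rounded indices, which is why it is
#' always derived from the unrounded ones.
#'
#' @param counts A one-row `data.frame` (or coercible list) with the six
#'   [count_summary()] columns.
#' @return A one-row `data.frame` with columns `f_prom`, `f_tfbs`,
#'   `f_tp_p`, `f_tp_t`, `ap` (unrounded percentages).
#' @examples
#' indices_from_counts(data.frame(
#'   n_peaks_total = 53972, n_peaks_promoter = 10282,
#'   n_tfbs_peaks_total = 15428, n_tfbs_peaks_promoter = 3934,
#'   n_tfbs_total = 110779, n_tfbs_promoter = 27615
#' ))
#' @export
indices_from_counts <- function(counts) {
  counts <- as.data.frame(counts)
  req <- c("n_peaks_total", "n_peaks_promoter", "n_tfbs_peaks_total",
           "n_tfbs_peaks_promoter")
  if (!all(req %in% names(counts))) {
    stop("counts need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(counts) != 1L) stop("counts must be a single row")
  for (d in c("n_peaks_total", "n_peaks_promoter", "n_tfbs_peaks_total")) {
    if (counts[[d]] == 0) {
      stop("index undefined: zero denominator '", d, "'")
    }
  }
  f_prom <- 100 * counts$n_peaks_promoter / counts$n_peaks_total
  f_tfbs <- 100 * counts$n_tfbs_peaks_total / counts$n_peaks_total
  f_tp_p <- 100 * counts$n_tfbs_peaks_promoter / counts$n_peaks_promoter
  f_tp_t <- 100 * counts$n_tfbs_peaks_promoter / counts$n_tfbs_peaks_total
  data.frame(
    f_prom = f_prom, f_tfbs = f_tfbs, f_tp_p = f_tp_p, f_tp_t = f_tp_t,
    ap = (f_prom + f_tfbs + f_tp_p + f_tp_t) / 4
  )
}

#' Round half away from zero
#'
#' Commercial rounding: 0.05 at the last kept digit rounds up in
#' magnitude, unlike [round()]'s round-half-to-even. Used when formatting
#' index tables so printed values match the usual reporting convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate individual callers and fusion combinations
#'
#' Runs the full comparison: every named input set, plus every fusion
#' expression, is fused (where applicable), annotated against the TFBS
#' catalog and promoter model, counted, and converted to precision
#' indices — one row per strategy. This is the table on which competing
#' peak callers and union/intersection strategies are compared.
#'
#' @param sets Named list of normalized peak sets.
#' @param exprs Character vector of fusion labels (see [fusion_expr()]);
#'   may be empty.
#' @param catalog A [tfbs_catalog()].
#' @param promoters Promoter windows from [promoter_windows()].
#' @param ... Passed to [fuse()].
#' @return A `data.frame` with a `label` column, the six count columns and
#'   the five index columns; one row per individual set and per expression.
#' @export
evaluate_combinations <- function(sets, exprs, catalog, promoters, ...) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  labels <- c(names(sets), exprs)
  rows <- lapply(labels, function(lab) {
    ps <- if (lab %in% names(sets)) sets[[lab]] else fuse(lab, sets, ...)
    cnt <- count_summary(annotate_peaks(ps, catalog, promoters))
    cbind(data.frame(label = lab, stringsAsFactors = FALSE),
          cnt, indices_from_counts(cnt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published SUMO-1 ChIP-seq benchmark counts
#'
#' The peak-feature counts reported for a SUMO-1 ChIP-seq experiment in
#' BCBL-1 cells analysed with four peak callers — MACS (M), CisGenome (C),
#' T-PIC (T) and BayesPeak (B) — and the union (`+`) and intersection
#' (`*`) fusions of the top three. Shipped as a plain-text table so the
#' index arithmetic of [indices_from_counts()] can be exercised on
#' genome-scale numbers without the (undeposited) raw data.
#'
#' @return A `data.frame` with columns `label` and the six
#'   [count_summary()] count columns, one row per strategy.
#' @export
sumo1_benchmark_counts <- function() {
  path <- system.file("extdata", "sumo1_bcbl1_counts.tsv",
                      package = "peakfusion", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
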