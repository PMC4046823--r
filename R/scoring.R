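#' Per-TF score from annotated peaks
#'
#' For factor `i` with catalog site set `TB_i`, the score is
#'
#' \deqn{S_i = \Big(\sum_{p \in P_i} h_p\Big) \times \frac{|TB_i \cap D|}{|TB_i|}}
#'
#' where `P_i` is the set of distinct peaks overlapping at least one site of
#' `TB_i`, `h_p` the peak height, and `|TB_i ∩ D|` the number of sites of
#' `TB_i` overlapped by any peak. Tall peaks over a factor's sites raise the
#' score; the weight discounts factors for which only a small fraction of
#' their genome-wide sites are covered, so abundant-motif factors are not
#' favoured merely for having many sites.
#'
#' Under `peak_sum = "per_peak"` (default) each peak contributes its height
#' once per factor even if it covers several of that factor's sites; under
#' `"per_site"` every (peak, site) overlap pair contributes, so a peak
#' spanning k sites counts k times.
#'
#' @param ann An [annotate_peaks()] result.
#' @param matrix_id Optional character vector restricting output to given
#'   factors (must exist in the catalog and have `|TB_i| > 0`).
#' @param peak_sum `"per_peak"` or `"per_site"`; see above.
#' @return A `data.frame` with columns `matrix_id`, `tf_name`, `score`,
#'   one row per factor (all catalog factors by default).
#' @export
score_tfs <- function(ann, matrix_id = NULL,
                      peak_sum = c("per_peak", "per_site")) {
  stopifnot(inherits(ann, "annotated_peaks"))
  peak_sum <- match.arg(peak_sum)
  cat <- ann$catalog
  ids <- if (is.null(matrix_id)) cat$tf_ids else as.character(matrix_id)
  unknown <- setdiff(ids, cat$tf_ids)
  if (length(unknown)) {
    stop("matrix id(s) not in catalog (|TB_i| undefined): ",
         paste(unknown, collapse = ", "))
  }
  heights <- ann$peaks$height
  hits <- ann$hits
  hits$matrix_id <- factor(hits$matrix_id, levels = cat$tf_ids)
  peak_height_sum <- if (peak_sum == "per_peak") {
    vapply(split(hits$peak, hits$matrix_id),
           function(p) sum(heights[unique(p)]), numeric(1))
  } else {
    vapply(split(hits$peak, hits$matrix_id),
           function(p) sum(heights[p]), numeric(1))
  }
  n_sites_hit <- vapply(split(hits$site, hits$matrix_id),
                        function(s) length(unique(s)), numeric(1))
  s <- peak_height_sum * (n_sites_hit / as.numeric(cat$sites_per_tf))
  out <- data.frame(
    matrix_id = cat$tf_ids,
    tf_name = matrix_id_to_tf_name(cat$tf_ids),
    score = unname(s),
    stringsAsFactors = FALSE
  )
  out[match(ids, out$matrix_id), , drop = FALSE]
}

#' Rank TFs by score
#'
#' Rank 1 is the highest score; ties are broken by matrix id in
#' lexicographic order, so ranking is deterministic and ranks are always a
#' permutation of `1..N`.
#'
#' @param scores A `data.frame` with columns `matrix_id` and `score`
#'   (e.g. from [score_tfs()]).
#' @return The input with a `rank` column added, sorted by rank.
#' @export
rank_tfs <- function(scores) {
  stopifnot(all(c("matrix_id", "score") %in% names(scores)))
  ord <- order(-scores$score, scores$matrix_id)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Hampel identifier constants, computed from their definitions
#'
#' The MAD-to-sigma divisor is the 0.75 quantile of the standard normal
#' distribution (so that MADN estimates the standard deviation under
#' normality), reported to 4 decimals; the outlier cutoff is the square
#' root of the 0.975 quantile of the chi-square distribution with one
#' degree of freedom (a two-sided 5% rule on a squared standardized
#' deviation), reported to 2 decimals.
#'
#' @return A list with `madn_divisor` (0.6745) and `cutoff` (2.24), both
#'   computed from [stats::qnorm()] / [stats::qchisq()], not hard-coded.
#' @export
hampel_constants <- function() {
  list(
    madn_divisor = round(stats::qnorm(0.75), 4),
    cutoff = round(sqrt(stats::qchisq(0.975, df = 1)), 2)
  )
}

#' Flag outlying TF scores with the Hampel identifier
#'
#' A robust outlier rule: with `M` the median score, `MAD` the median of
#' `|S_i - M|` and `MADN = MAD / 0.6745`, the statistic `|S_i - M| / MADN`
#' is compared against the cutoff 2.24. Median and MAD resist masking by
#' the very outliers being sought, which a mean/sd z-score does not. When
#' `MAD = 0` (at least half the scores equal the median) the statistic
#' degenerates; the limit behaviour is used: any score different from the
#' median is flagged (statistic `Inf`), scores at the median are not
#' (statistic 0).
#'
#' @param scores A `data.frame` with columns `matrix_id` and `score`, of at
#'   least 2 rows.
#' @param cutoff,madn_divisor Constants; default to the computed values of
#'   [hampel_constants()].
#' @return The input with columns `hampel` (the statistic) and `candidate`
#'   (`hampel > cutoff`, strict) added.
#' @examples
#' s <- data.frame(matrix_id = letters[1:5], score = c(10, 12, 11, 13, 50))
#' hampel_identify(s)
#' @export
hampel_identify <- function(scores, cutoff = NULL, madn_divisor = NULL) {
  stopifnot(all(c("matrix_id", "score") %in% names(scores)))
  if (nrow(scores) < 2L) {
    stop("Hampel identifier needs at least 2 scores")
  }
  const <- hampel_constants()
  if (is.null(cutoff)) cutoff <- const$cutoff
  if (is.null(madn_divisor)) madn_divisor <- const$madn_divisor
  stopifnot(cutoff >= 0, madn_divisor > 0)
  s <- scores$score
  m <- stats::median(s)
  dev <- abs(s - m)
  mad <- stats::median(dev)
  if (mad == 0) {
    stat <- ifelse(dev > 0, Inf, 0)
  } else {
    stat <- dev / (mad / madn_divisor)
  }
  scores$hampel <- stat
  scores$candidate <- stat > cutoff
  scores
}

#' Score, rank and flag candidate TFs in one step
#'
#' Convenience wrapper running [score_tfs()], [rank_tfs()] and
#' [hampel_identify()]: the per-factor candidate table for a peak set
#' (typically a fused set such as `M*C*T`), sorted by rank.
#'
#' @inheritParams score_tfs
#' @inheritParams hampel_identify
#' @return A `data.frame` with columns `rank`, `matrix_id`, `tf_name`,
#'   `score`, `hampel`, `candidate`.
#' @export
score_table <- function(ann, peak_sum = "per_peak", cutoff = NULL,
                        madn_divisor = NULL) {
  sc <- score_tfs(ann, peak_sum = peak_sum)
  sc <- hampel_identify(sc, cutoff = cutoff, madn_divisor = madn_divisor)
  sc <- rank_tfs(sc)
  sc[, c("rank", "matrix_id", "tf_name", "score", "hampel", "candidate")]
}
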