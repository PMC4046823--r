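#' TFBS catalog
#'
#' A catalog of transcription factor binding sites (TFBS), one record per
#' site, keyed by a TRANSFAC-style matrix identifier (e.g. `"V$ELK1_02"`).
#' The genome-wide UCSC `tfbsConsSites` track is the archetype: several
#' million conserved sites for a few hundred factors. For each factor
#' `i` the catalog holds its site set `TB_i`; the per-factor score in
#' [score_tfs()] divides by `|TB_i|`, so the catalog defines the scoring
#' universe.
#'
#' @param sites A `GRanges` with metadata column `matrix_id` (non-empty
#'   strings) and optionally `tf_name` and `site_score`. If `tf_name` is
#'   absent it is derived from the matrix id via [matrix_id_to_tf_name()].
#' @return An object of class `tfbs_catalog`: list with `sites` (the
#'   `GRanges`), `by_tf` (site indices per matrix id), `tf_ids`,
#'   `sites_per_tf` (named counts `|TB_i|`) and `tf_count`.
#' @export
tfbs_catalog <- function(sites) {
  stopifnot(is(sites, "GRanges"))
  if (is.null(sites$matrix_id)) stop("catalog sites need a 'matrix_id' column")
  mid <- as.character(sites$matrix_id)
  if (length(sites) && any(is.na(mid) | !nzchar(mid))) {
    stop("matrix_id must be non-empty for every site")
  }
  if (is.null(sites$tf_name)) sites$tf_name <- matrix_id_to_tf_name(mid)
  tf_ids <- sort(unique(mid))
  by_tf <- split(seq_along(sites), factor(mid, levels = tf_ids))
  structure(
    list(
      sites = sites,
      by_tf = by_tf,
      tf_ids = tf_ids,
      sites_per_tf = lengths(by_tf),
      tf_count = length(tf_ids)
    ),
    class = "tfbs_catalog"
  )
}

#' @export
print.tfbs_catalog <- function(x, ...) {
  cat("TFBS catalog:", length(x$sites), "sites for", x$tf_count,
      "TF matrices\n")
  invisible(x)
}

#' Display name of a TF from its matrix identifier
#'
#' `"V$ELK1_02"` names matrix 02 of factor ELK1: the leading `"V$"` library
#' prefix and the trailing `"_NN"` matrix suffix are stripped to obtain the
#' factor's display name.
#'
#' @param matrix_id Character vector of matrix identifiers.
#' @return Character vector of TF display names.
#' @examples
#' matrix_id_to_tf_name(c("V$ELK1_02", "V$CREB_Q2", "NFY_01"))
#' @export
matrix_id_to_tf_name <- function(matrix_id) {
  out <- sub("^V\\$", "", as.character(matrix_id))
  sub("_[^_]*$", "", out)
}

#' Promoter windows around transcription start sites
#'
#' The promoter of a gene is modelled as a fixed window around its TSS:
#' `upstream` bases 5' of the TSS plus `downstream` bases starting at the
#' TSS, oriented by strand (the default 5000/1000 gives the widely used
#' "5 kb upstream to 1 kb downstream" definition). Windows are clamped at
#' the chromosome start. Duplicate TSS records (same chromosome, position
#' and strand) are collapsed before window construction.
#'
#' @param tss A `data.frame` with columns `chrom`, `position` (0-based TSS
#'   coordinate), `strand` (`"+"` or `"-"`), and optionally `gene_id`.
#' @param upstream,downstream Window extents in bp (>= 0).
#' @return A `GRanges` of promoter windows with a `gene_id` column.
#' @examples
#' promoter_windows(data.frame(
#'   chrom = "chr1", position = 10000, strand = "+", gene_id = "G1"
#' ))
#' @export
promoter_windows <- function(tss, upstream = 5000, downstream = 1000) {
  stopifnot(upstream >= 0, downstream >= 0)
  req <- c("chrom", "position", "strand")
  if (!all(req %in% names(tss))) {
    stop("TSS table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(!tss$strand %in% c("+", "-"))) {
    stop("TSS strand must be '+' or '-'")
  }
  if (is.null(tss$gene_id)) {
    tss$gene_id <- sprintf("gene%d", seq_len(nrow(tss)))
  }
  tss <- tss[!duplicated(tss[, req]), , drop = FALSE]
  if (nrow(tss) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    return(gr)
  }
  pos1 <- as.integer(tss$position) + 1L
  site <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(pos1, pos1), strand = tss$strand,
    gene_id = as.character(tss$gene_id)
  )
  win <- suppressWarnings(
    GenomicRanges::promoters(site, upstream = upstream, downstream = downstream)
  )
  GenomicRanges::start(win) <- pmax(GenomicRanges::start(win), 1L)
  win
}

#' Annotate peaks with promoter membership and TFBS overlaps
#'
#' Core annotation step: every peak is tested for (a) overlap with any
#' promoter window and (b) overlap with every catalog binding site. A
#' single shared base suffices for either (no minimum-overlap fraction, no
#' containment requirement); strand is ignored throughout, as ChIP peaks
#' are unstranded.
#'
#' @param peaks A normalized peak set.
#' @param catalog A [tfbs_catalog()] (may be empty).
#' @param promoters A `GRanges` of promoter windows from
#'   [promoter_windows()] (may be empty).
#' @return An object of class `annotated_peaks`: list with
#'   \describe{
#'     \item{peaks}{the input `GRanges` with an added logical `in_promoter`
#'       column,}
#'     \item{hits}{a `data.frame` of all (peak, site) overlap pairs with
#'       columns `peak`, `site`, `matrix_id`,}
#'     \item{per_tf_sites}{for each matrix id, the indices of its catalog
#'       sites overlapped by at least one peak,}
#'     \item{catalog}{the catalog.}
#'   }
#' @export
annotate_peaks <- function(peaks, catalog, promoters) {
  stopifnot(inherits(catalog, "tfbs_catalog"))
  pp <- align_seqlevels(peaks, promoters)
  in_prom <- IRanges::overlapsAny(pp[[1]], pp[[2]], ignore.strand = TRUE)
  ps <- align_seqlevels(peaks, catalog$sites)
  ov <- GenomicRanges::findOverlaps(ps[[1]], ps[[2]], ignore.strand = TRUE)
  hits <- data.frame(
    peak = S4Vectors::queryHits(ov),
    site = S4Vectors::subjectHits(ov),
    matrix_id = as.character(catalog$sites$matrix_id[S4Vectors::subjectHits(ov)]),
    stringsAsFactors = FALSE
  )
  per_tf <- lapply(
    split(hits$site, factor(hits$matrix_id, levels = catalog$tf_ids)),
    function(s) sort(unique(s))
  )
  peaks$in_promoter <- in_prom
  structure(
    list(peaks = peaks, hits = hits, per_tf_sites = per_tf, catalog = catalog),
    class = "annotated_peaks"
  )
}

#' @export
print.annotated_peaks <- function(x, ...) {
  cat("Annotated peak set '", peak_set_name(x$peaks), "': ",
      length(x$peaks), " peaks, ", sum(x$peaks$in_promoter),
      " in promoters, ", length(unique(x$hits$site)),
      " TFBS overlapped\n", sep = "")
  invisible(x)
}

#' Summary counts of an annotated peak set
#'
#' The six counts that characterize a caller or fusion strategy, mirroring
#' a "Total / Promoter" peak-feature table:
#' total peaks; promoter peaks (overlap a promoter window); TFBS peaks
#' (overlap at least one binding site), overall and restricted to promoter
#' peaks; and distinct binding sites overlapped, overall and by promoter
#' peaks. A site is counted once however many peaks hit it; the promoter
#' TFBS count takes the peak-centric reading (sites hit by promoter peaks),
#' `site_in_promoter = TRUE` switches to counting hits whose site itself
#' lies in a promoter window.
#'
#' @param ann An [annotate_peaks()] result.
#' @param site_in_promoter Logical; see above.
#' @param promoters Required when `site_in_promoter = TRUE`: the promoter
#'   windows to test sites against.
#' @return A one-row `data.frame` with columns `n_peaks_total`,
#'   `n_peaks_promoter`, `n_tfbs_peaks_total`, `n_tfbs_peaks_promoter`,
#'   `n_tfbs_total`, `n_tfbs_promoter`.
#' @export
count_summary <- function(ann, site_in_promoter = FALSE, promoters = NULL) {
  stopifnot(inherits(ann, "annotated_peaks"))
  in_prom <- ann$peaks$in_promoter
  has_hit <- seq_along(ann$peaks) %in% ann$hits$peak
  if (site_in_promoter) {
    if (is.null(promoters)) {
      stop("promoters must be supplied when site_in_promoter = TRUE")
    }
    sp <- align_seqlevels(ann$catalog$sites, promoters)
    site_prom <- IRanges::overlapsAny(sp[[1]], sp[[2]], ignore.strand = TRUE)
    n_tfbs_prom <- length(unique(ann$hits$site[site_prom[ann$hits$site]]))
  } else {
    n_tfbs_prom <- length(unique(ann$hits$site[in_prom[ann$hits$peak]]))
  }
  data.frame(
    n_peaks_total = length(ann$peaks),
    n_peaks_promoter = sum(in_prom),
    n_tfbs_peaks_total = sum(has_hit),
    n_tfbs_peaks_promoter = sum(has_hit & in_prom),
    n_tfbs_total = length(unique(ann$hits$site)),
    n_tfbs_promoter = n_tfbs_prom
  )
}
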