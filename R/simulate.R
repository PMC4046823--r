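#' Default synthetic fixture configuration
#'
#' Study conditions for the seeded generator: a 2 Mb toy genome (two 1 Mb
#' chromosomes), 100 genes, a 20-factor catalog with 50 sites per factor,
#' three callers that each report the 30 true regions (with boundary jitter
#' and caller-specific heights) plus 200 caller-private noise peaks. One
#' factor is "planted": its sites sit inside promoter windows and the true
#' regions are placed over 30 of them, with true-region heights
#' (uniform 30-100) well above noise heights (uniform 1-20) so the
#' score/outlier stage has a recoverable signal.
#'
#' @param seed Integer seed; the same seed yields byte-identical fixtures.
#' @param ... Overrides for any config field (see the returned list).
#' @return A named list of generator parameters.
#' @export
fixture_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = c(chr1 = 1e6, chr2 = 1e6),
    n_tfs = 20L,
    sites_per_tf = 50L,
    site_width = c(8L, 20L),
    n_tss = 100L,
    n_true_regions = 30L,
    n_noise_peaks_per_caller = 200L,
    callers = c("M", "C", "T"),
    planted_tf = "V$TF01_01",
    true_height = c(30, 100),
    noise_height = c(1, 20),
    peak_width = c(200L, 500L),
    caller_jitter_bp = 20L,
    upstream = 5000L,
    downstream = 1000L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Generate a synthetic ChIP-seq fixture with a planted signal
#'
#' Emulates the inputs of the post-peak-calling pipeline: a TFBS catalog,
#' a TSS table, and one peak set per caller. True signal regions are
#' placed over binding sites of one planted factor inside promoter
#' windows and are reported by *every* caller — with per-caller boundary
#' jitter and per-caller heights — while noise peaks are caller-private
#' uniform placements with low heights. Intersection fusion should
#' therefore retain the true regions and shed the noise, and the planted
#' factor should dominate the score ranking; the truth record makes both
#' checkable.
#'
#' Real ChIP-seq data differ in ways the generator does not model: peak
#' callers disagree on true peaks too, heights are heavy-tailed rather
#' than uniform, and binding sites cluster by factor family.
#'
#' @param cfg A [fixture_config()] list.
#' @return A list with `peak_sets` (named list of normalized peak sets,
#'   one per caller), `catalog` (a [tfbs_catalog()]), `tss` (TSS
#'   `data.frame`), `promoters` (windows), and `truth` (list with
#'   `true_regions` GRanges and `planted_tf`).
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  set.seed(cfg$seed)
  glen <- cfg$genome
  if (is.null(names(glen)) || any(!nzchar(names(glen)))) {
    stop("genome must be a named vector of chromosome lengths")
  }
  margin <- cfg$upstream + max(cfg$peak_width) + cfg$caller_jitter_bp
  if (any(glen < 2 * margin)) {
    stop("genome too small to place requested features: need chromosomes of ",
         "at least ", 2 * margin, " bp")
  }
  if (cfg$n_true_regions > cfg$sites_per_tf) {
    stop("cannot place ", cfg$n_true_regions, " true regions over only ",
         cfg$sites_per_tf, " planted sites")
  }

  rand_chrom <- function(n) sample(names(glen), n, replace = TRUE,
                                   prob = glen / sum(glen))

  ## TSS table (0-based positions, kept away from chromosome ends)
  tss_chrom <- rand_chrom(cfg$n_tss)
  tss_pos <- vapply(tss_chrom, function(ch) {
    floor(stats::runif(1, margin, glen[[ch]] - margin))
  }, numeric(1))
  tss <- data.frame(
    chrom = tss_chrom,
    position = as.integer(tss_pos),
    strand = sample(c("+", "-"), cfg$n_tss, replace = TRUE),
    gene_id = sprintf("G%04d", seq_len(cfg$n_tss)),
    stringsAsFactors = FALSE
  )
  promoters <- promoter_windows(tss, cfg$upstream, cfg$downstream)

  ## TFBS catalog: planted factor's sites inside promoter windows,
  ## background factors uniform
  tf_ids <- sprintf("V$TF%02d_01", seq_len(cfg$n_tfs))
  if (!cfg$planted_tf %in% tf_ids) tf_ids[1] <- cfg$planted_tf
  site_rows <- lapply(tf_ids, function(id) {
    w <- sample(seq(cfg$site_width[1], cfg$site_width[2]),
                cfg$sites_per_tf, replace = TRUE)
    if (id == cfg$planted_tf) {
      host <- sample(seq_len(nrow(tss)), cfg$sites_per_tf, replace = TRUE)
      ch <- tss$chrom[host]
      offset <- floor(stats::runif(cfg$sites_per_tf, -2000, 500))
      s0 <- tss$position[host] + ifelse(tss$strand[host] == "+", offset, -offset)
      s0 <- pmax(0, pmin(s0, glen[ch] - w - 1))
    } else {
      ch <- rand_chrom(cfg$sites_per_tf)
      s0 <- floor(stats::runif(cfg$sites_per_tf, 0, glen[ch] - w))
    }
    data.frame(chrom = ch, start = as.integer(s0),
               end = as.integer(s0 + w), matrix_id = id,
               stringsAsFactors = FALSE)
  })
  site_df <- do.call(rbind, site_rows)
  sites <- GenomicRanges::GRanges(
    site_df$chrom,
    IRanges::IRanges(site_df$start + 1L, site_df$end),
    matrix_id = site_df$matrix_id
  )
  catalog <- tfbs_catalog(sites)

  ## True regions: centered on a sample of the planted factor's sites
  planted <- sites[sites$matrix_id == cfg$planted_tf]
  anchor <- sort(sample(seq_along(planted), cfg$n_true_regions))
  tw <- sample(seq(cfg$peak_width[1], cfg$peak_width[2]),
               cfg$n_true_regions, replace = TRUE)
  centre <- (GenomicRanges::start(planted[anchor]) +
             GenomicRanges::end(planted[anchor])) %/% 2
  tchrom <- as.character(GenomicRanges::seqnames(planted[anchor]))
  ts0 <- pmax(0L, as.integer(centre - tw %/% 2))
  te0 <- pmin(as.integer(glen[tchrom]), ts0 + tw)
  true_regions <- peak_set(tchrom, ts0, te0, height = 1, name = "truth")

  ## Per-caller peak sets: jittered true regions + private noise
  jitter <- function(n) {
    sample(seq(-cfg$caller_jitter_bp, cfg$caller_jitter_bp), n, replace = TRUE)
  }
  peak_sets <- lapply(cfg$callers, function(cl) {
    n <- cfg$n_true_regions
    s0 <- pmax(0L, ts0 + jitter(n))
    e0 <- pmin(as.integer(glen[tchrom]), te0 + jitter(n))
    e0 <- pmax(e0, s0 + 1L)
    th <- stats::runif(n, cfg$true_height[1], cfg$true_height[2])
    nn <- cfg$n_noise_peaks_per_caller
    nw <- sample(seq(cfg$peak_width[1], cfg$peak_width[2]), nn, replace = TRUE)
    nch <- rand_chrom(nn)
    ns0 <- floor(stats::runif(nn, 0, glen[nch] - nw))
    nh <- stats::runif(nn, cfg$noise_height[1], cfg$noise_height[2])
    ps <- peak_set(c(tchrom, nch), c(s0, ns0), c(e0, ns0 + nw),
                   height = c(th, nh), name = cl)
    normalize_peaks(ps)
  })
  names(peak_sets) <- cfg$callers

  list(
    peak_sets = peak_sets,
    catalog = catalog,
    tss = tss,
    promoters = promoters,
    truth = list(true_regions = true_regions, planted_tf = cfg$planted_tf)
  )
}

#' Write a generated fixture to disk
#'
#' Emits the fixture in the same plain-text formats the readers consume:
#' one BED6 per caller (score = height), a BED6 TFBS catalog
#' (name = matrix id), a TSS TSV, and a JSON truth record.
#'
#' @param fx A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (cl in names(fx$peak_sets)) {
    p <- file.path(dir, paste0("peaks_", cl, ".bed"))
    write_peaks_bed(fx$peak_sets[[cl]], p)
    paths[paste0("peaks_", cl)] <- p
  }
  cat_path <- file.path(dir, "tfbs_catalog.bed")
  s <- fx$catalog$sites
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(s)),
               GenomicRanges::start(s) - 1L, GenomicRanges::end(s),
               s$matrix_id, 0L, "."),
    cat_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  paths["tfbs"] <- cat_path
  tss_path <- file.path(dir, "tss.tsv")
  utils::write.table(fx$tss, tss_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["tss"] <- tss_path
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted_tf = fx$truth$planted_tf,
         true_regions = as_bed_df(fx$truth$true_regions)[, 1:3]),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  paths["truth"] <- truth_path
  invisible(paths)
}
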