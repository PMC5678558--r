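## MeDIP-seq peak summaries and BS-seq/MeDIP concordance.

#' Per-chromosome MeDIP peak density
#'
#' Summarises a peak set per chromosome: total peaks, annotated peaks
#' (assigned to a promoter or genic category by [assign_features()]),
#' chromosome length in Mb, and the per-Mb densities rounded to two
#' decimals (round-half-even, the R default).
#'
#' @param peaks `GRanges` of peaks.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param annotated logical vector (one per peak) flagging peaks in
#'   annotated (promoter or genic) regions; if `NULL` and `annotation` is
#'   given, computed via [assign_features()].
#' @param annotation optional `AnnotationSet` used to derive `annotated`.
#' @return data.frame per chromosome: `chrom`, `total_peaks`,
#'   `annotated_peaks`, `length_mb`, `total_per_mb`, `annotated_per_mb`.
#' @export
peak_density <- function(peaks, chrom_lengths, annotated = NULL,
                         annotation = NULL) {
  if (is.null(annotated)) {
    if (!is.null(annotation)) {
      cat_ <- assign_features(peaks, annotation)$category
      annotated <- cat_ %in% c("promoter", "CDS", "five_prime_UTR",
                               "three_prime_UTR", "intron")
    } else {
      annotated <- rep(FALSE, length(peaks))
    }
  }
  stopifnot(length(annotated) == length(peaks))
  ch <- as.character(seqnames(peaks))
  counts <- data.frame(
    chrom = names(chrom_lengths),
    total_peaks = as.integer(table(factor(ch,
      levels = names(chrom_lengths)))),
    annotated_peaks = vapply(names(chrom_lengths), function(cc)
      sum(annotated[ch == cc]), 0L),
    length_mb = unname(chrom_lengths) / 1e6)
  peak_density_from_counts(counts)
}

#' Peak densities from a per-chromosome count table
#'
#' Recomputes the per-Mb density cells from already-tabulated counts
#' (`chrom`, `total_peaks`, `annotated_peaks`, `length_mb`), as printed in
#' per-chromosome peak summary tables. Densities are rounded to two
#' decimals with round-half-even.
#'
#' @param counts data.frame with columns `chrom`, `total_peaks`,
#'   `annotated_peaks`, `length_mb`.
#' @return the input with `total_per_mb` and `annotated_per_mb` appended.
#' @export
peak_density_from_counts <- function(counts) {
  stopifnot(all(c("chrom", "total_peaks", "annotated_peaks", "length_mb")
                %in% names(counts)))
  counts$total_per_mb <- round(counts$total_peaks / counts$length_mb, 2)
  counts$annotated_per_mb <- round(counts$annotated_peaks /
                                     counts$length_mb, 2)
  counts
}

#' Common peaks between two genotypes
#'
#' Intersection intervals where a peak of set A and a peak of set B overlap
#' by at least `min_overlap_bp`; each merged overlap is reported once. The
#' operation is symmetric in its arguments.
#'
#' @param peaks_a,peaks_b `GRanges`.
#' @param min_overlap_bp minimum overlap width (default 1).
#' @return `GRanges` of common intervals.
#' @export
common_peaks <- function(peaks_a, peaks_b, min_overlap_bp = 1) {
  common <- GenomicRanges::intersect(granges(peaks_a), granges(peaks_b),
                                     ignore.strand = TRUE)
  common[width(common) >= min_overlap_bp]
}

#' Per-region methylation matrix from BS-seq calls
#'
#' One weighted level per region and context (delegating to the same
#' count-pooling as [weighted_level()]); `NA` where a region has no
#' qualifying site in a context. Suitable for heat-map export.
#'
#' @param mt a `MethylomeTable`.
#' @param regions `GRanges`.
#' @param min_depth per-site depth gate (default 1).
#' @param contexts contexts to compute (default all three).
#' @return data.frame: `chrom`, `start`, `end`, one level column per
#'   context (named `CG`, `CHG`, `CHH`).
#' @export
region_methylation <- function(mt, regions, min_depth = 1,
                               contexts = c("CG", "CHG", "CHH")) {
  out <- data.frame(chrom = as.character(seqnames(regions)),
                    start = start(regions), end = end(regions))
  for (ctx in contexts) {
    sub <- filter_sites(mt, ctx, NULL, min_depth)
    out[[ctx]] <- pooled_levels_by_region(sub, regions)$level
  }
  out
}

#' Paired comparison of region methylation between genotypes
#'
#' For every context column shared by the two matrices, a two-sided t-test
#' on per-region levels: paired by default (each region measured in both
#' genotypes); set `paired = FALSE` for the unpaired variant.
#'
#' @param matrix_a,matrix_b outputs of [region_methylation()] over the same
#'   regions in genotypes A and B.
#' @param contexts contexts to test.
#' @param paired paired t-test (default TRUE).
#' @return data.frame per context: `n` complete pairs, `mean_diff`
#'   (B minus A), `p_value`.
#' @export
compare_genotype_regions <- function(matrix_a, matrix_b,
                                     contexts = c("CG", "CHG", "CHH"),
                                     paired = TRUE) {
  stopifnot(nrow(matrix_a) == nrow(matrix_b))
  res <- lapply(contexts, function(ctx) {
    a <- matrix_a[[ctx]]; b <- matrix_b[[ctx]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) stop("fewer than 2 complete pairs for context ", ctx)
    d <- b[ok] - a[ok]
    p <- if (stats::var(d) == 0 && paired) NA_real_ else if (paired)
      t.test(d)$p.value else t.test(b[ok], a[ok])$p.value
    data.frame(context = ctx, n = sum(ok), mean_diff = mean(d),
               p_value = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' DMR / MeDIP-signal concordance report
#'
#' For each DMR, the interval-weighted mean MeDIP coverage per genotype
#' (from bedGraph tracks; DMRs entirely outside track coverage are excluded
#' from the means and counted), and the direction-concordant overlap
#' counts: hyper DMRs (higher in genotype B) overlapping B-upregulated
#' peaks, hypo DMRs overlapping A-upregulated peaks (>= 1 bp).
#'
#' @param dmrs list with `GRanges` elements `hyper` and `hypo` (e.g. from
#'   [merge_contexts()]).
#' @param cov_a,cov_b bedGraph coverage tracks as `GRanges` with `score`
#'   (from [read_regions()] with dialect `bedGraph`).
#' @param diff_peaks_a,diff_peaks_b `GRanges` of genotype-upregulated
#'   peaks (A-up and B-up respectively).
#' @return list with `signal` (data.frame per direction: mean coverage per
#'   genotype over DMRs, n used, n excluded) and `concordance` (data.frame
#'   per direction: n DMRs, concordant overlap count).
#' @export
dmr_peak_concordance <- function(dmrs, cov_a, cov_b,
                                 diff_peaks_a = GRanges(),
                                 diff_peaks_b = GRanges()) {
  mean_cov <- function(regions, cov) {
    if (!length(regions)) return(list(m = numeric(0)))
    hits <- findOverlaps(regions, cov, ignore.strand = TRUE)
    v <- numeric(length(regions)); w <- numeric(length(regions))
    if (length(hits)) {
      ow <- width(pintersect(regions[queryHits(hits)],
                             cov[subjectHits(hits)], ignore.strand = TRUE))
      sc <- cov$score[subjectHits(hits)]
      sv <- rowsum(ow * sc, queryHits(hits))
      sw <- rowsum(ow, queryHits(hits))
      idx <- as.integer(rownames(sv))
      v[idx] <- sv[, 1]; w[idx] <- sw[, 1]
    }
    list(m = ifelse(w > 0, v / w, NA_real_))
  }
  signal <- do.call(rbind, lapply(c("hyper", "hypo"), function(dir) {
    r <- dmrs[[dir]]
    ma <- mean_cov(r, cov_a)$m
    mb <- mean_cov(r, cov_b)$m
    ok <- !is.na(ma) & !is.na(mb)
    data.frame(direction = dir, n_dmrs = length(r), n_with_signal = sum(ok),
               n_excluded = length(r) - sum(ok),
               mean_cov_a = if (any(ok)) mean(ma[ok]) else NA_real_,
               mean_cov_b = if (any(ok)) mean(mb[ok]) else NA_real_)
  }))
  concordance <- data.frame(
    direction = c("hyper", "hypo"),
    n_dmrs = c(length(dmrs$hyper), length(dmrs$hypo)),
    n_concordant = c(
      sum(overlapsAny(dmrs$hyper, diff_peaks_b, ignore.strand = TRUE)),
      sum(overlapsAny(dmrs$hypo, diff_peaks_a, ignore.strand = TRUE))))
  list(signal = signal, concordance = concordance)
}
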