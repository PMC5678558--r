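## Scaled-body + fixed-flank methylation metaprofiles for genes and TEs.

#' Methylation metaprofile across a region set
#'
#' Computes the classic meta-plot: each region's body is divided into
#' `body_bins` equal fractions, and fixed windows of `flank_bin_bp` bp tile
#' the `flank_bp` upstream and downstream flanks. Per-bin levels are
#' count-pooled across regions (sum of methylated reads over sum of total
#' reads), so the result is independent of region order. For minus-strand
#' regions (when `strand_aware`) bins are reversed so that bin 1 is always
#' the 5'-most; sites falling in a flank are counted even if the flank
#' overlaps a neighbouring feature (no masking). Regions shorter than
#' `body_bins` bp still get body bins, via fractional assignment
#' `floor(body_bins * offset / width)`.
#'
#' @inheritParams weighted_level
#' @param regions non-empty `GRanges` (genes, TEs, ...). Sites overlapping
#'   several regions contribute to each.
#' @param flank_bp flank length on each side (bp); must be divisible by
#'   `flank_bin_bp`.
#' @param body_bins number of equal-fraction body bins.
#' @param flank_bin_bp width of each flank bin (bp).
#' @param strand_aware orient minus-strand regions 5' to 3'.
#' @return A `MetaProfile`: data.frame with `segment`
#'   (upstream/body/downstream), `bin` (1-based within segment, 5' to 3'),
#'   `level`, `n_meth`, `n_total`; attributes record the configuration and
#'   `n_regions`.
#' @export
meta_profile <- function(mt, regions, context = NULL, flank_bp = 2000,
                         body_bins = 20, flank_bin_bp = 100,
                         strand_aware = TRUE, min_depth = 1) {
  if (!length(regions)) stop("regions must be non-empty")
  if (flank_bp %% flank_bin_bp != 0)
    stop("flank_bp must be divisible by flank_bin_bp")
  nb <- as.integer(flank_bp / flank_bin_bp)
  sub <- filter_sites(mt, context, NULL, min_depth)

  ext <- GRanges(seqnames(regions),
                 IRanges(pmax(start(regions) - flank_bp, 1),
                         end(regions) + flank_bp))
  nbin_tot <- 2L * nb + body_bins
  meth <- numeric(nbin_tot); tot <- numeric(nbin_tot)
  if (nrow(sub)) {
    hits <- findOverlaps(site_granges(sub), ext, ignore.strand = TRUE)
    if (length(hits)) {
      q <- queryHits(hits); r <- subjectHits(hits)
      p <- sub$pos[q]
      s <- start(regions)[r]; e <- end(regions)[r]
      w <- e - s + 1
      minus <- strand_aware & as.character(strand(regions))[r] == "-"
      ## oriented offset: distance from the 5' outer edge of the extended
      ## region, in three segments
      seg <- integer(length(q))   # 1 upstream, 2 body, 3 downstream
      bin <- integer(length(q))
      up <- ifelse(minus, p > e, p < s)
      dn <- ifelse(minus, p < s, p > e)
      body <- !up & !dn
      ## upstream: distance from outer edge of the 5' flank
      uo <- ifelse(minus, (e + flank_bp) - p, p - (s - flank_bp))
      bin[up] <- uo[up] %/% flank_bin_bp + 1L
      seg[up] <- 1L
      bo <- ifelse(minus, e - p, p - s)
      bin[body] <- pmin(as.integer(body_bins * bo[body] / w[body]) + 1L,
                        body_bins)
      seg[body] <- 2L
      do <- ifelse(minus, (s - 1) - p, p - e - 1)
      bin[dn] <- do[dn] %/% flank_bin_bp + 1L
      seg[dn] <- 3L
      ok <- bin >= 1 & bin <= ifelse(seg == 2L, body_bins, nb)
      idx <- ifelse(seg == 1L, bin,
                    ifelse(seg == 2L, nb + bin, nb + body_bins + bin))[ok]
      dt <- data.table(idx = idx, m = as.numeric(sub$n_meth[q][ok]),
                       t = as.numeric((sub$n_meth + sub$n_unmeth)[q][ok]))
      agg <- dt[, .(m = sum(m), t = sum(t)), by = idx]
      meth[agg$idx] <- agg$m; tot[agg$idx] <- agg$t
    }
  }
  out <- data.frame(
    segment = rep(c("upstream", "body", "downstream"),
                  times = c(nb, body_bins, nb)),
    bin = c(seq_len(nb), seq_len(body_bins), seq_len(nb)),
    level = ifelse(tot > 0, meth / tot, NA_real_),
    n_meth = meth, n_total = tot)
  attr(out, "flank_bp") <- flank_bp
  attr(out, "body_bins") <- body_bins
  attr(out, "flank_bin_bp") <- flank_bin_bp
  attr(out, "n_regions") <- length(regions)
  class(out) <- c("MetaProfile", "data.frame")
  out
}

#' Metaprofiles per transposable-element class
#'
#' One [meta_profile()] per TE class. TEs are profiled strand-agnostically
#' unless the annotation carries strands (repeat annotations often do not).
#' Classes absent from the annotation are dropped with a warning.
#'
#' @inheritParams meta_profile
#' @param annotation an `AnnotationSet`.
#' @param classes TE class labels to profile.
#' @return named list of `MetaProfile`, one per class present.
#' @export
te_class_profiles <- function(mt, annotation,
                              classes = c("LTR/Copia", "LTR/Gypsy",
                                          "LINE", "DNA"),
                              context = NULL, flank_bp = 2000,
                              body_bins = 20, flank_bin_bp = 100,
                              min_depth = 1) {
  out <- list()
  for (cl in classes) {
    tes <- annotation$tes[annotation$tes$te_class == cl]
    if (!length(tes)) {
      warning("no TEs of class '", cl, "' in annotation; skipped")
      next
    }
    stranded <- any(as.character(strand(tes)) %in% c("+", "-"))
    out[[cl]] <- meta_profile(mt, tes, context = context,
                              flank_bp = flank_bp, body_bins = body_bins,
                              flank_bin_bp = flank_bin_bp,
                              strand_aware = stranded,
                              min_depth = min_depth)
  }
  out
}

#' Gene bodies free of intronic TEs
#'
#' Returns the gene spans whose introns overlap no transposable element
#' (any overlap of at least 1 bp excludes the gene). TEs in flanks or exons
#' do not exclude a gene; the rule's scope is introns only.
#'
#' @param annotation an `AnnotationSet`.
#' @return `GRanges` of gene bodies with `gene_id`.
#' @export
genes_without_intronic_tes <- function(annotation) {
  introns <- annotation$features[annotation$features$type == "intron"]
  bad <- character(0)
  if (length(introns) && length(annotation$tes)) {
    hits <- findOverlaps(introns, annotation$tes, ignore.strand = TRUE)
    bad <- unique(introns$gene_id[queryHits(hits)])
  }
  annotation$genes[!(annotation$genes$gene_id %in% bad)]
}
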