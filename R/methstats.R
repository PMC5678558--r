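## Weighted methylation statistics: genome-wide, per-site distribution,
## per-feature, per-window, and paired gene comparisons.

#' Weighted methylation level
#'
#' The weighted level is the read-count-weighted statistic
#' sum(n_meth) / sum(n_meth + n_unmeth) over qualifying sites -- NOT the
#' mean of per-site levels, so deeply covered sites carry more weight and
#' uneven depth does not bias the estimate.
#'
#' @param mt a `MethylomeTable`.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`, or `NULL` for all sites.
#' @param regions optional `GRanges`; only sites falling in these intervals
#'   are used.
#' @param min_depth minimum per-site depth (default 1; depth-0 sites never
#'   contribute anyway since they carry no reads).
#' @return one-row data.frame with `level`, `n_sites`, `total_meth_reads`,
#'   `total_reads`. `level` is `NA` when no site qualifies.
#' @export
weighted_level <- function(mt, context = NULL, regions = NULL,
                           min_depth = 1) {
  stopifnot(min_depth >= 1)
  sub <- filter_sites(mt, context, regions, min_depth)
  tm <- sum(as.numeric(sub$n_meth))
  tt <- tm + sum(as.numeric(sub$n_unmeth))
  data.frame(level = if (tt > 0) tm / tt else NA_real_,
             n_sites = nrow(sub), total_meth_reads = tm, total_reads = tt)
}

filter_sites <- function(mt, context = NULL, regions = NULL, min_depth = 1) {
  sub <- mt
  if (!is.null(context)) {
    ctx <- context
    sub <- sub[sub$context %in% ctx, ]
  }
  if (min_depth > 1)
    sub <- sub[sub$n_meth + sub$n_unmeth >= min_depth, ]
  if (!is.null(regions) && nrow(sub)) {
    hits <- findOverlaps(site_granges(sub), regions, ignore.strand = TRUE)
    sub <- sub[unique(queryHits(hits)), ]
  }
  sub
}

#' Per-site methylation level distribution
#'
#' Bins per-site levels (n_meth / depth) into low / intermediate / high
#' classes. Following the usual reporting convention, the boundaries are
#' strict on the outer bins: low means level < `bin_edges[1]`, high means
#' level > `bin_edges[2]`, and the middle bin is closed on both sides.
#'
#' @inheritParams weighted_level
#' @param bin_edges two strictly increasing values in (0,1);
#'   default `c(0.2, 0.6)`.
#' @param min_depth minimum site depth (default 5).
#' @return data.frame with one row per bin (`bin`, `proportion`, `n_sites`);
#'   proportions sum to 1. Attributes `context` and `min_depth` record the
#'   configuration.
#' @export
level_distribution <- function(mt, context, bin_edges = c(0.2, 0.6),
                               min_depth = 5) {
  stopifnot(length(bin_edges) == 2, bin_edges[1] < bin_edges[2],
            all(bin_edges > 0 & bin_edges < 1))
  sub <- filter_sites(mt, context, NULL, max(1, min_depth))
  if (!nrow(sub)) stop("no sites for context ", context,
                       " at min_depth ", min_depth)
  lev <- sub$n_meth / (sub$n_meth + sub$n_unmeth)
  lo <- lev < bin_edges[1]
  hi <- lev > bin_edges[2]
  n <- c(sum(lo), sum(!lo & !hi), sum(hi))
  out <- data.frame(
    bin = c(sprintf("<%g", bin_edges[1]),
            sprintf("[%g,%g]", bin_edges[1], bin_edges[2]),
            sprintf(">%g", bin_edges[2])),
    proportion = n / length(lev), n_sites = n)
  attr(out, "context") <- context
  attr(out, "min_depth") <- min_depth
  out
}

#' Feature GRanges for a named category
#'
#' Resolves a feature name against an `AnnotationSet`. `promoter` is the
#' `promoter_bp` window immediately upstream of the (strand-aware) TSS;
#' `UTR` pools both UTR types.
#' @keywords internal
feature_ranges <- function(annotation, feature, promoter_bp = 1000) {
  switch(feature,
    TE = annotation$tes,
    CDS = annotation$features[annotation$features$type == "CDS"],
    UTR = annotation$features[annotation$features$type %in%
            c("five_prime_UTR", "three_prime_UTR")],
    five_prime_UTR = annotation$features[
      annotation$features$type == "five_prime_UTR"],
    three_prime_UTR = annotation$features[
      annotation$features$type == "three_prime_UTR"],
    intron = annotation$features[annotation$features$type == "intron"],
    promoter = promoter_ranges(annotation$genes, annotation$chrom_lengths,
                               width_bp = promoter_bp, offset_bp = 0),
    gene = annotation$genes,
    stop("unknown feature '", feature, "'; valid: TE, promoter, CDS, UTR, ",
         "five_prime_UTR, three_prime_UTR, intron, gene")
  )
}

## Strand-aware upstream window [TSS - offset - width, TSS - offset - 1]
## (1-based, clipped to the chromosome). Strandless genes are treated as '+'.
promoter_ranges <- function(genes, chrom_lengths, width_bp = 1000,
                            offset_bp = 0) {
  if (!length(genes)) return(GRanges())
  st <- as.character(strand(genes))
  plus <- st != "-"
  s <- ifelse(plus, start(genes) - offset_bp - width_bp,
              end(genes) + offset_bp + 1)
  e <- ifelse(plus, start(genes) - offset_bp - 1,
              end(genes) + offset_bp + width_bp)
  len <- chrom_lengths[as.character(seqnames(genes))]
  s2 <- pmax(s, 1); e2 <- pmin(e, len)
  keep <- s2 <= e2
  gr <- GRanges(as.character(seqnames(genes))[keep],
                IRanges(s2[keep], e2[keep]), strand = st[keep])
  gr$gene_id <- genes$gene_id[keep]
  gr
}

#' Per-feature-instance weighted methylation levels
#'
#' One weighted level per feature instance (TE, promoter, CDS, UTR or
#' intron), as plotted in per-feature violin summaries. Instances with no
#' qualifying site are omitted; their number is recorded in the
#' `n_omitted` attribute.
#'
#' @inheritParams weighted_level
#' @param annotation an `AnnotationSet`.
#' @param feature one of `"TE"`, `"promoter"`, `"CDS"`, `"UTR"`, `"intron"`
#'   (also accepted: `"five_prime_UTR"`, `"three_prime_UTR"`, `"gene"`).
#' @return data.frame with one row per instance: `chrom`, `start`, `end`,
#'   `level`, `n_sites`, `total_meth_reads`, `total_reads`.
#' @export
feature_levels <- function(mt, annotation, feature, context = NULL,
                           min_depth = 1) {
  fr <- feature_ranges(annotation, feature)
  sub <- filter_sites(mt, context, NULL, min_depth)
  res <- pooled_levels_by_region(sub, fr)
  out <- data.frame(chrom = as.character(seqnames(fr)), start = start(fr),
                    end = end(fr), level = res$level, n_sites = res$n_sites,
                    total_meth_reads = res$tm, total_reads = res$tt)
  omit <- is.na(out$level)
  res <- out[!omit, , drop = FALSE]
  attr(res, "n_omitted") <- sum(omit)
  res
}

## Count-pooled level per region over a filtered site table.
pooled_levels_by_region <- function(sub, regions) {
  n <- length(regions)
  tm <- numeric(n); tt <- numeric(n); ns <- integer(n)
  if (nrow(sub) && n) {
    hits <- findOverlaps(site_granges(sub), regions, ignore.strand = TRUE)
    if (length(hits)) {
      q <- queryHits(hits); s <- subjectHits(hits)
      dt <- data.table(region = s, m = as.numeric(sub$n_meth[q]),
                       t = as.numeric(sub$n_meth[q] + sub$n_unmeth[q]))
      agg <- dt[, .(tm = sum(m), tt = sum(t), ns = .N), by = region]
      tm[agg$region] <- agg$tm; tt[agg$region] <- agg$tt
      ns[agg$region] <- agg$ns
    }
  }
  list(level = ifelse(tt > 0, tm / tt, NA_real_),
       n_sites = ns, tm = tm, tt = tt)
}

#' Windowed methylation track
#'
#' Tiles each chromosome with fixed-size windows (last window truncated at
#' the chromosome end) and computes the weighted level per window; windows
#' with no qualifying site carry `NA` score. The result is a `GRanges`
#' directly exportable as bedGraph via [write_regions()].
#'
#' @inheritParams weighted_level
#' @param window_size window width in bp.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @return `GRanges` of tiling windows with `score` = weighted level.
#' @export
window_track <- function(mt, context, window_size, chrom_lengths,
                         min_depth = 1) {
  stopifnot(window_size > 0)
  tiles <- tile_genome(chrom_lengths, window_size)
  sub <- filter_sites(mt, context, NULL, min_depth)
  res <- pooled_levels_by_region(sub, tiles)
  tiles$score <- res$level
  tiles
}

tile_genome <- function(chrom_lengths, width_bp) {
  parts <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    s <- seq(1, L, by = width_bp)
    data.frame(chrom = ch, start = s, end = pmin(s + width_bp - 1, L))
  })
  dt <- do.call(rbind, parts)
  GRanges(dt$chrom, IRanges(dt$start, dt$end))
}

#' Paired methylation comparison of homeologous gene pairs
#'
#' For collinear gene pairs between two subgenomes (pair identification is
#' upstream), compares per-gene methylation levels of pair members with a
#' two-sided paired t-test, per context.
#'
#' @param pair_table data.frame with two columns of gene IDs
#'   (subgenome A member, subgenome B member).
#' @param gene_levels data.frame with columns `gene_id`, `context`, `level`
#'   (e.g. built from [feature_levels()] on gene bodies).
#' @return data.frame per context: `n_pairs` (complete pairs),
#'   `mean_diff` (member2 - member1), `p_value`, `note`. When the pair
#'   differences have zero variance the t statistic is undefined; the
#'   p-value is reported as `NA` with note `"no difference"` when the mean
#'   difference is 0.
#' @export
subgenome_pair_comparison <- function(pair_table, gene_levels) {
  stopifnot(ncol(pair_table) >= 2)
  ids <- unique(c(as.character(pair_table[[1]]),
                  as.character(pair_table[[2]])))
  unknown <- setdiff(ids, unique(gene_levels$gene_id))
  if (length(unknown))
    stop("gene IDs absent from gene_levels: ",
         paste(head(unknown, 5), collapse = ", "))
  res <- lapply(split(gene_levels, gene_levels$context), function(gl) {
    lv <- setNames(gl$level, gl$gene_id)
    a <- lv[as.character(pair_table[[1]])]
    b <- lv[as.character(pair_table[[2]])]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) stop("insufficient pairs (<2 complete) for context ",
                          gl$context[1])
    d <- b[ok] - a[ok]
    if (isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0) {
      p <- NA_real_
      note <- if (mean(d) == 0) "no difference" else "constant difference"
    } else {
      p <- t.test(d)$p.value
      note <- ""
    }
    data.frame(context = gl$context[1], n_pairs = sum(ok),
               mean_diff = mean(d), p_value = p, note = note)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
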