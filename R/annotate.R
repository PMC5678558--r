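## Assign regions to genomic features, test overrepresentation, and
## associate regions with nearby TEs and genes.

FEATURE_PRECEDENCE <- c("TE", "CDS", "five_prime_UTR", "three_prime_UTR",
                        "intron", "promoter", "upstream_2kb",
                        "downstream_2kb", "intergenic")

## Build the candidate GRanges for every category except intergenic.
## promoter = 1 kb immediately upstream of the TSS, upstream_2kb = the
## remaining 1-2 kb band, downstream_2kb = 2 kb past the TES; all
## strand-aware (strandless genes treated as plus) and clipped to the
## chromosome.
category_ranges <- function(annotation, promoter_bp = 1000,
                            upstream_bp = 2000, downstream_bp = 2000) {
  g <- annotation$genes
  cl <- annotation$chrom_lengths
  f <- annotation$features
  list(
    TE = annotation$tes,
    CDS = f[f$type == "CDS"],
    five_prime_UTR = f[f$type == "five_prime_UTR"],
    three_prime_UTR = f[f$type == "three_prime_UTR"],
    intron = f[f$type == "intron"],
    promoter = promoter_ranges(g, cl, width_bp = promoter_bp,
                               offset_bp = 0),
    upstream_2kb = promoter_ranges(g, cl,
                                   width_bp = upstream_bp - promoter_bp,
                                   offset_bp = promoter_bp),
    downstream_2kb = downstream_ranges(g, cl, width_bp = downstream_bp)
  )
}

## Strand-aware window (TES, TES + width] (1-based, clipped).
downstream_ranges <- function(genes, chrom_lengths, width_bp = 2000) {
  if (!length(genes)) return(GRanges())
  st <- as.character(strand(genes))
  plus <- st != "-"
  s <- ifelse(plus, end(genes) + 1, start(genes) - width_bp)
  e <- ifelse(plus, end(genes) + width_bp, start(genes) - 1)
  len <- chrom_lengths[as.character(seqnames(genes))]
  s2 <- pmax(s, 1); e2 <- pmin(e, len)
  keep <- s2 <= e2
  gr <- GRanges(as.character(seqnames(genes))[keep],
                IRanges(s2[keep], e2[keep]), strand = st[keep])
  gr$gene_id <- genes$gene_id[keep]
  gr
}

#' Assign each region to one genomic feature category
#'
#' Every region receives exactly one label by precedence
#' TE > CDS > UTR > intron > promoter > upstream_2kb > downstream_2kb >
#' intergenic: the highest-precedence category the region overlaps by at
#' least 1 bp wins; regions overlapping nothing are intergenic. The
#' per-category overlap in bp is reported for all candidate categories.
#'
#' @param regions `GRanges` (DMRs, peaks, ...).
#' @param annotation an `AnnotationSet` with known `chrom_lengths`.
#' @param promoter_bp promoter width immediately upstream of the TSS
#'   (default 1000; the remaining band up to `upstream_bp` is
#'   `upstream_2kb`).
#' @param upstream_bp,downstream_bp flank extents (default 2000).
#' @return data.frame, one row per region: `chrom`, `start`, `end`,
#'   `category`, plus `overlap_<category>` bp columns.
#' @export
assign_features <- function(regions, annotation, promoter_bp = 1000,
                            upstream_bp = 2000, downstream_bp = 2000) {
  unknown <- setdiff(unique(as.character(seqnames(regions))),
                     names(annotation$chrom_lengths))
  if (length(unknown))
    stop("region on unknown chromosome: ", paste(unknown, collapse = ", "))
  cats <- category_ranges(annotation, promoter_bp, upstream_bp,
                          downstream_bp)
  n <- length(regions)
  ov <- matrix(0L, nrow = n, ncol = length(cats),
               dimnames = list(NULL, names(cats)))
  for (cn in names(cats)) {
    cr <- cats[[cn]]
    if (!length(cr)) next
    hits <- findOverlaps(regions, cr, ignore.strand = TRUE)
    if (!length(hits)) next
    w <- width(pintersect(regions[queryHits(hits)],
                          cr[subjectHits(hits)], ignore.strand = TRUE))
    agg <- rowsum(w, queryHits(hits))
    ov[as.integer(rownames(agg)), cn] <- agg[, 1]
  }
  category <- apply(ov, 1, function(x) {
    hit <- names(x)[x > 0]
    if (!length(hit)) "intergenic" else
      hit[which.min(match(hit, FEATURE_PRECEDENCE))]
  })
  if (!n) category <- character(0)
  out <- data.frame(chrom = as.character(seqnames(regions)),
                    start = start(regions), end = end(regions),
                    category = category)
  colnames(ov) <- paste0("overlap_", colnames(ov))
  cbind(out, as.data.frame(ov))
}

#' Hypergeometric feature-overrepresentation test
#'
#' Realises the overrepresentation test on a genome tiling: the genome is
#' cut into `tile_bp` windows, each labelled with one category by the same
#' precedence rule as [assign_features()]. With N total tiles, K tiles of a
#' category, n tiles overlapped by any region and k overlapped tiles of the
#' category, the one-sided p-value is P(X >= k) under the hypergeometric
#' null of region placement indifferent to category. Raw p-values are
#' BH-adjusted across categories.
#'
#' @inheritParams assign_features
#' @param tile_bp tiling window size in bp (default 100).
#' @return data.frame per category: `category`, `K_tiles`, `observed`,
#'   `expected`, `background_fraction`, `p_value`, `q_value`. Categories
#'   with no tile in the genome are skipped with a warning.
#' @export
enrichment_test <- function(regions, annotation, tile_bp = 100,
                            promoter_bp = 1000, upstream_bp = 2000,
                            downstream_bp = 2000) {
  if (!length(regions)) stop("regions must be non-empty")
  tiles <- tile_genome(annotation$chrom_lengths, tile_bp)
  lab <- assign_features(tiles, annotation, promoter_bp, upstream_bp,
                         downstream_bp)$category
  N <- length(tiles)
  hit <- overlapsAny(tiles, regions, ignore.strand = TRUE)
  n <- sum(hit)
  res <- lapply(FEATURE_PRECEDENCE, function(cat) {
    K <- sum(lab == cat)
    if (K == 0) {
      warning("category '", cat, "' has no tiles; skipped")
      return(NULL)
    }
    k <- sum(hit & lab == cat)
    data.frame(category = cat, K_tiles = K, observed = k,
               expected = n * K / N, background_fraction = K / N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Nearest transposable element per region
#'
#' For every region, the closest TE by genomic distance (0 when
#' overlapping; ties broken by the leftmost TE), its class, and its length
#' -- the inputs for TE-class histograms and associated-TE length violins.
#' Regions on chromosomes without any TE get `NA` distance.
#'
#' @inheritParams assign_features
#' @return data.frame per region: `chrom`, `start`, `end`, `te_class`,
#'   `distance`, `te_length`.
#' @export
nearest_te <- function(regions, annotation) {
  tes <- annotation$tes
  n <- length(regions)
  out <- data.frame(chrom = as.character(seqnames(regions)),
                    start = start(regions), end = end(regions),
                    te_class = NA_character_, distance = NA_real_,
                    te_length = NA_real_)
  if (!length(tes) || !n) return(out)
  for (i in seq_len(n)) {
    same <- which(as.character(seqnames(tes)) == out$chrom[i])
    if (!length(same)) next
    d <- distance(rep(regions[i], length(same)), tes[same],
                  ignore.strand = TRUE)
    best <- same[which(d == min(d))]
    best <- best[which.min(start(tes)[best])]   # tie -> leftmost TE
    out$te_class[i] <- tes$te_class[best]
    out$distance[i] <- min(d)
    out$te_length[i] <- width(tes)[best]
  }
  out
}

#' Genes within a distance of region sets
#'
#' Extracts the (de-duplicated) genes whose span lies within `max_dist` bp
#' of any region (distance 0 when overlapping; the rule is inclusive,
#' `<= max_dist`). When `regions` is a named list (e.g. the
#' `hyper` / `hypo` output of [merge_contexts()]), one gene list per
#' element is returned.
#'
#' @param regions `GRanges`, or a named list of `GRanges`.
#' @param annotation an `AnnotationSet`.
#' @param max_dist maximum gene-to-region distance in bp (default 2000).
#' @return character vector of gene IDs, or a named list of such vectors.
#' @export
genes_near <- function(regions, annotation, max_dist = 2000) {
  if (is.list(regions) && !is(regions, "GRanges"))
    return(lapply(regions, genes_near, annotation = annotation,
                  max_dist = max_dist))
  g <- annotation$genes
  if (!length(g) || !length(regions)) return(character(0))
  hits <- findOverlaps(g, regions, maxgap = max_dist, ignore.strand = TRUE)
  sort(unique(g$gene_id[queryHits(hits)]))
}
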