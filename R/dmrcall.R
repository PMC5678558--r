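## Core differential-methylation inference: per-cytosine Fisher exact tests,
## FDR correction, DMC clustering, DMR filtering and cross-context merging.

#' Two-sided Fisher exact test for a 2x2 methylation table
#'
#' Tests the table `[[a_meth, a_unmeth], [b_meth, b_unmeth]]` for one
#' cytosine observed in two genotypes. The two-sided p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 absorbs floating-point rounding when comparing table
#' probabilities, as in standard implementations). Vectorised over sites;
#' repeated count combinations are computed once.
#'
#' @param a_meth,a_unmeth,b_meth,b_unmeth non-negative integer read counts
#'   (vectors of equal length).
#' @return vector of p-values in (0, 1].
#' @export
test_dmc <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  n <- length(a_meth)
  stopifnot(length(a_unmeth) == n, length(b_meth) == n,
            length(b_unmeth) == n)
  if (any(c(a_meth, a_unmeth, b_meth, b_unmeth) < 0))
    stop("counts must be non-negative")
  d1 <- a_meth + a_unmeth
  d2 <- b_meth + b_unmeth
  if (any(d1 == 0) || any(d2 == 0))
    stop("zero-depth margin; filter sites before testing")
  key <- data.table(am = a_meth, au = a_unmeth, bm = b_meth, bu = b_unmeth)
  u <- unique(key)
  u[, p := fisher2x2_one(am, au, bm, bu), by = seq_len(nrow(u))]
  key[u, p := i.p, on = c("am", "au", "bm", "bu")]
  key$p
}

## single-table two-sided Fisher via the conditional hypergeometric
fisher2x2_one <- function(am, au, bm, bu, rel_tol = 1e-7) {
  m <- am + bm          # methylated margin
  n <- au + bu          # unmethylated margin
  k <- am + au          # genotype-A depth
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- probs[am - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values with monotonicity enforcement (delegates to
#' [stats::p.adjust]); the empty vector maps to the empty vector.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Call differentially methylated cytosines between two genotypes
#'
#' Tests every cytosine covered by at least `min_depth` reads in BOTH
#' genotypes with a two-sided Fisher exact test, applies Benjamini-Hochberg
#' correction (separately within each sequence context by default, since
#' power differs strongly between contexts), and returns sites with
#' q < `fdr_alpha`. Direction follows the two-genotype convention: `hyper`
#' means higher methylation in genotype B, `hypo` higher in genotype A.
#'
#' @param table_a,table_b `MethylomeTable`s for genotypes A and B, sharing
#'   a coordinate system.
#' @param min_depth joint depth gate (default 5).
#' @param fdr_alpha FDR threshold on q-values (default 0.05).
#' @param per_context_fdr adjust within each context separately (default)
#'   or pooled across contexts.
#' @return data.table of DMC records: site key (`chrom`, `pos`, `strand`,
#'   `context`), per-genotype counts and levels, `p_value`, `q_value`,
#'   `direction`. The attribute `n_tested` records the number of tested
#'   sites per context (the top of the funnel).
#' @export
call_dmcs <- function(table_a, table_b, min_depth = 5, fdr_alpha = 0.05,
                      per_context_fdr = TRUE) {
  a <- as.data.table(table_a)[, .(chrom, pos, strand, context,
                                  a_meth = n_meth, a_unmeth = n_unmeth)]
  b <- as.data.table(table_b)[, .(chrom, pos, strand, context,
                                  b_meth = n_meth, b_unmeth = n_unmeth)]
  j <- merge(a, b, by = c("chrom", "pos", "strand", "context"))
  j <- j[a_meth + a_unmeth >= min_depth & b_meth + b_unmeth >= min_depth]
  if (!nrow(j)) {
    warning("no common sites at min_depth ", min_depth)
    out <- j[, .(chrom, pos, strand, context, a_meth, a_unmeth,
                 b_meth, b_unmeth)]
    out[, `:=`(level_a = numeric(0), level_b = numeric(0),
               p_value = numeric(0), q_value = numeric(0),
               direction = character(0))]
    setattr(out, "n_tested", integer(0))
    return(out[])
  }
  n_tested <- table(j$context)
  j[, p_value := test_dmc(a_meth, a_unmeth, b_meth, b_unmeth)]
  if (per_context_fdr) {
    j[, q_value := bh_adjust(p_value), by = context]
  } else {
    j[, q_value := bh_adjust(p_value)]
  }
  j[, level_a := a_meth / (a_meth + a_unmeth)]
  j[, level_b := b_meth / (b_meth + b_unmeth)]
  out <- j[q_value < fdr_alpha]
  out[, direction := ifelse(level_b > level_a, "hyper", "hypo")]
  setkeyv(out, c("chrom", "pos", "strand"))
  setattr(out, "n_tested", n_tested)
  out[]
}

#' Cluster DMCs by genomic proximity
#'
#' Within one chromosome, context and (by default) direction, consecutive
#' DMCs whose positional gap is strictly less than `max_gap` bp join the
#' same cluster; strand is ignored for the gap computation. A gap of
#' exactly `max_gap` splits.
#'
#' @param dmcs data.table from [call_dmcs()].
#' @param max_gap clustering distance in bp (default 100; the gap rule is
#'   strict `< max_gap`).
#' @param split_direction keep hyper and hypo DMCs in separate clusters
#'   (default TRUE; mixed-direction clusters would cancel the region-level
#'   difference).
#' @return data.table of clusters: `chrom`, `context`, `direction`,
#'   `start_pos`, `end_pos` (1-based, inclusive), `n_dmcs`,
#'   `span_bp` (= end - start + 1).
#' @export
cluster_dmcs <- function(dmcs, max_gap = 100, split_direction = TRUE) {
  d <- as.data.table(dmcs)
  if (!nrow(d))
    return(data.table(chrom = character(), context = character(),
                      direction = character(), start_pos = integer(),
                      end_pos = integer(), n_dmcs = integer(),
                      span_bp = integer()))
  grp <- c("chrom", "context", if (split_direction) "direction")
  setorderv(d, c(grp, "pos"))
  d[, cluster_id := cumsum(c(1L, diff(pos) >= max_gap | diff(pos) < 0)),
    by = grp]
  if (split_direction) {
    out <- d[, .(start_pos = min(pos), end_pos = max(pos), n_dmcs = .N),
             by = c(grp, "cluster_id")]
  } else {
    out <- d[, .(start_pos = min(pos), end_pos = max(pos), n_dmcs = .N,
                 direction = if (length(unique(direction)) == 1)
                   direction[1] else "mixed"),
             by = c(grp, "cluster_id")]
  }
  out[, span_bp := end_pos - start_pos + 1L]
  out[, cluster_id := NULL]
  setcolorder(out, c("chrom", "context", "direction", "start_pos",
                     "end_pos", "n_dmcs", "span_bp"))
  setorderv(out, c("chrom", "start_pos"))
  out[]
}

#' Call differentially methylated regions from DMC clusters
#'
#' Keeps clusters with at least `min_dmcs` member DMCs AND spanning at
#' least `min_span` bp (conjunctive rule), recomputes the region weighted
#' level per genotype over ALL sites of the cluster's context inside
#' `[start_pos, end_pos]` that pass the joint depth gate (not only the DMC
#' members, unless `dmc_sites_only`), and retains regions whose absolute
#' level difference strictly exceeds the context threshold (defaults 0.4 /
#' 0.2 / 0.1 for CG / CHG / CHH). Direction comes from the sign of
#' `region_level_b - region_level_a`.
#'
#' @param clusters data.table from [cluster_dmcs()].
#' @param table_a,table_b the genotype `MethylomeTable`s.
#' @param min_dmcs minimum DMCs per cluster (default 4).
#' @param min_span minimum cluster span in bp (default 50).
#' @param thresholds named vector of per-context absolute level-difference
#'   thresholds (strict `>`).
#' @param min_depth joint depth gate for the region-level recomputation
#'   (default 5, matching the DMC gate).
#' @param dmc_sites_only if TRUE, region levels use only sites that are
#'   themselves DMC positions is not required; default FALSE uses all
#'   context sites in the span.
#' @param dmcs required when `dmc_sites_only = TRUE`: the DMC table.
#' @return data.table of DMRs: interval, context, `n_dmcs`,
#'   `region_level_a`, `region_level_b`, `diff` (= b - a), `direction`.
#' @export
call_dmrs <- function(clusters, table_a, table_b, min_dmcs = 4,
                      min_span = 50,
                      thresholds = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                      min_depth = 5, dmc_sites_only = FALSE, dmcs = NULL) {
  cl <- as.data.table(clusters)[n_dmcs >= min_dmcs & span_bp >= min_span]
  empty <- data.table(chrom = character(), start_pos = integer(),
                      end_pos = integer(), context = character(),
                      n_dmcs = integer(), region_level_a = numeric(),
                      region_level_b = numeric(), diff = numeric(),
                      direction = character())
  if (!nrow(cl)) return(empty)
  a <- as.data.table(table_a)[, .(chrom, pos, strand, context,
                                  a_meth = n_meth, a_unmeth = n_unmeth)]
  b <- as.data.table(table_b)[, .(chrom, pos, strand, context,
                                  b_meth = n_meth, b_unmeth = n_unmeth)]
  j <- merge(a, b, by = c("chrom", "pos", "strand", "context"))
  j <- j[a_meth + a_unmeth >= min_depth & b_meth + b_unmeth >= min_depth]
  if (dmc_sites_only) {
    if (is.null(dmcs)) stop("dmc_sites_only requires the dmcs table")
    j <- j[dmcs[, .(chrom, pos, strand, context)],
           on = c("chrom", "pos", "strand", "context"), nomatch = NULL]
  }
  rows <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    ci <- cl[i]
    s <- j[chrom == ci$chrom & context == ci$context &
             pos >= ci$start_pos & pos <= ci$end_pos]
    stopifnot(nrow(s) > 0)  # cluster members qualify by construction
    la <- sum(s$a_meth) / sum(s$a_meth + s$a_unmeth)
    lb <- sum(s$b_meth) / sum(s$b_meth + s$b_unmeth)
    rows[[i]] <- data.table(chrom = ci$chrom, start_pos = ci$start_pos,
                            end_pos = ci$end_pos, context = ci$context,
                            n_dmcs = ci$n_dmcs, region_level_a = la,
                            region_level_b = lb, diff = lb - la)
  }
  out <- rbindlist(rows)
  th <- thresholds[out$context]
  if (anyNA(th)) stop("no threshold for context: ",
                      paste(unique(out$context[is.na(th)]), collapse = ", "))
  out <- out[abs(diff) > th]
  if (!nrow(out)) return(empty)
  out[, direction := ifelse(diff > 0, "hyper", "hypo")]
  setorderv(out, c("chrom", "start_pos"))
  out[]
}

#' Merge per-context DMRs across contexts, per direction
#'
#' Since differential regions typically co-occur across contexts,
#' downstream analyses use the cross-context union: within each direction,
#' overlapping or book-ended intervals are merged. Directions are never
#' merged with each other.
#'
#' @param dmrs data.table from [call_dmrs()] (any mix of contexts).
#' @return list with `GRanges` elements `hyper` and `hypo`.
#' @export
merge_contexts <- function(dmrs) {
  d <- as.data.table(dmrs)
  out <- list(hyper = GRanges(), hypo = GRanges())
  for (dir in c("hyper", "hypo")) {
    dd <- d[direction == dir]
    if (!nrow(dd)) next
    gr <- GRanges(dd$chrom, IRanges(dd$start_pos, dd$end_pos))
    out[[dir]] <- reduce(gr, min.gapwidth = 1L)
  }
  out
}

#' Run the full DMC -> DMR pipeline
#'
#' Convenience wrapper chaining [call_dmcs()], [cluster_dmcs()],
#' [call_dmrs()] and [merge_contexts()], returning every intermediate plus
#' a funnel summary (tested sites, raw p < alpha, DMCs, qualifying
#' clusters, DMRs per context).
#'
#' @inheritParams call_dmcs
#' @inheritParams call_dmrs
#' @param max_gap DMC clustering distance (bp).
#' @return list with `dmcs`, `clusters`, `dmrs`, `merged`, `funnel`.
#' @export
dmr_pipeline <- function(table_a, table_b, min_depth = 5, fdr_alpha = 0.05,
                         max_gap = 100, min_dmcs = 4, min_span = 50,
                         thresholds = c(CG = 0.4, CHG = 0.2, CHH = 0.1)) {
  dmcs <- call_dmcs(table_a, table_b, min_depth = min_depth,
                    fdr_alpha = fdr_alpha)
  clusters <- cluster_dmcs(dmcs, max_gap = max_gap)
  dmrs <- call_dmrs(clusters, table_a, table_b, min_dmcs = min_dmcs,
                    min_span = min_span, thresholds = thresholds,
                    min_depth = min_depth)
  merged <- merge_contexts(dmrs)
  n_tested <- attr(dmcs, "n_tested")
  ctxs <- VALID_CONTEXTS
  qual <- as.data.table(clusters)[n_dmcs >= min_dmcs & span_bp >= min_span]
  funnel <- data.frame(
    context = ctxs,
    n_tested = as.integer(n_tested[ctxs]),
    n_dmcs = vapply(ctxs, function(cc) sum(dmcs$context == cc), 0L),
    n_clusters = vapply(ctxs, function(cc) sum(qual$context == cc), 0L),
    n_dmrs = vapply(ctxs, function(cc) sum(dmrs$context == cc), 0L))
  funnel$n_tested[is.na(funnel$n_tested)] <- 0L
  list(dmcs = dmcs, clusters = clusters, dmrs = dmrs, merged = merged,
       funnel = funnel)
}
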