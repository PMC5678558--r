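## Shared fixtures and independent oracles for the test suite.
suppressWarnings(suppressMessages({
  library(GenomicRanges)
  library(IRanges)
}))

## quick MethylomeTable from vectors
mk_mt <- function(pos, n_meth, n_unmeth, context = "CG", chrom = "Chr01",
                  strand = "+", id = "s") {
  n <- length(pos)
  methylome_table(data.frame(
    chrom = rep_len(chrom, n), pos = pos, strand = rep_len(strand, n),
    context = rep_len(context, n), n_meth = n_meth, n_unmeth = n_unmeth),
    id)
}

## Independent two-sided Fisher oracle: explicit enumeration of all tables
## with the observed margins via log-binomial coefficients (no dhyper).
fisher_oracle <- function(am, au, bm, bu) {
  m <- am + bm; n <- au + bu; k <- am + au
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  pr <- exp(logp)
  pobs <- pr[xs == am]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

## Brute-force single-linkage clustering under the strict gap rule.
cluster_oracle <- function(pos, max_gap) {
  pos <- sort(pos)
  grp <- integer(length(pos))
  g <- 1L
  grp[1] <- g
  for (i in seq_along(pos)[-1]) {
    if (pos[i] - pos[i - 1] >= max_gap) g <- g + 1L
    grp[i] <- g
  }
  split(pos, grp)
}

## Small shared simulated dataset, built once per test run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_chroms = 1, chrom_length = 2e5)
      g <- simulate_genome(cfg)
      ann <- simulate_annotation(cfg, g)
      sim <- suppressWarnings(simulate_methylome_pair(cfg, g, ann))
      cache <<- list(cfg = cfg, genome = g, ann = ann, sim = sim)
    }
    cache
  }
})

## Tiny hand-built annotation on a 10 kb chromosome: 3 genes, 5 TEs.
toy_annotation <- function() {
  genes <- GRanges("Chr01", IRanges(c(1001, 4001, 7001),
                                    c(2000, 5000, 8000)),
                   strand = c("+", "-", "+"))
  genes$gene_id <- c("g1", "g2", "g3")
  feats <- GRanges("Chr01", IRanges(
    c(1001, 1101, 1501, 1401, 1901,   4001, 4101, 4501, 4401, 4901,
      7001, 7101, 7501, 7401, 7901),
    c(1100, 1400, 1900, 1500, 2000,   4100, 4400, 4900, 4500, 5000,
      7100, 7400, 7900, 7500, 8000)))
  feats$type <- rep(c("five_prime_UTR", "CDS", "CDS", "intron",
                      "three_prime_UTR"), 3)
  feats$gene_id <- rep(c("g1", "g2", "g3"), each = 5)
  ## g2 is on '-' so swap its UTR labels
  feats$type[feats$gene_id == "g2"][c(1, 5)] <-
    c("three_prime_UTR", "five_prime_UTR")
  tes <- GRanges("Chr01", IRanges(c(3001, 3501, 6001, 6501, 9001),
                                  c(3200, 3800, 6300, 6700, 9400)))
  tes$te_class <- c("LTR/Gypsy", "LTR/Gypsy", "LTR/Copia", "LINE", "DNA")
  annotation_set(genes, feats, tes, c(Chr01 = 12000))
}
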