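test_that("Fisher test matches known values and the enumeration oracle", {
  expect_equal(test_dmc(5, 5, 5, 5), 1.0)
  # full enumeration oracle on the crossed table
  expect_equal(test_dmc(8, 2, 2, 8), fisher_oracle(8, 2, 2, 8),
               tolerance = 1e-12)
  # perfectly separated table: only the two extreme tables are as extreme
  expect_equal(test_dmc(20, 0, 0, 20), 2 / choose(40, 20),
               tolerance = 1e-12)
  expect_error(test_dmc(0, 0, 1, 1), "zero-depth")
  expect_error(test_dmc(-1, 2, 1, 1), "non-negative")
})

test_that("Fisher test agrees with the oracle over random tables", {
  set.seed(5)
  am <- sample(0:25, 400, TRUE); au <- sample(0:25, 400, TRUE)
  bm <- sample(0:25, 400, TRUE); bu <- sample(0:25, 400, TRUE)
  keep <- (am + au) > 0 & (bm + bu) > 0
  p <- test_dmc(am[keep], au[keep], bm[keep], bu[keep])
  po <- mapply(fisher_oracle, am[keep], au[keep], bm[keep], bu[keep])
  expect_lt(max(abs(p - po)), 1e-10)
  expect_true(all(p > 0 & p <= 1))
})

test_that("BH adjustment reproduces hand step-up values and its bounds", {
  expect_equal(bh_adjust(0.03), 0.03)
  # step-up by hand: q_i = min_{j>=i} p_(j) * m / j
  # p = (0.01,0.02,0.03,0.04), m=4: 0.04*4/4=0.04 floor for all ranks
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  p <- runif(500)^2
  q <- bh_adjust(p)
  expect_gte(min(q), min(p))
  expect_lte(max(q), 1)
  # order preserving on the sorted scale
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("joint depth gate excludes sites shallow in either genotype", {
  a <- mk_mt(c(10, 20), c(5, 2), c(5, 2))   # depths 10, 4
  b <- mk_mt(c(10, 20), c(0, 0), c(10, 10))
  dmcs <- call_dmcs(a, b, min_depth = 5, fdr_alpha = 1.1)
  expect_equal(dmcs$pos, 10L)   # site 20 has depth 4 in genotype A
  expect_equal(attr(dmcs, "n_tested")[["CG"]], 1L)
})

test_that("DMC direction and genotype swap behave symmetrically", {
  set.seed(21)
  n <- 400
  pos <- seq(10, by = 50, length.out = n)
  pa <- c(rep(0.05, 200), rep(0.9, 200))
  pb <- c(rep(0.9, 200), rep(0.05, 200))
  da <- rep(30L, n); db <- rep(30L, n)
  ma <- rbinom(n, da, pa); mb <- rbinom(n, db, pb)
  a <- mk_mt(pos, ma, da - ma)
  b <- mk_mt(pos, mb, db - mb)
  fwd <- call_dmcs(a, b)
  rev_ <- call_dmcs(b, a)
  expect_equal(nrow(fwd), nrow(rev_))
  expect_equal(fwd$p_value, rev_$p_value)
  expect_equal(fwd$q_value, rev_$q_value)
  expect_equal(fwd$direction,
               ifelse(rev_$direction == "hyper", "hypo", "hyper"))
  # first block is higher in B -> hyper
  expect_true(all(fwd$direction[fwd$pos <= pos[200]] == "hyper"))
})

test_that("clustering applies the strict gap rule and matches brute force", {
  dm <- data.table::data.table(
    chrom = "Chr01", pos = c(100L, 150L, 400L), strand = "+",
    context = "CG", direction = "hyper")
  cl <- cluster_dmcs(dm, max_gap = 100)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_dmcs, c(2L, 1L))
  expect_equal(cl$span_bp, c(51L, 1L))
  # boundary: gap of exactly max_gap splits
  dm2 <- dm[1:2][, pos := c(100L, 200L)]
  expect_equal(nrow(cluster_dmcs(dm2, max_gap = 100)), 2L)
  dm2[, pos := c(100L, 199L)]
  expect_equal(nrow(cluster_dmcs(dm2, max_gap = 100)), 1L)

  set.seed(31)
  pos <- sort(sample(1e5, 1000))
  dmr <- data.table::data.table(chrom = "Chr01", pos = pos, strand = "+",
                                context = "CG", direction = "hyper")
  cl2 <- cluster_dmcs(dmr, max_gap = 100)
  oracle <- cluster_oracle(pos, 100)
  expect_equal(nrow(cl2), length(oracle))
  expect_equal(cl2$n_dmcs, unname(lengths(oracle)))
  expect_equal(cl2$start_pos, unname(vapply(oracle, min, 0)))
})

test_that("directions are clustered separately by default", {
  dm <- data.table::data.table(
    chrom = "Chr01", pos = c(100L, 150L, 180L), strand = "+",
    context = "CG", direction = c("hyper", "hypo", "hyper"))
  expect_equal(nrow(cluster_dmcs(dm)), 2L)
  expect_equal(nrow(cluster_dmcs(dm, split_direction = FALSE)), 1L)
})

test_that("DMR filters apply the conjunctive keep-rule and strict threshold", {
  mkpair <- function(pos, la, lb, depth = 20L) {
    list(a = mk_mt(pos, as.integer(round(la * depth)),
                   depth - as.integer(round(la * depth))),
         b = mk_mt(pos, as.integer(round(lb * depth)),
                   depth - as.integer(round(lb * depth))))
  }
  cl3 <- data.table::data.table(chrom = "Chr01", context = "CG",
    direction = "hypo", start_pos = 100L, end_pos = 300L, n_dmcs = 3L,
    span_bp = 201L)
  pr <- mkpair(c(100L, 200L, 300L), 0.9, 0.1)
  expect_equal(nrow(call_dmrs(cl3, pr$a, pr$b)), 0L)  # 3 DMCs: discarded

  cl4 <- data.table::data.table(chrom = "Chr01", context = "CG",
    direction = "hypo", start_pos = 100L, end_pos = 139L, n_dmcs = 5L,
    span_bp = 40L)
  pr2 <- mkpair(seq(100L, 139L, 10L), 0.9, 0.1)
  expect_equal(nrow(call_dmrs(cl4, pr2$a, pr2$b)), 0L)  # 40 bp: discarded

  # qualifying cluster, region levels 0.9 vs 0.45 -> diff -0.45 -> hypo DMR
  cl5 <- data.table::data.table(chrom = "Chr01", context = "CG",
    direction = "hypo", start_pos = 100L, end_pos = 250L, n_dmcs = 4L,
    span_bp = 151L)
  pr3 <- mkpair(c(100L, 150L, 200L, 250L), 0.9, 0.45, depth = 20L)
  dmr <- call_dmrs(cl5, pr3$a, pr3$b)
  expect_equal(nrow(dmr), 1L)
  expect_equal(dmr$region_level_a, 0.9)
  expect_equal(dmr$region_level_b, 0.45)
  expect_equal(dmr$direction, "hypo")

  # a difference exactly at the threshold is rejected (strict >)
  pr4 <- mkpair(c(100L, 150L, 200L, 250L), 0.9, 0.5, depth = 20L)
  expect_equal(nrow(call_dmrs(cl5, pr4$a, pr4$b)), 0L)
  # CHG threshold 0.2 would accept the same 0.45 difference
  clc <- data.table::copy(cl5)[, context := "CHG"]
  prc <- list(a = mk_mt(c(100L, 150L, 200L, 250L), 18L, 2L,
                        context = "CHG"),
              b = mk_mt(c(100L, 150L, 200L, 250L), 9L, 11L,
                        context = "CHG"))
  expect_equal(nrow(call_dmrs(clc, prc$a, prc$b)), 1L)
})

test_that("cross-context merging unions intervals within a direction only", {
  dmrs <- data.table::data.table(
    chrom = "Chr01",
    start_pos = c(100L, 150L), end_pos = c(199L, 249L),
    context = c("CG", "CHG"), n_dmcs = 4L,
    region_level_a = 0.1, region_level_b = 0.7, diff = 0.6,
    direction = c("hyper", "hyper"))
  m <- merge_contexts(dmrs)
  expect_equal(length(m$hyper), 1L)
  expect_equal(start(m$hyper), 100L)
  expect_equal(end(m$hyper), 249L)
  # opposite directions stay separate
  dmrs2 <- data.table::copy(dmrs)[, direction := c("hyper", "hypo")]
  m2 <- merge_contexts(dmrs2)
  expect_equal(length(m2$hyper), 1L)
  expect_equal(length(m2$hypo), 1L)
  expect_equal(end(m2$hyper), 199L)

  # known overlap graph: 10 context-DMRs -> hand-drawn union
  dmrs3 <- data.table::data.table(
    chrom = "Chr01",
    start_pos = c(100L, 150L, 160L, 500L, 700L, 720L, 900L, 1200L,
                  1250L, 2000L),
    end_pos = c(200L, 260L, 300L, 600L, 800L, 810L, 1000L, 1300L,
                1350L, 2100L),
    context = rep(c("CG", "CHG"), 5), n_dmcs = 4L,
    region_level_a = 0.1, region_level_b = 0.7, diff = 0.6,
    direction = c(rep("hyper", 7), rep("hypo", 3)))
  m3 <- merge_contexts(dmrs3)
  expect_equal(length(m3$hyper), 4L)  # {100-300, 500-600, 700-810, 900-1000}
  expect_equal(length(m3$hypo), 2L)   # {1200-1350, 2000-2100}
})

test_that("planted extreme sites are recovered with correct direction", {
  set.seed(77)
  n_null <- 10000
  pos_null <- seq(100L, by = 37L, length.out = n_null)
  p0 <- runif(n_null, 0.3, 0.5)
  d <- 30L
  ma <- rbinom(n_null, d, p0); mb <- rbinom(n_null, d, p0)
  pos_sig <- seq(max(pos_null) + 1000L, by = 37L, length.out = 100L)
  msa <- rbinom(100, d, 0.1); msb <- rbinom(100, d, 0.9)
  a <- mk_mt(c(pos_null, pos_sig), c(ma, msa), d - c(ma, msa))
  b <- mk_mt(c(pos_null, pos_sig), c(mb, msb), d - c(mb, msb))
  dmcs <- call_dmcs(a, b)
  found <- dmcs[dmcs$pos %in% pos_sig]
  expect_gte(nrow(found), 90L)
  expect_true(all(found$direction == "hyper"))
})

test_that("the pipeline funnel shrinks monotonically", {
  sm <- small_sim()
  pipe <- dmr_pipeline(sm$sim$a, sm$sim$b)
  f <- pipe$funnel
  expect_true(all(f$n_tested >= f$n_dmcs))
  expect_true(all(f$n_dmcs >= f$n_clusters))
  expect_true(all(f$n_clusters >= f$n_dmrs))
  # planted CG DMRs dominate the calls in the small simulation
  expect_gt(f$n_dmrs[f$context == "CG"], 0)
})
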