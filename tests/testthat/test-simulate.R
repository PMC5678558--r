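test_that("all four generators are deterministic per seed", {
  cfg <- sim_config(seed = 12, n_chroms = 2, chrom_length = 3e4,
                    dmr_count = 3, dmr_min_sites = 5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)
  a1 <- simulate_annotation(cfg, g1)
  a2 <- simulate_annotation(cfg, g2)
  expect_identical(start(a1$genes), start(a2$genes))
  expect_identical(a1$tes$te_class, a2$tes$te_class)
  s1 <- suppressWarnings(simulate_methylome_pair(cfg, g1, a1))
  s2 <- suppressWarnings(simulate_methylome_pair(cfg, g2, a2))
  expect_identical(s1$a$n_meth, s2$a$n_meth)
  expect_identical(s1$b$n_unmeth, s2$b$n_unmeth)
  expect_identical(start(s1$truth), start(s2$truth))
  m1 <- simulate_medip(cfg, s1$a, g1$chrom_lengths)
  m2 <- simulate_medip(cfg, s2$a, g2$chrom_lengths)
  expect_identical(start(m1$peaks), start(m2$peaks))
  expect_identical(m1$coverage$score, m2$coverage$score)
})

test_that("genome matches requested shape and GC content", {
  cfg <- sim_config(seed = 4, n_chroms = 2, chrom_length = 1e5, gc = 0.5)
  g <- simulate_genome(cfg)
  expect_equal(length(g$seqs), 2L)
  expect_equal(unname(nchar(g$seqs)), c(1e5, 1e5))
  gc_obs <- mean(strsplit(g$seqs[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 0.01)
  # FASTA export round-trips through Biostrings
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  ss <- Biostrings::readDNAStringSet(f)
  expect_equal(names(ss), names(g$seqs))
  expect_equal(as.character(ss[[1]]), g$seqs[[1]])
})

test_that("annotation respects requested counts and genome bounds", {
  cfg <- sim_config(seed = 6, n_chroms = 1, chrom_length = 2e5)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, g)
  expect_equal(length(ann$genes), round(80 * 2e5 / 1e6))
  expect_gte(length(ann$tes), round(150 * 2e5 / 1e6))  # + intronic TEs
  expect_true(all(start(ann$genes) >= 1))
  expect_true(all(end(ann$genes) <= 2e5))
  expect_true(all(end(ann$tes) <= 2e5))
  expect_true(all(ann$tes$te_class %in% names(cfg$te_class_mix)))
  # sub-features nest within genes (enforced by the constructor, so the
  # object exists at all)
  expect_s3_class(ann, "AnnotationSet")
})

test_that("a configured fraction of genes carries intronic TEs", {
  cfg <- sim_config(seed = 2, n_chroms = 2, chrom_length = 5e5,
                    intronic_te_fraction = 0.3)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, g)
  introns <- ann$features[ann$features$type == "intron"]
  hit <- unique(introns$gene_id[IRanges::overlapsAny(introns, ann$tes)])
  expect_lt(abs(length(hit) / length(ann$genes) - 0.3), 0.12)
})

test_that("simulated CX reports round-trip with zero rejected rows", {
  sm <- small_sim()
  f <- withr::local_tempfile(fileext = ".txt")
  write_cx_report(sm$sim$a, f)
  back <- read_cytosine_report(f, min_depth = 0)
  expect_equal(attr(back, "rows_in"), nrow(sm$sim$a))
  expect_equal(attr(back, "rows_filtered"), 0L)
  expect_identical(back$n_meth, sm$sim$a$n_meth)
  expect_identical(back$pos, sm$sim$a$pos)
  expect_identical(back$context, sm$sim$a$context)
})

test_that("site contexts derive from the actual sequence", {
  g <- list(seqs = c(Chr01 = "TACGGTCAGCCTTT"), chrom_lengths = c(Chr01 = 14))
  s <- methgrass:::cytosine_sites(g$seqs[[1]])
  plus <- s[s$strand == "+"]
  # C at 3 (CGG -> CG), C at 7 (CAG -> CHG), C at 10,11 (CCT->CHH, CTT->CHH)
  expect_equal(plus$pos, c(3L, 7L, 10L, 11L))
  expect_equal(plus$context, c("CG", "CHG", "CHH", "CHH"))
  minus <- s[s$strand == "-"]
  # on the minus strand the G positions are read 3'->5' of the plus strand:
  # G4 preceded by C3 -> CG; G5 has C two back -> CHG; G9 likewise CHG
  expect_equal(minus$pos, c(4L, 5L, 9L))
  expect_equal(minus$context, c("CG", "CHG", "CHG"))
})

test_that("truth set size is exact and observed levels track true means", {
  sm <- small_sim()
  expect_equal(length(sm$sim$truth), sm$cfg$dmr_count)
  expect_true(all(sm$sim$truth$direction %in% c("hyper", "hypo")))
  # every truth region holds at least the configured number of CG sites
  ns <- vapply(seq_along(sm$sim$truth), function(i) {
    tr <- sm$sim$truth[i]
    sum(sm$sim$a$context == "CG" &
          sm$sim$a$chrom == as.character(seqnames(tr)) &
          sm$sim$a$pos >= start(tr) & sm$sim$a$pos <= end(tr))
  }, 0L)
  expect_true(all(ns >= sm$cfg$dmr_min_sites))
})

test_that("observed levels converge to configured means at high depth", {
  cfg <- sim_config(seed = 13, n_chroms = 1, chrom_length = 2e5,
                    depth_mu = 200, depth_mu_repeat = 200, dmr_count = 0,
                    tss_dip_bp = 0, gypsy_flank_boost = 1)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, g)
  sim <- suppressWarnings(simulate_methylome_pair(cfg, g, ann))
  # with flat depth the intergenic solve makes the weighted CHG/CHH means
  # equal the configured targets
  expect_lt(abs(weighted_level(sim$a, "CHG")$level - cfg$chg_target),
            0.005)
  expect_lt(abs(weighted_level(sim$a, "CHH")$level - cfg$chh_target),
            0.005)
  # CG follows the marginal mixture expectation
  mus <- vapply(cfg$cg_components, function(ab) ab[1] / sum(ab), 0)
  expected_cg <- sum(cfg$cg_weights_genome * mus)
  expect_lt(abs(weighted_level(sim$a, "CG")$level - expected_cg), 0.01)
})

test_that("null configuration makes the genotypes exchangeable", {
  cfg <- sim_config(seed = 14, n_chroms = 1, chrom_length = 5e4,
                    dmr_count = 0, b_ratio = c(CG = 1, CHG = 1, CHH = 1))
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, g)
  sim <- suppressWarnings(simulate_methylome_pair(cfg, g, ann))
  wa <- weighted_level(sim$a, "CG")$level
  wb <- weighted_level(sim$b, "CG")$level
  expect_lt(abs(wa - wb), 0.02)
  dmcs <- call_dmcs(sim$a, sim$b)
  expect_lt(nrow(dmcs), 3)
})
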