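## Deterministic synthetic two-genotype methylome generator: genome,
## annotation, per-cytosine counts with planted DMRs, MeDIP-like peaks and
## coverage. Every stage is fully determined by the configuration seed.

#' Simulation configuration
#'
#' Builds the configuration for the synthetic two-genotype methylome. The
#' defaults emulate the broad shape of a plant WGBS study of two closely
#' related genotypes: context-specific weighted levels around 0.38/0.36
#' (CG), 0.25/0.24 (CHG) and 0.05/0.04 (CHH) for genotypes A and B; a
#' bimodal per-site CG level distribution (roughly 40% of sites below 0.2
#' and 48% above 0.6); TEs more methylated than genic regions; methylation
#' dips at gene TSS/TTS; elevated Gypsy-flank methylation; and
#' negative-binomial read depth with lower depth in repeat-like regions
#' (mirroring the reduced unique-mapping rate of repeats, which is what
#' reconciles a high per-site fraction of heavily methylated CGs with a
#' moderate read-weighted mean).
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_chroms,chrom_length,gc genome shape: number of chromosomes,
#'   length of each (bp), GC fraction.
#' @param genes_per_mb,tes_per_mb annotation densities.
#' @param te_class_mix named probabilities over TE classes.
#' @param intronic_te_fraction fraction of genes carrying an intronic TE.
#' @param cg_weights_genome genome-wide marginal CG mixture weights
#'   (low/mid/high component); per-category weights for TE and genic sites
#'   are fixed and the intergenic weights absorb the residual so the
#'   marginal is exact regardless of annotation randomness.
#' @param cg_components list of `c(alpha, beta)` for the low/mid/high CG
#'   Beta components.
#' @param chg_means,chh_means per-category (TE, gene) mean levels; the
#'   intergenic mean is solved so the read-weighted genome mean matches
#'   `chg_target` / `chh_target`.
#' @param chg_target,chh_target,cg_target genotype-A genome-wide weighted
#'   level targets per context.
#' @param b_ratio genotype-B/genotype-A scaling of true levels per context.
#' @param depth_mu,depth_mu_repeat,depth_size negative-binomial depth:
#'   mean for ordinary sites, mean for repeat-like sites (high-CG-component
#'   sites and TE non-CG sites), and dispersion size.
#' @param tss_dip_bp,tss_dip_depth methylation dip half-width around gene
#'   TSS/TTS and the multiplier at the boundary (ramping linearly to 1).
#' @param gypsy_flank_boost,gypsy_flank_bp multiplier applied to CG/CHG
#'   levels of non-TE sites within `gypsy_flank_bp` of an LTR/Gypsy element.
#' @param dmr_count,dmr_width,dmr_context,dmr_delta,dmr_hyper_fraction,
#'   dmr_base_mean,dmr_base_conc,dmr_min_sites planted-DMR block: number,
#'   width (bp), context, per-site effect size (the less-methylated side is
#'   drawn from `Beta(mean = dmr_base_mean, conc = dmr_base_conc)`
#'   truncated so the shifted side stays in \[0, 1\]), hyper fraction, and
#'   the minimum context sites a candidate region must contain.
#' @param medip_window,medip_base_cov,medip_cov_scale,medip_min_peak_cov
#'   MeDIP emulation: window size, background Poisson coverage, coverage
#'   per unit of summed site methylation in a window, and the absolute
#'   coverage floor for peak calling.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 1e6, gc = 0.46,
                       genes_per_mb = 80, tes_per_mb = 150,
                       te_class_mix = c("LTR/Copia" = 0.25,
                                        "LTR/Gypsy" = 0.35,
                                        "LINE" = 0.15, "DNA" = 0.20,
                                        "RC/Helitron" = 0.05),
                       intronic_te_fraction = 0.2,
                       cg_weights_genome = c(low = 0.385, mid = 0.085,
                                             high = 0.530),
                       cg_components = list(low = c(0.40, 9.60),
                                            mid = c(2.05, 2.95),
                                            high = c(12.0, 2.0)),
                       cg_target = 0.38,
                       chg_means = c(te = 0.62, gene = 0.12),
                       chg_target = 0.25,
                       chh_means = c(te = 0.08, gene = 0.03),
                       chh_target = 0.05,
                       b_ratio = c(CG = 0.36 / 0.38, CHG = 0.24 / 0.25,
                                   CHH = 0.04 / 0.05),
                       depth_mu = 22, depth_mu_repeat = 11,
                       depth_size = 5,
                       tss_dip_bp = 300, tss_dip_depth = 0.15,
                       gypsy_flank_boost = 1.6, gypsy_flank_bp = 2000,
                       dmr_count = 30, dmr_width = 300,
                       dmr_context = "CG", dmr_delta = 0.5,
                       dmr_hyper_fraction = 0.5, dmr_base_mean = 0.04,
                       dmr_base_conc = 2, dmr_min_sites = 8,
                       medip_window = 200, medip_base_cov = 2,
                       medip_cov_scale = 1, medip_min_peak_cov = 12) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc > 0, cfg$gc < 1,
            abs(sum(cfg$cg_weights_genome) - 1) < 1e-9,
            cfg$dmr_delta >= 0, cfg$dmr_delta <= 1,
            cfg$dmr_base_mean + cfg$dmr_delta <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a random genome
#'
#' Independent nucleotides at the configured GC fraction; deterministic
#' per seed.
#'
#' @param config a [sim_config()].
#' @return list with `seqs` (named character vector of chromosome
#'   sequences) and `chrom_lengths` (named numeric, bp).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  nm <- sprintf("Chr%02d", seq_len(config$n_chroms))
  seqs <- vapply(nm, function(ch)
    paste(sample(names(probs), config$chrom_length, replace = TRUE,
                 prob = probs), collapse = ""), "")
  list(seqs = seqs,
       chrom_lengths = setNames(rep(config$chrom_length,
                                    config$n_chroms), nm))
}

#' Write a simulated genome as FASTA
#' @param genome output of [simulate_genome()].
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Simulate a gene/TE annotation
#'
#' Places non-overlapping genes (5'UTR, 2-5 CDS exons with introns, 3'UTR;
#' random strand) and transposable elements (intergenic, plus one intronic
#' TE in a configurable fraction of genes) with class labels drawn from the
#' configured mix. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return an [annotation_set()].
#' @export
simulate_annotation <- function(config, genome) {
  set.seed(config$seed + 1L)
  genes_l <- list(); feats_l <- list(); tes_l <- list()
  min_gap <- 2500
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    ng <- round(config$genes_per_mb * L / 1e6)
    ## draw structures first, then place by splitting the leftover space
    structs <- lapply(seq_len(ng), function(i) {
      u5 <- sample(80:300, 1); u3 <- sample(80:300, 1)
      ne <- sample(2:5, 1)
      ex <- sample(150:500, ne, replace = TRUE)
      int <- if (ne > 1) sample(100:800, ne - 1, replace = TRUE) else
        integer(0)
      list(u5 = u5, u3 = u3, ex = ex, int = int,
           len = u5 + u3 + sum(ex) + sum(int))
    })
    lens <- vapply(structs, `[[`, 0, "len")
    extra <- L - sum(lens) - (ng + 1) * min_gap
    if (extra < 0) stop("requested genes exceed genome capacity")
    props <- diff(c(0, sort(runif(ng)), 1))
    gaps <- min_gap + floor(props * extra)
    starts <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0, head(lens, -1))) + 1
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    for (i in seq_len(ng)) {
      st <- structs[[i]]; s <- starts[i]; e <- s + st$len - 1
      gid <- sprintf("%s.g%03d", ch, i)
      ## left-to-right piece layout: utrL, exon/intron alternation, utrR
      pieces <- list(c(s, s + st$u5 - 1))
      cur <- s + st$u5
      cds <- list(); ints <- list()
      for (k in seq_along(st$ex)) {
        cds[[k]] <- c(cur, cur + st$ex[k] - 1)
        cur <- cur + st$ex[k]
        if (k < length(st$ex)) {
          ints[[k]] <- c(cur, cur + st$int[k] - 1)
          cur <- cur + st$int[k]
        }
      }
      utrR <- c(cur, cur + st$u3 - 1)
      utrL <- pieces[[1]]
      plus <- strands[i] == "+"
      genes_l[[length(genes_l) + 1L]] <-
        data.table(chrom = ch, start = s, end = e, strand = strands[i],
                   gene_id = gid)
      ft <- rbind(
        data.table(start = utrL[1], end = utrL[2],
                   type = if (plus) "five_prime_UTR" else
                     "three_prime_UTR"),
        data.table(start = vapply(cds, `[`, 0, 1),
                   end = vapply(cds, `[`, 0, 2), type = "CDS"),
        if (length(ints))
          data.table(start = vapply(ints, `[`, 0, 1),
                     end = vapply(ints, `[`, 0, 2), type = "intron"),
        data.table(start = utrR[1], end = utrR[2],
                   type = if (plus) "three_prime_UTR" else
                     "five_prime_UTR"))
      ft[, `:=`(chrom = ch, strand = strands[i], gene_id = gid)]
      feats_l[[length(feats_l) + 1L]] <- ft
    }
  }
  genes_dt <- rbindlist(genes_l)
  feats_dt <- rbindlist(feats_l, use.names = TRUE)

  ## intronic TEs: a fraction of genes gets one TE inside a random intron
  introns <- feats_dt[type == "intron"]
  with_introns <- unique(introns$gene_id)
  n_itg <- round(config$intronic_te_fraction * nrow(genes_dt))
  itg <- sample(with_introns, min(n_itg, length(with_introns)))
  for (gid in itg) {
    gi <- introns[gene_id == gid]
    gi <- gi[gi$end - gi$start + 1 >= 160]
    if (!nrow(gi)) next
    row <- gi[sample(nrow(gi), 1)]
    te_len <- sample(120:min(400, row$end - row$start + 1 - 20), 1)
    ts <- sample(row$start + 10:(row$end - row$start - te_len - 9), 1)
    tes_l[[length(tes_l) + 1L]] <-
      data.table(chrom = row$chrom, start = ts, end = ts + te_len - 1)
  }
  ## intergenic TEs, non-overlapping, by rejection sampling inside gaps
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    nt <- round(config$tes_per_mb * L / 1e6)
    gch <- genes_dt[chrom == ch]
    occ_s <- gch$start; occ_e <- gch$end
    lens <- pmin(pmax(round(stats::rlnorm(nt, log(800), 0.7)), 150), 6000)
    tries <- 0
    k <- 1
    ps <- integer(nt); pe <- integer(nt)
    while (k <= nt && tries < nt * 60) {
      tries <- tries + 1
      s <- sample.int(L - lens[k], 1)
      e <- s + lens[k] - 1L
      if (any(s <= occ_e & e >= occ_s)) next
      ps[k] <- s; pe[k] <- e
      occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
      k <- k + 1
    }
    if (k <= nt) stop("requested TEs exceed genome capacity")
    tes_l[[length(tes_l) + 1L]] <- data.table(chrom = ch, start = ps,
                                              end = pe)
  }
  tes_dt <- rbindlist(tes_l)
  tes_dt[, te_class := sample(names(config$te_class_mix), .N,
                              replace = TRUE,
                              prob = config$te_class_mix)]
  setorderv(tes_dt, c("chrom", "start"))

  genes <- GRanges(genes_dt$chrom, IRanges(genes_dt$start, genes_dt$end),
                   strand = genes_dt$strand)
  genes$gene_id <- genes_dt$gene_id
  features <- GRanges(feats_dt$chrom,
                      IRanges(feats_dt$start, feats_dt$end),
                      strand = feats_dt$strand)
  features$type <- feats_dt$type
  features$gene_id <- feats_dt$gene_id
  tes <- GRanges(tes_dt$chrom, IRanges(tes_dt$start, tes_dt$end))
  tes$te_class <- tes_dt$te_class
  annotation_set(genes, features, tes, genome$chrom_lengths)
}

#' Write an AnnotationSet as GFF3
#'
#' Emits gene/mRNA/exon/CDS/UTR rows (exons derived as the transcript span
#' minus introns) and TE rows of type `transposable_element` carrying a
#' `class` attribute, with `##sequence-region` pragmas, in a form that
#' round-trips through [read_gff3()].
#'
#' @param annotation an `AnnotationSet`.
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(annotation$chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       as.integer(annotation$chrom_lengths[[ch]])), con)
  gl <- function(chrom, src, type, s, e, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type,
            as.integer(s), as.integer(e), strand, attrs)
  lines <- character(0)
  g <- annotation$genes
  f <- annotation$features
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    ch <- as.character(seqnames(g))[i]
    st <- as.character(strand(g))[i]; if (st == "*") st <- "."
    mid <- paste0(gid, ".1")
    lines <- c(lines,
      gl(ch, "sim", "gene", start(g)[i], end(g)[i], st,
         paste0("ID=", gid)),
      gl(ch, "sim", "mRNA", start(g)[i], end(g)[i], st,
         paste0("ID=", mid, ";Parent=", gid)))
    sub <- f[f$gene_id == gid]
    introns <- sub[sub$type == "intron"]
    exons <- setdiff(granges(g[i]), granges(introns),
                     ignore.strand = TRUE)
    for (k in seq_along(exons))
      lines <- c(lines, gl(ch, "sim", "exon", start(exons)[k],
                           end(exons)[k], st, paste0("Parent=", mid)))
    for (tp in c("CDS", "five_prime_UTR", "three_prime_UTR")) {
      ss <- sub[sub$type == tp]
      for (k in seq_along(ss))
        lines <- c(lines, gl(ch, "sim", tp, start(ss)[k], end(ss)[k], st,
                             paste0("Parent=", mid)))
    }
  }
  te <- annotation$tes
  for (i in seq_along(te)) {
    st <- as.character(strand(te))[i]; if (st == "*") st <- "."
    lines <- c(lines,
      gl(as.character(seqnames(te))[i], "sim", "transposable_element",
         start(te)[i], end(te)[i], st,
         sprintf("ID=te%05d;class=%s", i, te$te_class[i])))
  }
  writeLines(lines, con)
  invisible(path)
}

## Enumerate cytosines on both strands of one sequence with their context.
cytosine_sites <- function(seq_string) {
  b <- strsplit(seq_string, "")[[1]]
  L <- length(b)
  ip <- which(b == "C")
  ip <- ip[ip <= L - 2]
  ctx_p <- ifelse(b[ip + 1] == "G", "CG",
                  ifelse(b[ip + 2] == "G", "CHG", "CHH"))
  im <- which(b == "G")
  im <- im[im >= 3]
  ctx_m <- ifelse(b[im - 1] == "C", "CG",
                  ifelse(b[im - 2] == "C", "CHG", "CHH"))
  data.table(pos = c(ip, im),
             strand = rep(c("+", "-"), c(length(ip), length(im))),
             context = c(ctx_p, ctx_m))
}

rbeta_mean <- function(n, mean, conc) {
  mean <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Simulate a two-genotype per-cytosine methylome pair
#'
#' Derives cytosine positions and contexts from the actual simulated
#' sequence (both strands), draws each site's true methylation level from a
#' context- and feature-dependent Beta (mixture) model -- TE sites
#' elevated, TSS/TTS dips, Gypsy flanks elevated -- scales genotype B's
#' levels by the configured per-context ratio, plants DMRs of the
#' configured effect size, and observes counts as
#' depth ~ NegBin, n_meth ~ Binomial(depth, level). Repeat-like sites
#' (high-CG-component sites and TE non-CG sites) receive the lower depth
#' mean, emulating reduced unique mappability of repeats.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param annotation output of [simulate_annotation()] (or any
#'   `AnnotationSet` over the same genome).
#' @return list with `a` and `b` (`MethylomeTable`s) and `truth` (`GRanges`
#'   of planted DMRs with `direction`, `context`, `delta`).
#' @export
simulate_methylome_pair <- function(config, genome, annotation) {
  set.seed(config$seed + 2L)
  sites_l <- lapply(names(genome$seqs), function(ch) {
    s <- cytosine_sites(genome$seqs[[ch]])
    s[, chrom := ch]
    s
  })
  sites <- rbindlist(sites_l)
  setorderv(sites, c("chrom", "pos", "strand"))
  n <- nrow(sites)
  sgr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))

  in_te <- overlapsAny(sgr, annotation$tes, ignore.strand = TRUE)
  in_gene <- !in_te & overlapsAny(sgr, annotation$genes,
                                  ignore.strand = TRUE)
  cat_site <- ifelse(in_te, "te", ifelse(in_gene, "gene", "intergenic"))

  is_cg <- sites$context == "CG"
  f <- c(te = mean(cat_site[is_cg] == "te"),
         gene = mean(cat_site[is_cg] == "gene"),
         intergenic = mean(cat_site[is_cg] == "intergenic"))

  ## per-category CG component weights; intergenic absorbs the residual so
  ## the genome-wide marginal equals cg_weights_genome exactly
  w_te <- c(0.08, 0.08, 0.84)
  w_gene <- c(0.62, 0.16, 0.22)
  w_int <- (config$cg_weights_genome - f[["te"]] * w_te -
              f[["gene"]] * w_gene) / f[["intergenic"]]
  if (any(w_int < 0) || any(w_int > 1)) {
    warning("intergenic CG weights clipped to the simplex; genome-wide ",
            "CG mixture will deviate from the configured marginal")
    w_int <- pmin(pmax(w_int, 0), 1)
    w_int <- w_int / sum(w_int)
  }
  wmat <- rbind(te = w_te, gene = w_gene, intergenic = w_int)

  comp <- integer(n)          # 0 = not CG; 1/2/3 = low/mid/high
  u <- runif(n)
  for (cat_ in rownames(wmat)) {
    idx <- which(is_cg & cat_site == cat_)
    cw <- cumsum(wmat[cat_, ])
    comp[idx] <- 1L + (u[idx] > cw[1]) + (u[idx] > cw[2])
  }
  p <- numeric(n)
  for (k in 1:3) {
    idx <- which(comp == k)
    ab <- config$cg_components[[k]]
    p[idx] <- rbeta(length(idx), ab[1], ab[2])
  }

  ## CHG / CHH: per-category Beta means; intergenic mean solved so the
  ## depth-weighted genome mean hits the configured target
  for (ctx in c("CHG", "CHH")) {
    mns <- if (ctx == "CHG") config$chg_means else config$chh_means
    target <- if (ctx == "CHG") config$chg_target else config$chh_target
    conc <- if (ctx == "CHG") 2 else 4
    sel <- sites$context == ctx
    fc <- c(te = mean(cat_site[sel] == "te"),
            gene = mean(cat_site[sel] == "gene"),
            intergenic = mean(cat_site[sel] == "intergenic"))
    d_te <- config$depth_mu_repeat; d_o <- config$depth_mu
    m_int <- (target * (fc[["te"]] * d_te +
                          (fc[["gene"]] + fc[["intergenic"]]) * d_o) -
                fc[["te"]] * d_te * mns[["te"]] -
                fc[["gene"]] * d_o * mns[["gene"]]) /
      (fc[["intergenic"]] * d_o)
    m_int <- min(max(m_int, 1e-3), 0.95)
    mm <- c(te = mns[["te"]], gene = mns[["gene"]], intergenic = m_int)
    for (cat_ in names(mm)) {
      idx <- which(sel & cat_site == cat_)
      p[idx] <- rbeta_mean(length(idx), mm[[cat_]], conc)
    }
  }

  ## TSS/TTS dip: multiplier ramps from tss_dip_depth at the boundary to 1
  ## at tss_dip_bp away, applied in all contexts
  if (length(annotation$genes) && config$tss_dip_bp > 0) {
    bnd <- c(GRanges(seqnames(annotation$genes),
                     IRanges(start(annotation$genes), width = 1L)),
             GRanges(seqnames(annotation$genes),
                     IRanges(end(annotation$genes), width = 1L)))
    dtn <- distanceToNearest(sgr, bnd)
    dd <- rep(NA_real_, n)
    dd[queryHits(dtn)] <- mcols(dtn)$distance
    near <- !is.na(dd) & dd <= config$tss_dip_bp
    mult <- config$tss_dip_depth + (1 - config$tss_dip_depth) *
      dd[near] / config$tss_dip_bp
    p[near] <- p[near] * mult
  }

  ## Gypsy flanks: CG/CHG of non-TE sites near LTR/Gypsy elements elevated
  gy <- annotation$tes[annotation$tes$te_class == "LTR/Gypsy"]
  if (length(gy) && config$gypsy_flank_boost > 1) {
    fl <- c(flank(gy, config$gypsy_flank_bp, start = TRUE,
                  ignore.strand = TRUE),
            flank(gy, config$gypsy_flank_bp, start = FALSE,
                  ignore.strand = TRUE))
    sel <- overlapsAny(sgr, fl, ignore.strand = TRUE) & !in_te &
      sites$context %in% c("CG", "CHG")
    p[sel] <- pmin(p[sel] * config$gypsy_flank_boost, 0.98)
  }

  ratio <- config$b_ratio[sites$context]
  pa <- p
  pb <- p * ratio

  ## plant DMRs: the less-methylated side is redrawn from the base Beta
  ## truncated to [0, 1 - delta]; the other side is shifted by exactly
  ## +delta at every site, so the regional difference is delta by design
  truth <- GRanges()
  planted <- logical(n)
  nd <- config$dmr_count
  if (nd > 0) {
    ctx_idx <- which(sites$context == config$dmr_context)
    dirs <- rep(c("hyper", "hypo"),
                c(round(nd * config$dmr_hyper_fraction), nd))[seq_len(nd)]
    dch <- character(nd); ds <- integer(nd); de <- integer(nd)
    placed <- 0L
    tries <- 0
    while (placed < nd && tries < nd * 100) {
      tries <- tries + 1
      ch <- sample(names(genome$chrom_lengths), 1)
      s <- sample.int(genome$chrom_lengths[[ch]] - config$dmr_width, 1)
      e <- s + config$dmr_width - 1L
      if (placed && any(dch[seq_len(placed)] == ch &
                          s <= de[seq_len(placed)] + 200L &
                          e >= ds[seq_len(placed)] - 200L)) next
      idx <- ctx_idx[sites$chrom[ctx_idx] == ch &
                       sites$pos[ctx_idx] >= s & sites$pos[ctx_idx] <= e]
      if (length(idx) < config$dmr_min_sites) next
      placed <- placed + 1L
      planted[idx] <- TRUE
      dch[placed] <- ch; ds[placed] <- s; de[placed] <- e
      base <- rbeta_mean(length(idx), config$dmr_base_mean,
                         config$dmr_base_conc)
      base <- pmin(base, 1 - config$dmr_delta)
      if (dirs[placed] == "hyper") {  # higher in genotype B
        pa[idx] <- base
        pb[idx] <- base + config$dmr_delta
      } else {
        pa[idx] <- base + config$dmr_delta
        pb[idx] <- base
      }
    }
    if (placed < nd)
      stop("could not place ", nd, " DMRs with >= ", config$dmr_min_sites,
           " ", config$dmr_context, " sites (placement retry cap hit)")
    truth <- GRanges(dch, IRanges(ds, de))
    truth$direction <- dirs
    truth$context <- config$dmr_context
    truth$delta <- config$dmr_delta
  }

  ## repeat-like (lower unique-mapping depth): heavily methylated CG sites
  ## and TE non-CG sites; planted sites had their level overridden, so
  ## their repeat-likeness follows TE membership of the sequence instead
  repeat_like <- ifelse(planted, in_te, (comp == 3L) | (in_te & !is_cg))
  mu <- ifelse(repeat_like, config$depth_mu_repeat, config$depth_mu)
  da <- rnbinom(n, size = config$depth_size, mu = mu)
  db <- rnbinom(n, size = config$depth_size, mu = mu)
  ma <- rbinom(n, da, pa)
  mb <- rbinom(n, db, pmin(pmax(pb, 0), 1))

  mk <- function(meth, depth, id) {
    methylome_table(data.table(chrom = sites$chrom, pos = sites$pos,
                               strand = sites$strand,
                               context = sites$context,
                               n_meth = meth, n_unmeth = depth - meth), id)
  }
  list(a = mk(ma, da, "genotypeA"), b = mk(mb, db, "genotypeB"),
       truth = truth)
}

#' Simulate MeDIP-like coverage and peaks from a methylome
#'
#' Converts windowed methylation (the sum of observed per-site levels in
#' each window, a proxy for the number of methylated cytosines an
#' anti-methylcytosine pull-down would capture) into expected coverage
#' through a linear link, adds Poisson noise, and calls peaks as merged
#' runs of windows whose coverage exceeds both the absolute floor and
#' twice the genome-wide median.
#'
#' @param config a [sim_config()].
#' @param mt a `MethylomeTable` (one genotype).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param seed_offset small integer added to the seed so the two genotypes
#'   get independent noise.
#' @return list with `coverage` (`GRanges` with `score`, bedGraph-ready)
#'   and `peaks` (`GRanges`).
#' @export
simulate_medip <- function(config, mt, chrom_lengths, seed_offset = 0L) {
  set.seed(config$seed + 10L + seed_offset)
  tiles <- tile_genome(chrom_lengths, config$medip_window)
  depth <- mt$n_meth + mt$n_unmeth
  keep <- depth > 0
  lev <- mt$n_meth[keep] / depth[keep]
  sgr <- GRanges(mt$chrom[keep], IRanges(mt$pos[keep], width = 1L))
  hits <- findOverlaps(sgr, tiles, ignore.strand = TRUE)
  msum <- numeric(length(tiles))
  if (length(hits)) {
    agg <- rowsum(lev[queryHits(hits)], subjectHits(hits))
    msum[as.integer(rownames(agg))] <- agg[, 1]
  }
  lambda <- config$medip_base_cov + config$medip_cov_scale * msum
  cov <- rpois(length(tiles), lambda)
  tiles$score <- cov
  thr <- max(config$medip_min_peak_cov, 2 * median(cov))
  peaks <- reduce(tiles[cov > thr], min.gapwidth = 1L)
  list(coverage = tiles, peaks = granges(peaks))
}
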