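#' @import data.table
#' @import GenomicRanges
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom stats rbinom rnbinom rpois rbeta runif p.adjust t.test
#'   dhyper phyper median quantile setNames complete.cases
#' @importFrom utils head tail
#' @importFrom methods is
NULL

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a per-cytosine methylome table
#'
#' A `MethylomeTable` holds one genotype's per-cytosine methylation calls:
#' chromosome, 1-based position, strand, sequence context (CG/CHG/CHH) and
#' the methylated/unmethylated read counts. Internally a keyed
#' [data.table::data.table] sorted by (chrom, pos, strand), so iteration is
#' always in ascending genomic order.
#'
#' @param calls data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`), `context` (`CG`, `CHG`, `CHH`; `CpG` is normalised to `CG`),
#'   `n_meth`, `n_unmeth` (non-negative integer read counts).
#' @param sample_id label for the genotype/sample (e.g. `"AP13"`).
#' @return A `MethylomeTable` (a keyed data.table with attribute `sample_id`).
#' @export
methylome_table <- function(calls, sample_id = "sample") {
  dt <- as.data.table(calls)
  req <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dt <- dt[, req, with = FALSE]
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, strand := as.character(strand)]
  dt[, context := normalize_context(context)]
  dt[, n_meth := as.integer(n_meth)]
  dt[, n_unmeth := as.integer(n_unmeth)]
  if (anyNA(dt$n_meth) || anyNA(dt$n_unmeth) ||
      any(dt$n_meth < 0) || any(dt$n_unmeth < 0))
    stop("read counts must be non-negative integers")
  if (!all(dt$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(dt$context %in% VALID_CONTEXTS))
    stop("context must be one of ", paste(VALID_CONTEXTS, collapse = ", "))
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) keys")
  setkeyv(dt, c("chrom", "pos", "strand"))
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "class", c("MethylomeTable", class(dt)))
  dt[]
}

normalize_context <- function(x) {
  x <- as.character(x)
  x[x == "CpG"] <- "CG"
  x
}

#' @export
print.MethylomeTable <- function(x, ...) {
  cat(sprintf("MethylomeTable '%s': %d cytosines on %d sequence(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    tab <- table(x$context)
    cat("  contexts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Read a Bismark-style cytosine (CX) report
#'
#' Expects the 7-column tab-separated per-cytosine format: chrom, 1-based
#' position, strand, count methylated, count unmethylated, context,
#' trinucleotide. The `CpG` context label is normalised to `CG`. Rows whose
#' total depth (meth + unmeth) is below `min_depth` are filtered out; the
#' counts of input/kept/filtered rows are attached as attributes so no
#' well-formed line is ever silently dropped. Malformed lines (wrong column
#' count, non-integer counts, unknown context) abort with the line number.
#'
#' @param path file path.
#' @param min_depth minimum read depth (meth + unmeth) for a row to be kept.
#' @param sample_id sample label; defaults to the file's base name.
#' @return A [methylome_table()] with attributes `rows_in`, `rows_kept`,
#'   `rows_filtered`.
#' @export
read_cytosine_report <- function(path, min_depth = 0, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) == 0) {
    empty <- methylome_table(data.table(chrom = character(), pos = integer(),
      strand = character(), context = character(),
      n_meth = integer(), n_unmeth = integer()), sample_id)
    setattr(empty, "rows_in", 0L)
    setattr(empty, "rows_kept", 0L)
    setattr(empty, "rows_filtered", 0L)
    return(empty)
  }
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE)
  if (ncol(dt) != 7)
    stop("cytosine report must have 7 tab-separated columns, found ",
         ncol(dt))
  setnames(dt, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                 "context", "tri"))
  # locate malformed rows precisely so the error can name a line number
  pos <- suppressWarnings(as.integer(dt$pos))
  nm <- suppressWarnings(as.integer(dt$n_meth))
  nu <- suppressWarnings(as.integer(dt$n_unmeth))
  ctx <- normalize_context(dt$context)
  bad <- which(is.na(pos) | is.na(nm) | is.na(nu) | nm < 0 | nu < 0 |
                 !(ctx %in% VALID_CONTEXTS) | !(dt$strand %in% c("+", "-")) |
                 dt$chrom == "")
  if (length(bad))
    stop("malformed cytosine report line ", bad[1], ": '",
         paste(unlist(dt[bad[1]]), collapse = "\t"), "'")
  out <- data.table(chrom = dt$chrom, pos = pos, strand = dt$strand,
                    context = ctx, n_meth = nm, n_unmeth = nu)
  rows_in <- nrow(out)
  out <- out[nm + nu >= min_depth]
  mt <- methylome_table(out, sample_id)
  setattr(mt, "rows_in", rows_in)
  setattr(mt, "rows_kept", nrow(out))
  setattr(mt, "rows_filtered", rows_in - nrow(out))
  mt
}

#' Write a methylome table as a cytosine (CX) report
#'
#' Emits the 7-column tab-separated format read by
#' [read_cytosine_report()]; the trinucleotide column is written as `"."`
#' (it is not retained in a `MethylomeTable`).
#'
#' @param mt a `MethylomeTable`.
#' @param path output file path.
#' @export
write_cx_report <- function(mt, path) {
  out <- data.table(mt$chrom, mt$pos, mt$strand, mt$n_meth, mt$n_unmeth,
                    mt$context, ".")
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Annotation

#' Construct an annotation set
#'
#' Bundles gene models, gene sub-features (CDS, UTRs, introns derived from
#' one representative transcript per gene), transposable elements with class
#' labels, and chromosome lengths.
#'
#' @param genes `GRanges` of gene spans with a `gene_id` metadata column.
#' @param features `GRanges` of gene sub-features with `type` in
#'   `CDS`/`five_prime_UTR`/`three_prime_UTR`/`intron` and `gene_id`.
#' @param tes `GRanges` of transposable elements with a `te_class` column.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(genes, features, tes, chrom_lengths) {
  stopifnot(is(genes, "GRanges"), is(features, "GRanges"), is(tes, "GRanges"))
  if (is.null(genes$gene_id)) stop("genes must carry a gene_id column")
  if (is.null(tes$te_class) && length(tes))
    stop("tes must carry a te_class column")
  if (length(features)) {
    ok <- features$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR",
                               "intron")
    if (!all(ok)) stop("unknown sub-feature type: ",
                       paste(unique(features$type[!ok]), collapse = ", "))
    hit <- findOverlaps(features, genes, type = "within")
    m <- match(features$gene_id, genes$gene_id)
    within_parent <- mapply(function(i, g) {
      any(subjectHits(hit)[queryHits(hit) == i] == g)
    }, seq_along(features), m)
    if (!all(within_parent))
      stop("sub-feature outside its parent gene span (feature ",
           which(!within_parent)[1], ")")
  }
  structure(list(genes = genes, features = features, tes = tes,
                 chrom_lengths = chrom_lengths),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d genes, %d sub-features, %d TEs, %d sequences\n",
              length(x$genes), length(x$features), length(x$tes),
              length(x$chrom_lengths)))
  if (length(x$tes)) {
    tab <- table(x$tes$te_class)
    cat("  TE classes:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Read a GFF3 annotation into an AnnotationSet
#'
#' Genes, mRNAs, exons, CDS and UTRs are taken from standard GFF3
#' parent/child structure; one representative transcript (the longest) is
#' retained per gene and introns are derived as the transcript span minus
#' its exons. Transposable elements are features of type
#' `transposable_element`, `repeat_region` or `transposon_fragment`; their
#' class is read from a `class` (or `te_class`) attribute, defaulting to
#' `"other"` with a warning when absent. Chromosome lengths come from
#' `##sequence-region` pragmas when present, else from the
#' `chrom_lengths` argument.
#'
#' @param path GFF3 file path.
#' @param chrom_lengths optional named vector of chromosome lengths (bp),
#'   used when the file carries no `##sequence-region` pragmas.
#' @return An [annotation_set()].
#' @export
read_gff3 <- function(path, chrom_lengths = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  hdr <- grep("^##sequence-region", readLines(path, n = 200), value = TRUE)
  if (length(hdr)) {
    parts <- strsplit(trimws(hdr), "[ \t]+")
    sl <- setNames(vapply(parts, function(x) as.numeric(x[4]), 0),
                   vapply(parts, `[`, "", 2))
  } else if (!is.null(chrom_lengths)) {
    sl <- chrom_lengths
  } else {
    stop("no ##sequence-region pragmas in ", path, "; supply chrom_lengths")
  }
  type <- as.character(gff$type)

  te_types <- c("transposable_element", "repeat_region",
                "transposon_fragment")
  tes <- gff[type %in% te_types]
  te_class <- if (!is.null(tes$class)) as.character(tes$class)
              else if (!is.null(tes$te_class)) as.character(tes$te_class)
              else rep(NA_character_, length(tes))
  if (anyNA(te_class) && length(tes)) {
    warning(sum(is.na(te_class)), " TE(s) lack a class attribute; ",
            "assigned te_class 'other'")
    te_class[is.na(te_class)] <- "other"
  }
  tes <- granges(tes)
  tes$te_class <- te_class

  genes <- gff[type == "gene"]
  gene_id <- as.character(genes$ID)
  genes_out <- granges(genes)
  genes_out$gene_id <- gene_id

  mrna <- gff[type == "mRNA"]
  feats <- list()
  if (length(mrna)) {
    mrna_parent <- as.character(unlist(mrna$Parent))
    if (length(mrna_parent) != length(mrna))
      stop("every mRNA must have exactly one Parent")
    # representative transcript: the longest per gene
    keep <- tapply(seq_along(mrna), mrna_parent, function(i)
      i[which.max(width(mrna)[i])])
    mrna <- mrna[unlist(keep)]
    mrna_parent <- as.character(unlist(mrna$Parent))
    mrna_id <- as.character(mrna$ID)
    # children within parent span check
    gsp <- genes_out[match(mrna_parent, genes_out$gene_id)]
    if (any(start(mrna) < start(gsp) | end(mrna) > end(gsp)))
      stop("mRNA outside its parent gene span")
    kids <- gff[type %in% c("exon", "CDS", "five_prime_UTR",
                            "three_prime_UTR")]
    kid_parent <- as.character(unlist(kids$Parent))
    sel <- kid_parent %in% mrna_id
    kids <- kids[sel]; kid_parent <- kid_parent[sel]
    msp <- mrna[match(kid_parent, mrna_id)]
    if (any(start(kids) < start(msp) | end(kids) > end(msp)))
      stop("child feature outside its parent mRNA span")
    ktype <- as.character(kids$type)
    gene_of <- genes_out$gene_id[match(mrna_parent, genes_out$gene_id)]
    for (i in seq_along(mrna)) {
      gi <- gene_of[i]
      k <- kids[kid_parent == mrna_id[i]]
      kt <- as.character(k$type)
      ex <- k[kt == "exon"]
      if (!length(ex)) ex <- k[kt %in% c("CDS", "five_prime_UTR",
                                         "three_prime_UTR")]
      introns <- setdiff(granges(mrna[i]), reduce(granges(ex)))
      sub <- c(granges(k[kt != "exon"]), introns)
      subtype <- c(kt[kt != "exon"], rep("intron", length(introns)))
      if (length(sub)) {
        sub$type <- subtype
        sub$gene_id <- gi
        feats[[length(feats) + 1L]] <- sub
      }
    }
  }
  features <- if (length(feats)) do.call(c, feats) else {
    gr <- GRanges()
    gr$type <- character(0); gr$gene_id <- character(0)
    gr
  }
  annotation_set(genes_out, features, tes, sl)
}

## ---------------------------------------------------------------------------
## BED-family interval I/O
##
## Internal container for region sets is GRanges (1-based closed, the
## Bioconductor convention); BED-family files are 0-based half-open and the
## +1/-0 shift happens here and only here.

#' Read BED / narrowPeak / bedGraph intervals
#'
#' BED-family files are 0-based half-open on disk; the returned `GRanges`
#' uses the usual 1-based closed convention. narrowPeak keeps its score
#' (column 5), bedGraph keeps its value as `score`.
#'
#' @param path file path.
#' @param dialect one of `"bed"`, `"narrowPeak"`, `"bedGraph"`; by default
#'   guessed from the file extension (falling back to `"bed"`).
#' @return `GRanges` with optional `name` and `score` metadata columns and a
#'   `source` attribute carrying the dialect.
#' @export
read_regions <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    ext <- tolower(sub(".*\\.", "", path))
    dialect <- switch(ext, narrowpeak = "narrowPeak",
                      bedgraph = "bedGraph", bg = "bedGraph", "bed")
  }
  dialect <- match.arg(dialect, c("bed", "narrowPeak", "bedGraph"))
  if (file.size(path) == 0) {
    gr <- GRanges()
    attr(gr, "source") <- dialect
    return(gr)
  }
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  start0 <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start0) | is.na(end) | start0 < 0 | start0 >= end)
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at line ", bad[1],
         " of ", path)
  gr <- GRanges(as.character(dt[[1]]),
                IRanges(start = as.integer(start0) + 1L,
                        end = as.integer(end)),
                strand = if (ncol(dt) >= 6 && dialect != "bedGraph")
                  ifelse(dt[[6]] %in% c("+", "-"), dt[[6]], "*") else "*")
  if (dialect == "bedGraph") {
    gr$score <- as.numeric(dt[[4]])
  } else {
    if (ncol(dt) >= 4) gr$name <- as.character(dt[[4]])
    if (ncol(dt) >= 5) gr$score <- as.numeric(dt[[5]])
  }
  attr(gr, "source") <- dialect
  gr
}

#' Write intervals as BED6 (plus optional extra columns)
#'
#' Coordinates are converted back to the BED 0-based half-open convention,
#' so `read_regions(write_regions(x))` round-trips exactly.
#'
#' @param regions `GRanges`.
#' @param path output path.
#' @param extra_columns optional data.frame of additional columns appended
#'   after the BED6 fields.
#' @export
write_regions <- function(regions, path, extra_columns = NULL) {
  n <- length(regions)
  nm <- if (!is.null(regions$name)) regions$name else
    if (n) paste0("region_", seq_len(n)) else character(0)
  sc <- if (!is.null(regions$score)) regions$score else rep(0, n)
  st <- as.character(strand(regions))
  st[st == "*"] <- "."
  out <- data.table(chrom = as.character(seqnames(regions)),
                    start = start(regions) - 1L, end = end(regions),
                    name = nm, score = sc, strand = st)
  if (!is.null(extra_columns)) out <- cbind(out, as.data.table(extra_columns))
  if (n == 0) { file.create(path); return(invisible(path)) }
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome length table (name TAB length)
#' @param path TSV path.
#' @return named numeric vector of lengths in bp.
#' @export
read_chrom_lengths <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

## Convert methylome positions to site GRanges (width-1, 1-based).
site_granges <- function(mt) {
  GRanges(mt$chrom, IRanges(mt$pos, width = 1L), strand = mt$strand)
}
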