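test_that("load_alignments honors SAM flags and splits spliced reads into blocks", {
  sq <- c(chrT = 2000L)
  seq22 <- strrep("A", 22L)
  recs <- data.frame(
    qname = c(paste0("p", 1:5), "sec1", "sec2", "unm"),
    flag = c(0L, 16L, 0L, 16L, 0L, 256L, 272L, 4L),
    chrom = c(rep("chrT", 7L), "*"),
    pos = c(10L, 50L, 100L, 150L, 200L, 10L, 50L, 0L),
    cigar = c(rep("22M", 7L), "*"),
    seq = rep(seq22, 8L), stringsAsFactors = FALSE)
  bam <- make_test_bam(recs, sq)

  aln <- load_alignments(bam, min_len = 0L, max_len = Inf)
  expect_equal(sort(aln$reads$read_id), sort(paste0("p", 1:5)))
  expect_equal(nrow(aln$reads), 5L)

  aln2 <- load_alignments(bam, min_len = 0L, max_len = Inf,
                          keep_secondary = TRUE)
  expect_equal(nrow(aln2$reads), 7L)

  # 22-nt read over a 100-nt intron: two 11-nt blocks
  spl <- data.frame(qname = "j1", flag = 16L, chrom = "chrT", pos = 301L,
                    cigar = "11M100N11M", seq = seq22,
                    stringsAsFactors = FALSE)
  bam2 <- make_test_bam(spl, sq)
  a <- load_alignments(bam2, 0L, Inf)
  b <- a$blocks
  expect_length(b, 2L)
  expect_equal(BiocGenerics::start(b), c(301L, 412L))
  expect_equal(BiocGenerics::end(b), c(311L, 422L))
  expect_equal(unique(S4Vectors::mcols(b)$read_id), "j1")
})

test_that("read-length bounds select exactly the in-range reads", {
  sq <- c(chrT = 50000L)
  set.seed(7)
  len <- c(sample(18:30, 200L, replace = TRUE),   # in range
           sample(c(10:16, 36:45), 50L, replace = TRUE))  # out of range
  recs <- data.frame(
    qname = paste0("r", seq_along(len)), flag = 0L, chrom = "chrT",
    pos = seq(1L, by = 60L, length.out = length(len)),
    cigar = paste0(len, "M"),
    seq = vapply(len, function(l) strrep("C", l), character(1)),
    stringsAsFactors = FALSE)
  bam <- make_test_bam(recs, sq)
  aln <- load_alignments(bam, min_len = 18L, max_len = 30L)
  expect_equal(nrow(aln$reads), 200L)
  expect_true(all(aln$reads$length >= 18L & aln$reads$length <= 30L))
})

test_that("load_alignments rejects missing index and unsorted input", {
  sq <- c(chrT = 100L)
  recs <- data.frame(qname = "r1", flag = 0L, chrom = "chrT", pos = 1L,
                     cigar = "22M", seq = strrep("A", 22L),
                     stringsAsFactors = FALSE)
  bam <- make_test_bam(recs, sq)
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(load_alignments(noidx), "index")

  # queryname-sorted header must be refused
  d <- tempfile("qs"); dir.create(d)
  sam <- file.path(d, "q.sam")
  writeLines(c("@HD\tVN:1.6\tSO:queryname", "@SQ\tSN:chrT\tLN:100",
               paste("r1", 0L, "chrT", 1L, 60L, "22M", "*", 0L, 0L,
                     strrep("A", 22L), strrep("I", 22L), sep = "\t")), sam)
  qbam <- Rsamtools::asBam(sam, file.path(d, "q"), overwrite = TRUE,
                           indexDestination = FALSE)
  file.create(paste0(qbam, ".bai"))
  expect_error(load_alignments(qbam), "sorted")
})

test_that("antisense filtering keeps opposite-strand overlaps only", {
  regions <- build_candidate_regions(features_granges(data.frame(
    chrom = "chrT", start = 101L, end = 200L, strand = "+",
    gene_id = "g1")))
  blk <- function(strand) {
    gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(121L, 142L),
                                 strand = strand)
    S4Vectors::mcols(gr)$read_id <- "r1"
    structure(list(blocks = gr,
                   reads = data.frame(read_id = "r1", strand = strand,
                                      seq = strrep("A", 22L), length = 22L)),
              class = "sr_alignments")
  }
  hit <- filter_antisense(blk("-"), regions)
  expect_length(hit, 1L)
  expect_equal(as.character(S4Vectors::mcols(hit)$gene_ids[[1L]]), "g1")
  expect_length(filter_antisense(blk("+"), regions), 0L)
})

test_that("antisense filtering matches the brute-force pair oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    fdf <- random_features_df(8L, chroms = "chrZ", max_pos = 1000L)
    regions <- build_candidate_regions(features_granges(fdf))
    n <- 100L
    start <- sample.int(980L, n, replace = TRUE)
    bdf <- data.frame(chrom = "chrZ", start = start, end = start + 21L,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(bdf$chrom,
                                 IRanges::IRanges(bdf$start, bdf$end),
                                 strand = bdf$strand)
    S4Vectors::mcols(gr)$read_id <- paste0("r", seq_len(n))
    aln <- structure(list(blocks = gr, reads = data.frame()),
                     class = "sr_alignments")
    got <- filter_antisense(aln, regions)
    rdf <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions)),
      start = BiocGenerics::start(regions),
      end = BiocGenerics::end(regions),
      strand = as.character(BiocGenerics::strand(regions)))
    keep <- brute_antisense(bdf, rdf)
    expect_equal(sort(S4Vectors::mcols(got)$read_id),
                 sort(paste0("r", which(keep))))
  }
})

test_that("r/s gating follows the documented threshold semantics", {
  # 10 identical blocks 0-based [100,122) = 1-based (101,122)
  h <- hits_granges("chrT", rep(101L, 10L), rep(122L, 10L), "-",
                    paste0("r", 1:10), rep("g1", 10L))
  r1 <- merge_into_sirna_regions(h, r = 10L, s = 10L)
  expect_length(r1, 1L)
  expect_equal(BiocGenerics::start(r1), 101L)
  expect_equal(BiocGenerics::end(r1), 122L)
  expect_equal(S4Vectors::mcols(r1)$read_count, 10L)
  expect_equal(as.character(BiocGenerics::strand(r1)), "-")

  # strictly-greater flag: 10 reads no longer pass r = 10
  expect_length(merge_into_sirna_regions(h, r = 10L, s = 10L,
                                         strict_greater_r = TRUE), 0L)

  h9 <- h[1:9]
  expect_length(merge_into_sirna_regions(h9, r = 10L, s = 10L), 0L)
})

test_that("chained blocks merge transitively into one region", {
  # 0-based [0,12),[10,22),[20,32) x4 each = 1-based (1,12),(11,22),(21,32)
  starts <- rep(c(1L, 11L, 21L), each = 4L)
  ends <- rep(c(12L, 22L, 32L), each = 4L)
  h <- hits_granges("chrT", starts, ends, "-", paste0("r", 1:12),
                    rep("g1", 12L))
  out <- merge_into_sirna_regions(h, r = 10L, s = 10L)
  expect_length(out, 1L)
  expect_equal(BiocGenerics::start(out), 1L)
  expect_equal(BiocGenerics::end(out), 32L)
  expect_equal(S4Vectors::mcols(out)$read_count, 12L)

  # per-base coverage connectivity oracle: one connected covered run
  cov <- sort(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
  expect_true(all(diff(cov) == 1L))
})

test_that("sirna BED serialization matches the contract and round-trips", {
  gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(101L, 122L),
                               strand = "-")
  S4Vectors::mcols(gr)$read_count <- 15L
  S4Vectors::mcols(gr)$gene_ids <- IRanges::CharacterList(list("g1"))
  bed <- tempfile(fileext = ".bed")
  write_sirna_bed(gr, bed)
  expect_equal(readLines(bed), "chrI\t100\t122\tg1.sir1\t15\t-")

  write_sirna_bed(gr[0L], bed)
  expect_equal(readLines(bed), character(0))

  # round trip through the independent parser
  gr2 <- c(gr, GenomicRanges::GRanges(
    "chrI", IRanges::IRanges(500L, 560L), strand = "+",
    read_count = 30L, gene_ids = IRanges::CharacterList(list(c("g2", "g3")))))
  write_sirna_bed(gr2, bed)
  back <- read_bed6(bed)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(gr2))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(gr2))
  expect_equal(as.numeric(S4Vectors::mcols(back)$score), c(15, 30))
  expect_equal(S4Vectors::mcols(back)$name, c("g1.sir1", "g2;g3.sir2"))
})

test_that("raising r or s never adds regions (monotonicity)", {
  fix <- make_fixture(dir = tempfile("mono"), seed = 5, n_clusters = 4,
                      reads_per_cluster = 14L)
  features <- parse_annotation(fix$gtf, "exon")
  regions <- build_candidate_regions(features)
  aln <- load_alignments(fix$bam)
  hits <- filter_antisense(aln, regions)
  key <- function(gr) paste(GenomicRanges::seqnames(gr),
                            BiocGenerics::start(gr), BiocGenerics::end(gr),
                            BiocGenerics::strand(gr))
  base <- key(merge_into_sirna_regions(hits, r = 10L, s = 10L))
  for (d in c(1L, 5L, 50L)) {
    expect_true(all(key(merge_into_sirna_regions(hits, r = 10L + d, s = 10L))
                    %in% base))
    expect_true(all(key(merge_into_sirna_regions(hits, r = 10L, s = 10L + d))
                    %in% base))
  }
})

test_that("siRNA regions sit inside their cluster's blocks, antisense to the feature", {
  fix <- make_fixture(dir = tempfile("cont"), seed = 9, n_clusters = 3)
  sir <- run_sirna(fix$bam, fix$gtf, out = tempfile(fileext = ".bed"))
  features <- parse_annotation(fix$gtf, "exon")
  ov <- GenomicRanges::findOverlaps(sir, features, ignore.strand = TRUE)
  expect_equal(length(ov), length(sir))
  expect_true(all(
    as.character(BiocGenerics::strand(sir))[S4Vectors::queryHits(ov)] !=
    as.character(BiocGenerics::strand(features))[S4Vectors::subjectHits(ov)]))
})
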