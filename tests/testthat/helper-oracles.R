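# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own interval/matching
# machinery: positions are enumerated base by base and strings compared by
# substring.

`%or%` <- function(a, b) if (is.null(a)) b else a

# ---- region-algebra oracle -------------------------------------------------

# df: chrom, start, end (1-based closed), strand
brute_covered <- function(df, str) {
  rows <- df[df$strand == str, , drop = FALSE]
  unique(unlist(lapply(seq_len(nrow(rows)), function(i) {
    paste0(rows$chrom[i], ":", seq(rows$start[i], rows$end[i]))
  })) %or% character(0))
}

# candidate positions per strand = same-strand cover minus both-strand cover
brute_candidate_positions <- function(df) {
  plus <- brute_covered(df, "+")
  minus <- brute_covered(df, "-")
  both <- intersect(plus, minus)
  list("+" = sort(setdiff(plus, both)), "-" = sort(setdiff(minus, both)))
}

granges_positions <- function(gr, str) {
  g <- gr[as.character(BiocGenerics::strand(gr)) == str]
  if (length(g) == 0L) return(character(0))
  sort(unlist(lapply(seq_along(g), function(i) {
    paste0(as.character(GenomicRanges::seqnames(g))[i], ":",
           seq(BiocGenerics::start(g)[i], BiocGenerics::end(g)[i]))
  })))
}

random_features_df <- function(n, chroms = c("chrA", "chrB"),
                               max_pos = 5000L) {
  start <- sample.int(max_pos - 250L, n, replace = TRUE)
  width <- sample(5:200, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             gene_id = paste0("g", seq_len(n)),
             stringsAsFactors = FALSE)
}

features_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         strand = df$strand, feature_kind = "exon",
                         gene_id = df$gene_id, attributes = "")
}

# ---- antisense-filter oracle ----------------------------------------------

# double loop over (block, region) pairs: >= 1 shared base, same chrom,
# opposite strand
brute_antisense <- function(blocks_df, regions_df) {
  keep <- logical(nrow(blocks_df))
  for (i in seq_len(nrow(blocks_df))) {
    for (j in seq_len(nrow(regions_df))) {
      if (blocks_df$chrom[i] == regions_df$chrom[j] &&
          blocks_df$strand[i] != regions_df$strand[j] &&
          blocks_df$start[i] <= regions_df$end[j] &&
          blocks_df$end[i] >= regions_df$start[j]) {
        keep[i] <- TRUE
      }
    }
  }
  keep
}

# ---- tail-calling oracle ---------------------------------------------------

brute_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# longest-common-prefix scan over every genomic offset and strand;
# genome_chr: named character vector of chromosome sequences
brute_tail <- function(seq, genome_chr, min_prefix) {
  n <- nchar(seq)
  if (n < min_prefix) return(NULL)
  for (L in seq(n, min_prefix)) {
    p <- substr(seq, 1L, L)
    hits <- list()
    for (chr in names(genome_chr)) {
      g <- genome_chr[[chr]]
      if (nchar(g) < L) next
      for (off in seq_len(nchar(g) - L + 1L)) {
        w <- substr(g, off, off + L - 1L)
        if (w == p) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chr, start = off, end = off + L - 1L, strand = "+",
            stringsAsFactors = FALSE)
        }
        if (w == brute_revcomp(p)) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chr, start = off, end = off + L - 1L, strand = "-",
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) {
      return(list(L = L, tail = substr(seq, L + 1L, n),
                  hits = do.call(rbind, hits)))
    }
  }
  NULL
}

# ---- hand-built BAMs -------------------------------------------------------

# records: data.frame qname, flag, chrom, pos, cigar, seq
make_test_bam <- function(records, seqlens, dir = tempfile("tbam")) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "t.sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(seqlens), "\tLN:", seqlens))
  body <- with(records, paste(qname, flag, chrom, pos,
                              ifelse(flag == 4L, 0L, 60L), cigar, "*", 0L,
                              0L, seq, strrep("I", nchar(seq)), sep = "\t"))
  writeLines(c(header, body), sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# hits GRanges in the shape filter_antisense() emits
hits_granges <- function(chrom, start, end, strand, read_id, gene) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$read_id <- read_id
  S4Vectors::mcols(gr)$gene_ids <-
    IRanges::CharacterList(as.list(gene))
  gr
}
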