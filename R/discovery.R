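#' Load small-RNA alignments as reference-matched blocks
#'
#' Reads a coordinate-sorted, indexed BAM and decomposes each primary,
#' mapped alignment into reference-matched blocks: match/deletion segments
#' merged, split at skipped-region (`N`, intron) segments. A spliced
#' alignment therefore yields one entry per exon-side segment. Read length
#' is the full query sequence length (soft clips included) and the length
#' filter is applied to it.
#'
#' @param path Path to a coordinate-sorted, indexed BAM file.
#' @param min_len,max_len Inclusive read-length bounds in nt. Defaults
#'   17-35, the conventional small-RNA range; `c(0, Inf)` disables the
#'   filter.
#' @param keep_secondary Admit secondary alignments (default drops them;
#'   supplementary and unmapped records are always dropped).
#' @return An object of class `sr_alignments`: a list with `blocks` (a
#'   `GRanges`, one range per block, strand = alignment strand, metadata
#'   `read_id`) and `reads` (a `data.frame` of `read_id`, `strand`, `seq`
#'   in original read orientation, `length`).
#' @export
load_alignments <- function(path, min_len = 17L, max_len = 35L,
                            keep_secondary = FALSE) {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("BAM index not found for ", path,
         "; create one with samtools index or Rsamtools::indexBam()")
  }
  if (min_len > max_len) stop("min_len must be <= max_len")

  hdr <- Rsamtools::scanBamHeader(path)[[1L]]$text
  hd <- hdr[["@HD"]]
  if (!is.null(hd)) {
    so <- sub("^SO:", "", grep("^SO:", hd, value = TRUE))
    if (length(so) == 1L && so != "coordinate") {
      stop("BAM is not coordinate-sorted (SO:", so,
           "); sort it with samtools sort")
    }
  }

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (keep_secondary) NA else FALSE,
    isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("seq"))
  aln <- GenomicAlignments::readGAlignments(path, param = param,
                                            use.names = TRUE)

  seqs <- S4Vectors::mcols(aln)$seq
  len <- BiocGenerics::width(seqs)
  keep <- len >= min_len & len <= max_len
  aln <- aln[keep]
  seqs <- seqs[keep]
  len <- len[keep]

  strand <- as.character(BiocGenerics::strand(aln))
  # SEQ is stored reference-forward; recover original read orientation
  if (any(strand == "-")) {
    seqs[strand == "-"] <- Biostrings::reverseComplement(seqs[strand == "-"])
  }

  blocks_list <- GenomicAlignments::grglist(aln, drop.D.ranges = FALSE)
  blocks <- BiocGenerics::unlist(blocks_list, use.names = FALSE)
  S4Vectors::mcols(blocks)$read_id <- rep(names(aln),
                                          lengths(blocks_list))

  structure(list(
    blocks = blocks,
    reads = data.frame(read_id = names(aln), strand = strand,
                       seq = as.character(seqs), length = len,
                       stringsAsFactors = FALSE)
  ), class = "sr_alignments")
}

#' Pool alignments from several BAM files
#'
#' Reads are pooled before clustering; read ids are prefixed with the file
#' index so ids stay unique across samples.
#'
#' @param paths Character vector of BAM paths.
#' @inheritParams load_alignments
#' @return An `sr_alignments` object.
#' @export
load_alignments_pooled <- function(paths, min_len = 17L, max_len = 35L,
                                   keep_secondary = FALSE) {
  parts <- lapply(seq_along(paths), function(i) {
    a <- load_alignments(paths[[i]], min_len, max_len, keep_secondary)
    pre <- paste0("s", i, ":")
    S4Vectors::mcols(a$blocks)$read_id <-
      paste0(pre, S4Vectors::mcols(a$blocks)$read_id)
    a$reads$read_id <- paste0(pre, a$reads$read_id)
    a
  })
  structure(list(
    blocks = do.call(c, lapply(parts, `[[`, "blocks")),
    reads = do.call(rbind, lapply(parts, `[[`, "reads"))
  ), class = "sr_alignments")
}

#' Keep read blocks mapping antisense to a candidate region
#'
#' Emits each read block that shares at least one base (same chromosome)
#' with a candidate region whose strand is opposite to the read's alignment
#' strand. Blocks overlapping no region, or only same-strand regions, are
#' dropped. Region-set disjointness guarantees each block pairs with at
#' most one region.
#'
#' @param alignments `sr_alignments` from [load_alignments()].
#' @param regions Candidate `GRanges` from [build_candidate_regions()].
#' @return A `GRanges` of retained blocks
#'   (strand = read strand) with metadata `read_id` and `gene_ids` (the
#'   parent region's genes).
#' @export
filter_antisense <- function(alignments, regions) {
  blocks <- alignments$blocks
  if (length(blocks) == 0L || length(regions) == 0L) {
    hits <- GenomicRanges::GRanges()
    S4Vectors::mcols(hits) <- S4Vectors::DataFrame(
      read_id = character(0), gene_ids = IRanges::CharacterList())
    return(hits)
  }
  ov <- GenomicRanges::findOverlaps(blocks, regions, ignore.strand = TRUE)
  anti <- as.character(BiocGenerics::strand(blocks))[S4Vectors::queryHits(ov)] !=
    as.character(BiocGenerics::strand(regions))[S4Vectors::subjectHits(ov)]
  ov <- ov[anti]
  hits <- blocks[S4Vectors::queryHits(ov)]
  S4Vectors::mcols(hits)$gene_ids <-
    S4Vectors::mcols(regions)$gene_ids[S4Vectors::subjectHits(ov)]
  hits
}

#' Merge antisense read blocks into putative siRNA regions
#'
#' Within each (chromosome, read-strand) group, blocks are merged
#' transitively: a block joins a cluster if it shares at least one base
#' with any block already in it (single-linkage interval merging). A
#' cluster becomes a putative siRNA region if its distinct supporting-read
#' count passes the support gate `r` and its merged span is at least `s`
#' base pairs.
#'
#' @param hits `sr_hits` from [filter_antisense()].
#' @param r Minimum supporting reads (default 10). The gate is
#'   `count >= r`; set `strict_greater_r = TRUE` for `count > r`.
#' @param s Minimum span in bp (default 10), inclusive.
#' @param strict_greater_r Use the strictly-greater reading of the support
#'   threshold.
#' @return `GRanges` of siRNA regions (strand = read strand) with metadata
#'   `read_count` and `gene_ids`, sorted by (chrom, start).
#' @export
merge_into_sirna_regions <- function(hits, r = 10L, s = 10L,
                                     strict_greater_r = FALSE) {
  stopifnot(r >= 1L, s >= 1L)
  empty <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      read_count = integer(0), gene_ids = IRanges::CharacterList())
    gr
  }
  if (length(hits) == 0L) return(empty())

  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(hits),
    ranges = IRanges::ranges(hits),
    strand = BiocGenerics::strand(hits))
  clusters <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(clusters, gr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)

  fac <- factor(qh, levels = seq_along(clusters))
  read_count <- as.integer(tapply(
    S4Vectors::mcols(hits)$read_id[sh],
    fac, function(x) length(unique(x)), default = 0L))
  gene_sets <- tapply(sh, fac, function(i) {
    sort(unique(unlist(S4Vectors::mcols(hits)$gene_ids[i])))
  }, simplify = FALSE)
  gene_sets[vapply(gene_sets, is.null, logical(1))] <- list(character(0))

  S4Vectors::mcols(clusters)$read_count <- read_count
  S4Vectors::mcols(clusters)$gene_ids <- IRanges::CharacterList(gene_sets)

  pass_r <- if (strict_greater_r) read_count > r else read_count >= r
  pass_s <- BiocGenerics::width(clusters) >= s
  out <- clusters[pass_r & pass_s]
  if (length(out) == 0L) return(empty())
  BiocGenerics::sort(out, ignore.strand = TRUE)
}

#' Write putative siRNA regions as BED6
#'
#' Six columns, 0-based half-open: chrom, start, end, name (semicolon-joined
#' gene ids plus a `.sirN` serial suffix), score (supporting read count),
#' strand (read strand). Rows are sorted by (chrom, start).
#'
#' @param regions `GRanges` from [merge_into_sirna_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sirna_bed <- function(regions, path) {
  regions <- BiocGenerics::sort(regions, ignore.strand = TRUE)
  genes <- vapply(S4Vectors::mcols(regions)$gene_ids,
                  paste, character(1), collapse = ";")
  genes[!nzchar(genes)] <- "NA"
  name <- paste0(genes, ".sir", seq_along(regions))
  write_bed6(regions, name = name,
             score = S4Vectors::mcols(regions)$read_count, path = path)
}
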