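# Synthetic-fixture generator: toy genome, annotation, and reads with
# planted antisense siRNA clusters and known 3' tails, plus a ground-truth
# manifest. Everything is deterministic under a fixed seed and text-based
# (SAM is converted to sorted/indexed BAM at run time).

#' Generate a toy genome
#'
#' I.i.d. uniform A/C/G/T sequences, deterministic for a fixed seed.
#'
#' @param n_chroms Number of reference sequences.
#' @param length Length of each sequence in bp (>= 1000).
#' @param seed Integer seed.
#' @return A `DNAStringSet` named `chr1..chrN`.
#' @export
make_genome <- function(n_chroms = 1L, length = 10000L, seed = 1L) {
  stopifnot(length >= 1000L)
  set.seed(seed)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chroms))
  genome
}

#' Write a genome FASTA with index
#'
#' 60-column line wrapping; a `.fai` index is created alongside.
#'
#' @param genome `DNAStringSet` from [make_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Generate a toy annotation layout
#'
#' Places non-overlapping genes sequentially along the genome (round-robin
#' over chromosomes), alternating strands by default. Multi-exon genes
#' carry introns of at least 50 bp. Same-strand and cross-strand
#' overlapping gene pairs can be injected for region-algebra tests; they
#' are recorded in the layout (`overlap_role` column) so oracle tests know
#' where to look.
#'
#' @param genome `DNAStringSet`.
#' @param n_genes Number of (non-injected) genes.
#' @param exons_per_gene Exons per gene (introns of `intron_len` bp).
#' @param exon_len,intron_len,gap Sizes in bp; `gap` separates genes.
#' @param strands Optional character vector recycled over genes; default
#'   alternates `+`/`-`.
#' @param same_strand_overlaps,cross_strand_overlaps Number of extra genes
#'   injected to overlap an existing gene on the same / the opposite
#'   strand.
#' @return A `data.frame` layout: `gene_id`, `chrom`, `exon`, `start`,
#'   `end` (1-based inclusive, GTF convention), `strand`, `overlap_role`.
#' @export
make_annotation <- function(genome, n_genes = 10L, exons_per_gene = 1L,
                            exon_len = 300L, intron_len = 100L, gap = 150L,
                            strands = NULL,
                            same_strand_overlaps = 0L,
                            cross_strand_overlaps = 0L) {
  stopifnot(intron_len >= 50L, exon_len >= 50L)
  if (is.null(strands)) strands <- c("+", "-")
  strands <- rep_len(strands, n_genes)
  chrom_len <- stats::setNames(BiocGenerics::width(genome), names(genome))
  gene_span <- exons_per_gene * exon_len + (exons_per_gene - 1L) * intron_len

  pos <- stats::setNames(rep(1L, length(genome)), names(genome))
  rows <- list()
  for (i in seq_len(n_genes)) {
    chrom <- names(genome)[(i - 1L) %% length(genome) + 1L]
    start <- pos[[chrom]] + gap
    if (start + gene_span - 1L > chrom_len[[chrom]]) {
      stop("cannot place gene ", i, " on ", chrom,
           ": genome too short for requested layout")
    }
    for (e in seq_len(exons_per_gene)) {
      es <- start + (e - 1L) * (exon_len + intron_len)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0("g", i), chrom = chrom, exon = e,
        start = es, end = es + exon_len - 1L, strand = strands[i],
        overlap_role = "none", stringsAsFactors = FALSE)
    }
    pos[[chrom]] <- start + gene_span
  }
  layout <- do.call(rbind, rows)

  inject <- function(layout, n, role) {
    hosts <- unique(layout$gene_id[layout$overlap_role == "none"])
    if (n > length(hosts)) stop("not enough genes to host injected overlaps")
    for (j in seq_len(n)) {
      host <- layout[layout$gene_id == hosts[j] & layout$exon == 1L, ]
      str <- if (role == "same") host$strand else flip_strand(host$strand)
      ns <- host$start + exon_len %/% 2L  # overlap host exon 1 by half
      layout <- rbind(layout, data.frame(
        gene_id = paste0(host$gene_id, "_", role, "ov"), chrom = host$chrom,
        exon = 1L, start = ns, end = ns + exon_len - 1L, strand = str,
        overlap_role = role, stringsAsFactors = FALSE))
      layout$overlap_role[layout$gene_id == host$gene_id] <- paste0(role, "_host")
    }
    layout
  }
  if (same_strand_overlaps > 0L) layout <- inject(layout, same_strand_overlaps, "same")
  if (cross_strand_overlaps > 0L) layout <- inject(layout, cross_strand_overlaps, "cross")
  max_end <- tapply(layout$end, layout$chrom, max)
  stopifnot(all(max_end <= chrom_len[names(max_end)]))
  rownames(layout) <- NULL
  layout
}

#' Write a layout as GTF
#'
#' One `exon` line per layout row, `gene_id`/`transcript_id` attributes.
#'
#' @param layout From [make_annotation()].
#' @param path Output path (use a `.gtf` extension so dialect detection
#'   works downstream).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(layout, path) {
  attrs <- paste0("gene_id \"", layout$gene_id, "\"; transcript_id \"",
                  layout$gene_id, ".t1\";")
  lines <- paste(layout$chrom, "sirtail_sim", "exon", layout$start,
                 layout$end, ".", layout$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Default planted-cluster specification
#'
#' One cluster in exon 1 of each of the first `k` non-injected genes.
#'
#' @param layout From [make_annotation()].
#' @param k Number of clusters.
#' @param n_reads Reads per cluster.
#' @param span Coverage footprint span in bp (>= read length).
#' @param label Free-text label stored in the manifest (e.g. `"pass"`).
#' @return `data.frame` cluster spec for [make_reads()].
#' @export
default_clusters <- function(layout, k, n_reads = 12L, span = 60L,
                             label = "pass") {
  genes <- unique(layout$gene_id[layout$overlap_role == "none"])
  stopifnot(k <= length(genes))
  data.frame(gene_id = genes[seq_len(k)], exon = 1L, n_reads = n_reads,
             span = span, n_junction = 0L, label = label,
             stringsAsFactors = FALSE)
}

# The read-orientation base that would extend the templated prefix of a
# read covering genome[start..end] (1-based) by one nucleotide; "" at a
# chromosome boundary.
next_templated_base <- function(genome, chrom, start, end, read_strand) {
  if (read_strand == "+") {
    if (end + 1L > BiocGenerics::width(genome[chrom])) return("")
    as.character(Biostrings::subseq(genome[[chrom]], end + 1L, end + 1L))
  } else {
    if (start - 1L < 1L) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], start - 1L, start - 1L)))
  }
}

#' Generate reads with planted antisense clusters and known tails
#'
#' For every row of `clusters`, plants `n_reads` reads of length
#' `read_len` antisense to the stated exon of the stated gene: read
#' sequences are reverse complements of exonic windows (for `+` genes;
#' genomic-sense sequences for `-` genes), evenly tiled so the coverage
#' footprint is exactly `span` bp and consecutive reads overlap. Tails are
#' drawn per read from `tail_spec` and appended to the read 3' end; in the
#' alignment records they are soft-clipped, as a real aligner would emit
#' them. `n_junction` extra antisense reads per cluster span the junction
#' into the next exon (CIGAR `xMyNzM`). Sense-strand decoys inside exons
#' and intergenic noise reads are added at `noise_frac` of the planted
#' total. Output is a coordinate-sorted, indexed BAM, a FASTQ, and a JSON
#' ground-truth manifest.
#'
#' @param genome `DNAStringSet`.
#' @param layout From [make_annotation()].
#' @param clusters Cluster spec, e.g. [default_clusters()]: columns
#'   `gene_id`, `exon`, `n_reads`, `span`, `n_junction`, `label`.
#' @param read_len Read length in nt (default 22, nematode-siRNA-like).
#' @param tail_spec Named probability vector over tail strings (RNA or DNA
#'   alphabet; name `""` = untailed). Must sum to 1. Default: all untailed.
#' @param noise_frac Noise reads as a fraction of planted reads (default
#'   0.1), split evenly between sense-exonic and intergenic.
#' @param seed Integer seed; the whole fixture is deterministic in it.
#' @param dir Output directory (created if needed).
#' @return A list: `bam`, `fastq`, `sam`, `manifest_path`, and `manifest`
#'   (regions with 0-based half-open footprints on the read strand,
#'   per-region tail counts, per-gene planted read totals, noise counts).
#' @export
make_reads <- function(genome, layout, clusters, read_len = 22L,
                       tail_spec = stats::setNames(1, ""),
                       noise_frac = 0.1, seed = 1L, dir = tempfile("fix")) {
  if (abs(sum(tail_spec) - 1) > 1e-9) {
    stop("tail_spec probabilities must sum to 1")
  }
  stopifnot(all(clusters$span >= read_len))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tails_dna <- chartr("U", "T", names(tail_spec))

  recs <- list()   # SAM record fields per read
  rid <- 0L
  add_read <- function(chrom, pos, read_strand, templ_ref, tail_dna,
                       cigar_core) {
    # templ_ref: templated part in reference-forward orientation
    rid <<- rid + 1L
    read_seq <- if (read_strand == "-") {
      paste0(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(templ_ref))), tail_dna)
    } else {
      paste0(templ_ref, tail_dna)
    }
    t <- nchar(tail_dna)
    if (read_strand == "-") {
      stored <- paste0(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tail_dna))), templ_ref)
      cigar <- if (t > 0L) paste0(t, "S", cigar_core) else cigar_core
      flag <- 16L
    } else {
      stored <- paste0(templ_ref, tail_dna)
      cigar <- if (t > 0L) paste0(cigar_core, t, "S") else cigar_core
      flag <- 0L
    }
    recs[[length(recs) + 1L]] <<- list(
      qname = sprintf("r%06d", rid), flag = flag, chrom = chrom, pos = pos,
      cigar = cigar, stored = stored, read = read_seq)
    invisible(rid)
  }

  region_rows <- list()
  region_tails <- list()
  gene_counts <- list()

  for (ci in seq_len(nrow(clusters))) {
    cl <- clusters[ci, ]
    ex <- layout[layout$gene_id == cl$gene_id & layout$exon == cl$exon, ]
    if (nrow(ex) != 1L) stop("cluster gene/exon not found in layout: ",
                             cl$gene_id, "/", cl$exon)
    exon_w <- ex$end - ex$start + 1L
    if (cl$span > exon_w) stop("cluster span exceeds exon width")
    w0 <- ex$start + sample.int(exon_w - cl$span + 1L, 1L) - 1L
    read_strand <- flip_strand(ex$strand)

    starts <- if (cl$n_reads == 1L) w0 else
      round(seq(w0, w0 + cl$span - read_len, length.out = cl$n_reads))
    spacing <- diff(sort(starts))
    if (length(spacing) && any(spacing >= read_len)) {
      stop("cluster ", ci, " cannot tile span ", cl$span, " with ",
           cl$n_reads, " reads of ", read_len, " nt without gaps")
    }
    drawn <- integer(cl$n_reads)
    for (j in seq_len(cl$n_reads)) {
      templ <- as.character(Biostrings::subseq(genome[[ex$chrom]],
                                               starts[j],
                                               starts[j] + read_len - 1L))
      # a tail whose first base continues the genome would be templated,
      # not nontemplated: redraw until the planted tail is recoverable
      nxt <- next_templated_base(genome, ex$chrom, starts[j],
                                 starts[j] + read_len - 1L, read_strand)
      recoverable <- function(k) {
        tails_dna[k] == "" || substr(tails_dna[k], 1L, 1L) != nxt
      }
      k <- sample(seq_along(tail_spec), 1L, prob = tail_spec)
      tries <- 0L
      while (!recoverable(k) && tries < 100L) {
        k <- sample(seq_along(tail_spec), 1L, prob = tail_spec)
        tries <- tries + 1L
      }
      if (!recoverable(k)) {
        k <- match("", tails_dna)
        if (is.na(k)) stop("tail_spec has no tail recoverable at this locus")
      }
      drawn[j] <- k
      add_read(ex$chrom, starts[j], read_strand, templ, tails_dna[k],
               paste0(read_len, "M"))
    }

    n_j <- if (!is.null(cl$n_junction)) cl$n_junction else 0L
    if (n_j > 0L) {
      ex2 <- layout[layout$gene_id == cl$gene_id & layout$exon == cl$exon + 1L, ]
      if (nrow(ex2) != 1L) stop("junction reads need a following exon")
      k <- read_len %/% 2L
      intron <- ex2$start - ex$end - 1L
      for (j in seq_len(n_j)) {
        b1 <- as.character(Biostrings::subseq(genome[[ex$chrom]],
                                              ex$end - k + 1L, ex$end))
        b2 <- as.character(Biostrings::subseq(genome[[ex$chrom]],
                                              ex2$start,
                                              ex2$start + (read_len - k) - 1L))
        add_read(ex$chrom, ex$end - k + 1L, read_strand,
                 paste0(b1, b2), "",
                 paste0(k, "M", intron, "N", read_len - k, "M"))
      }
    }

    region_id <- paste0("planted", ci)
    region_rows[[ci]] <- data.frame(
      region_id = region_id, gene_id = cl$gene_id, chrom = ex$chrom,
      start = w0 - 1L, end = w0 - 1L + cl$span,  # 0-based half-open footprint
      strand = read_strand, n_reads = cl$n_reads, span = cl$span,
      n_junction = n_j, label = cl$label, stringsAsFactors = FALSE)
    tl <- table(chartr("T", "U", names(tail_spec))[drawn])
    region_tails[[region_id]] <- stats::setNames(as.integer(tl), names(tl))
    gene_counts[[cl$gene_id]] <-
      (gene_counts[[cl$gene_id]] %||% 0L) + cl$n_reads + n_j
  }

  n_planted <- rid
  n_noise <- round(noise_frac * n_planted)
  n_sense <- n_noise %/% 2L
  n_inter <- n_noise - n_sense

  exon_rows <- layout[layout$overlap_role == "none", , drop = FALSE]
  for (j in seq_len(n_sense)) {
    ex <- exon_rows[sample.int(nrow(exon_rows), 1L), ]
    p <- ex$start + sample.int(ex$end - ex$start + 2L - read_len, 1L) - 1L
    templ <- as.character(Biostrings::subseq(genome[[ex$chrom]], p,
                                             p + read_len - 1L))
    add_read(ex$chrom, p, ex$strand, templ, "", paste0(read_len, "M"))
  }
  # intergenic: sample positions until the window clears every feature
  feat_gr <- GenomicRanges::GRanges(layout$chrom,
                                    IRanges::IRanges(layout$start, layout$end))
  for (j in seq_len(n_inter)) {
    repeat {
      chrom <- names(genome)[sample.int(length(genome), 1L)]
      p <- sample.int(BiocGenerics::width(genome[chrom]) - read_len + 1L, 1L)
      w <- GenomicRanges::GRanges(chrom, IRanges::IRanges(p, p + read_len - 1L))
      if (length(GenomicRanges::findOverlaps(w, feat_gr)) == 0L) break
    }
    templ <- as.character(Biostrings::subseq(genome[[chrom]], p,
                                             p + read_len - 1L))
    add_read(chrom, p, sample(c("+", "-"), 1L), templ, "",
             paste0(read_len, "M"))
  }

  # serialize: SAM -> sorted, indexed BAM; FASTQ in read orientation
  sam_path <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(genome), "\tLN:",
                     BiocGenerics::width(genome)))
  body <- vapply(recs, function(r) {
    paste(r$qname, r$flag, r$chrom, r$pos, 60L, r$cigar, "*", 0L, 0L,
          r$stored, strrep("I", nchar(r$stored)), sep = "\t")
  }, character(1))
  writeLines(c(header, body), sam_path)
  bam_path <- Rsamtools::asBam(sam_path, file.path(dir, "reads"),
                               overwrite = TRUE, indexDestination = TRUE)

  fastq_path <- file.path(dir, "reads.fastq")
  fq <- unlist(lapply(recs, function(r) {
    c(paste0("@", r$qname), r$read, "+", strrep("I", nchar(r$read)))
  }))
  writeLines(fq, fastq_path)

  manifest <- list(
    seed = seed, read_len = read_len,
    regions = do.call(rbind, region_rows),
    tails = region_tails,
    gene_counts = unlist(gene_counts),
    noise = list(sense = n_sense, intergenic = n_inter),
    n_reads_total = rid,
    files = list(bam = bam_path, fastq = fastq_path, sam = sam_path)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(bam = bam_path, fastq = fastq_path, sam = sam_path,
       manifest_path = manifest_path, manifest = manifest)
}

#' Generate a complete fixture tree
#'
#' Convenience wrapper: genome + annotation + reads in one directory.
#'
#' @param dir Output directory.
#' @param seed Integer seed controlling every random choice.
#' @param n_genes,exons_per_gene,n_clusters,reads_per_cluster,span,read_len,tail_spec,noise_frac
#'   Passed through to the generators.
#' @return List with paths (`genome`, `gtf`, `bam`, `fastq`,
#'   `manifest_path`), the `genome` object, `layout` and `manifest`.
#' @export
make_fixture <- function(dir = tempfile("fix"), seed = 1L, n_genes = 10L,
                         exons_per_gene = 1L, n_clusters = 5L,
                         reads_per_cluster = 12L, span = 60L,
                         read_len = 22L,
                         tail_spec = stats::setNames(1, ""),
                         noise_frac = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_len <- max(2000L, n_genes * (exons_per_gene * 400L + 200L))
  genome <- make_genome(1L, genome_len, seed = seed)
  layout <- make_annotation(genome, n_genes = n_genes,
                            exons_per_gene = exons_per_gene)
  fa <- write_genome_fasta(genome, file.path(dir, "genome.fa"))
  gtf <- write_gtf(layout, file.path(dir, "annotation.gtf"))
  clusters <- default_clusters(layout, n_clusters,
                               n_reads = reads_per_cluster, span = span)
  reads <- make_reads(genome, layout, clusters, read_len = read_len,
                      tail_spec = tail_spec, noise_frac = noise_frac,
                      seed = seed + 1L, dir = dir)
  c(list(genome_fa = fa, gtf = gtf, genome = genome, layout = layout),
    reads)
}
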