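#' Call 3' nontemplated tails by maximal templated-prefix matching
#'
#' For each read sequence, finds the maximal length `L >= min_prefix` such
#' that the first `L` nucleotides of the read match the reference genome
#' exactly (zero mismatches; `N` matches nothing) at some location on
#' either strand (minus-strand locations match via reverse complement).
#' One call is returned per genomic location achieving that maximal `L`;
#' the remainder of the read, `read[L+1..]`, is the nontemplated tail
#' (empty tail = fully templated, "untailed"). Reads whose first
#' `min_prefix` bases occur nowhere in the genome produce no calls.
#'
#' Prefix matchability is monotone in `L` (every prefix of a match is a
#' match), so the search walks down from the full read length and stops at
#' the first matching length; maximality of every reported location is
#' implied.
#'
#' @param seqs Named character vector of read sequences in original read
#'   orientation (names are read ids), A/C/G/T/N alphabet.
#' @param genome A `DNAStringSet`, or path to a FASTA file.
#' @param min_prefix Minimum templated-prefix length in nt (default 18,
#'   the conventional lower bound of mature small-RNA lengths).
#' @return A `data.frame` of class `tail_calls`, one row per (read,
#'   location): `read_id`, `templated_len`, `tail_seq` (DNA alphabet, read
#'   orientation), `chrom`, `start`, `end` (1-based closed interval of the
#'   matched genomic prefix), `strand`, `n_loc` (locations for that read).
#' @export
call_tails <- function(seqs, genome, min_prefix = 18L) {
  stopifnot(min_prefix >= 1L)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("read sequences must contain only A/C/G/T/N")
  }

  empty <- data.frame(read_id = character(0), templated_len = integer(0),
                      tail_seq = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_loc = integer(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(structure(empty, class = c("tail_calls", "data.frame")))

  # search once per unique sequence, then fan results back out to reads
  uniq <- unique(unname(seqs))
  per_seq <- lapply(uniq, function(s) {
    locate_max_prefix(s, genome, min_prefix)
  })
  names(per_seq) <- uniq

  rows <- lapply(seq_along(seqs), function(i) {
    loc <- per_seq[[seqs[[i]]]]
    if (is.null(loc) || nrow(loc) == 0L) return(NULL)
    L <- loc$templated_len[1L]
    data.frame(read_id = names(seqs)[i], templated_len = L,
               tail_seq = substr(seqs[[i]], L + 1L, nchar(seqs[[i]])),
               chrom = loc$chrom, start = loc$start, end = loc$end,
               strand = loc$strand, n_loc = nrow(loc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  structure(out, class = c("tail_calls", "data.frame"))
}

# All genomic locations of the longest exactly-matching prefix of one read.
locate_max_prefix <- function(seq, genome, min_prefix) {
  n <- nchar(seq)
  if (n < min_prefix) return(NULL)
  for (L in seq(n, min_prefix)) {
    prefix <- Biostrings::DNAString(substr(seq, 1L, L))
    fwd <- Biostrings::vmatchPattern(prefix, genome, fixed = TRUE)
    rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(prefix),
                                     genome, fixed = TRUE)
    hits <- rbind(matches_to_df(fwd, "+", L), matches_to_df(rev, "-", L))
    if (nrow(hits) > 0L) return(hits)
  }
  NULL
}

matches_to_df <- function(mindex, strand, L) {
  starts <- lapply(mindex, BiocGenerics::start)
  n <- lengths(starts)
  st <- unlist(starts, use.names = FALSE) %||% integer(0)
  data.frame(
    templated_len = rep(L, length(st)),
    chrom = rep(names(starts), n),
    start = st,
    end = st + L - 1L,
    strand = rep(strand, length(st)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve multi-mapping tail calls
#'
#' A read whose maximal templated prefix matches several genomic locations
#' equally well is a multimapper. `fractional` gives each of the k
#' equal-best locations weight 1/k (table counts may then be fractional);
#' `random` keeps one location drawn under the session RNG (set a seed for
#' reproducibility); `drop` discards reads with k > 1.
#'
#' @param calls `tail_calls` from [call_tails()].
#' @param policy One of `"fractional"`, `"random"`, `"drop"`.
#' @return `tail_calls` with a `weight` column.
#' @export
resolve_multimappers <- function(calls,
                                 policy = c("fractional", "random", "drop")) {
  policy <- match.arg(policy)
  if (nrow(calls) == 0L) {
    calls$weight <- numeric(0)
    return(calls)
  }
  if (policy == "fractional") {
    calls$weight <- 1 / calls$n_loc
  } else if (policy == "drop") {
    calls <- calls[calls$n_loc == 1L, , drop = FALSE]
    calls$weight <- rep(1, nrow(calls))
  } else {
    keep <- unlist(lapply(split(seq_len(nrow(calls)), calls$read_id),
                          function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)),
                   use.names = FALSE)
    calls <- calls[sort(keep), , drop = FALSE]
    calls$weight <- rep(1, nrow(calls))
  }
  rownames(calls) <- NULL
  calls
}

#' Assign tail calls to small-RNA regions and tabulate tails
#'
#' Each call is assigned to every region its templated genomic interval
#' overlaps by at least one base on the same strand as the region record.
#' BED files produced by sirna mode record the read strand, so same-strand
#' assignment is read-strand agreement; for user BEDs annotated on the
#' genomic sense strand set `antisense_assign = TRUE` to flip the test.
#' Per region, tail counts accumulate by exact tail sequence, reported in
#' the RNA alphabet (T shown as U); the empty tail is the "untailed" class.
#'
#' @param calls `tail_calls` with weights from [resolve_multimappers()].
#' @param regions `GRanges` of target regions with a `name` column, e.g.
#'   from [read_bed6()].
#' @param antisense_assign Require opposite-strand instead of same-strand
#'   overlap.
#' @return A `data.frame` of class `tail_table` with columns `target`,
#'   `tail` (`""` for untailed) and `count`, plus attribute `unassigned`
#'   (total weight of calls overlapping no region).
#' @export
assign_to_regions <- function(calls, regions, antisense_assign = FALSE) {
  if (is.null(calls$weight)) calls$weight <- rep(1, nrow(calls))
  empty <- structure(
    data.frame(target = character(0), tail = character(0),
               count = numeric(0), stringsAsFactors = FALSE),
    class = c("tail_table", "data.frame"), unassigned = 0)
  if (nrow(calls) == 0L || length(regions) == 0L) {
    attr(empty, "unassigned") <- sum(calls$weight)
    return(empty)
  }
  call_gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$start, end = calls$end),
    strand = if (antisense_assign) flip_strand(calls$strand) else calls$strand)
  ov <- GenomicRanges::findOverlaps(call_gr, regions, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)

  unassigned <- sum(calls$weight[!seq_len(nrow(calls)) %in% qh])

  if (length(ov) == 0L) {
    attr(empty, "unassigned") <- unassigned
    return(empty)
  }
  tail_rna <- chartr("T", "U", calls$tail_seq[qh])
  tab <- stats::aggregate(
    list(count = calls$weight[qh]),
    by = list(target = S4Vectors::mcols(regions)$name[sh], tail = tail_rna),
    FUN = sum)
  tab <- tab[order(tab$target, tab$tail != "", tab$tail), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("tail_table", "data.frame"),
            unassigned = unassigned)
}

#' Summarize a tail table per target
#'
#' @param table `tail_table` from [assign_to_regions()].
#' @return `data.frame` with one row per target: `untailed`, `all_tails`
#'   (sum over the individual tail types) and `total` (their sum, the total
#'   reads assigned to that target).
#' @export
tail_table_totals <- function(table) {
  targets <- sort(unique(table$target))
  untailed <- vapply(targets, function(t)
    sum(table$count[table$target == t & table$tail == ""]), numeric(1))
  all_tails <- vapply(targets, function(t)
    sum(table$count[table$target == t & table$tail != ""]), numeric(1))
  data.frame(target = targets, untailed = unname(untailed),
             all_tails = unname(all_tails),
             total = unname(untailed + all_tails),
             stringsAsFactors = FALSE)
}

#' Write a tail table as long-format CSV
#'
#' Columns `target,tail,count`; tail values are the observed tail strings
#' in the RNA alphabet plus the reserved rows `untailed` and `all_tails`
#' (one of each per target). The sum of `untailed` and `all_tails` equals
#' the total reads assigned to the target.
#'
#' @param table `tail_table` from [assign_to_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tail_csv <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("target,tail,count", con)
  if (nrow(table) == 0L) return(invisible(path))
  fmt <- function(x) {
    vapply(x, function(v) {
      if (abs(v - round(v)) < 1e-9) sprintf("%d", as.integer(round(v)))
      else sub("0+$", "", sprintf("%.9f", v))
    }, character(1))
  }
  totals <- tail_table_totals(table)
  for (t in totals$target) {
    rows <- table[table$target == t & table$tail != "", , drop = FALSE]
    rows <- rows[order(rows$tail), , drop = FALSE]
    writeLines(c(
      paste(t, "untailed", fmt(totals$untailed[totals$target == t]), sep = ","),
      if (nrow(rows)) paste(rows$target, rows$tail, fmt(rows$count), sep = ","),
      paste(t, "all_tails", fmt(totals$all_tails[totals$target == t]), sep = ",")
    ), con)
  }
  invisible(path)
}

#' Re-read a tail CSV into a tail table
#'
#' Inverse of [write_tail_csv()]; the `all_tails` rows are consistency
#' checked against the individual tail rows and then dropped.
#'
#' @param path CSV path.
#' @return `tail_table`.
#' @export
read_tail_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  at <- df[df$tail == "all_tails", , drop = FALSE]
  body <- df[df$tail != "all_tails", , drop = FALSE]
  body$tail[body$tail == "untailed"] <- ""
  for (i in seq_len(nrow(at))) {
    got <- sum(body$count[body$target == at$target[i] & body$tail != ""])
    if (abs(got - at$count[i]) > 1e-6) {
      stop("inconsistent all_tails total for target ", at$target[i])
    }
  }
  body <- body[order(body$target, body$tail != "", body$tail), , drop = FALSE]
  rownames(body) <- NULL
  structure(body, class = c("tail_table", "data.frame"), unassigned = NA_real_)
}

#' Extract read sequences for tail mode
#'
#' Accepts a BAM (sequences taken in original read orientation from primary
#' mapped records) or a FASTQ file.
#'
#' @param path BAM or FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_sequences <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    aln <- load_alignments(path, min_len = 0L, max_len = Inf)
    stats::setNames(aln$reads$seq, aln$reads$read_id)
  } else {
    sq <- Biostrings::readDNAStringSet(path, format = "fastq")
    stats::setNames(as.character(sq), sub("\\s.*$", "", names(sq)))
  }
}
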