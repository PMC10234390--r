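# Shared small helpers: BED6 I/O and strand arithmetic.

flip_strand <- function(s) {
  s <- as.character(s)
  out <- s
  out[s == "+"] <- "-"
  out[s == "-"] <- "+"
  out
}

# BED6 writer: GRanges (1-based closed) -> 0-based half-open text.
write_bed6 <- function(gr, name, score, path) {
  if (length(gr) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = name,
    score = score,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  lines <- do.call(paste, c(df, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of stranded regions
#'
#' Parses a six-column BED (0-based half-open) into a `GRanges` (1-based
#' closed) with `name` and `score` metadata columns. Used both to re-load
#' sirna-mode output for tail mode and as the round-trip oracle in tests.
#'
#' @param path BED file path.
#' @return `GRanges` with `name` and `score` columns.
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = character(0),
                                                 score = numeric(0))
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 6L)) {
    stop("malformed BED line ", which(n < 6L)[1L], ": expected >= 6 columns")
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  strand <- m[, 6L]
  if (!all(strand %in% c("+", "-"))) {
    stop("malformed strand column in BED: values must be '+' or '-'")
  }
  GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = as.integer(m[, 2L]) + 1L,
                              end = as.integer(m[, 3L])),
    strand = strand,
    name = m[, 4L],
    score = as.numeric(m[, 5L])
  )
}
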