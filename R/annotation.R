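#' Parse a GTF/GFF annotation and keep one feature kind
#'
#' Reads a standard nine-column, tab-separated GTF or GFF3 file and returns
#' the records whose third column equals `feature_kind`, as a stranded
#' `GRanges` (1-based, closed intervals, the GTF convention). The attribute
#' dialect is auto-detected from the file extension (`.gtf` vs
#' `.gff`/`.gff3`) unless overridden with `dialect`.
#'
#' Records on unstranded lines (strand `.` or `?`) are excluded and counted
#' in a warning: the downstream region algebra is strand-resolved and has no
#' meaningful interpretation for them. Records whose attributes yield no
#' gene identifier are kept but flagged (`gene_id` is `NA`) with a warning.
#'
#' @param path Path to a GTF or GFF3 file. Comment lines start with `#`.
#' @param feature_kind Feature type string to select (third column), e.g.
#'   `"exon"` or `"three_prime_utr"`.
#' @param dialect One of `"auto"`, `"gtf"`, `"gff3"`. With `"auto"` the
#'   dialect is chosen by file extension; an unknown extension is an error
#'   suggesting an explicit dialect.
#' @param gene_key Attribute key(s) holding the gene identifier, tried in
#'   order. Defaults to `"gene_id"` for GTF and `c("Parent", "ID")` for GFF3.
#' @return A `GRanges` with metadata columns `feature_kind`, `gene_id` and
#'   `attributes` (the raw ninth column).
#' @export
parse_annotation <- function(path, feature_kind,
                             dialect = c("auto", "gtf", "gff3"),
                             gene_key = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      gtf = "gtf",
      gff = "gff3",
      gff3 = "gff3",
      stop("cannot detect annotation dialect from extension '.", ext,
           "'; pass dialect = \"gtf\" or \"gff3\" explicitly")
    )
  }
  if (is.null(gene_key)) {
    gene_key <- if (dialect == "gtf") "gene_id" else c("Parent", "ID")
  }

  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_feature_granges())
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol != 9L)) {
    bad <- lineno[which(ncol != 9L)[1L]]
    stop("malformed annotation line ", bad, ": expected 9 tab-separated ",
         "columns, found ", ncol[which(ncol != 9L)[1L]])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)

  sel <- m[, 3L] == feature_kind
  m <- m[sel, , drop = FALSE]
  lineno <- lineno[sel]
  if (nrow(m) == 0L) return(empty_feature_granges())

  stranded <- m[, 7L] %in% c("+", "-")
  n_unstranded <- sum(!stranded)
  if (n_unstranded > 0L) {
    warning(n_unstranded, " unstranded '", feature_kind,
            "' record(s) excluded")
    m <- m[stranded, , drop = FALSE]
    lineno <- lineno[stranded]
  }
  if (nrow(m) == 0L) return(empty_feature_granges())

  start <- as.integer(m[, 4L])
  end <- as.integer(m[, 5L])
  if (anyNA(start) || anyNA(end) || any(start > end) || any(start < 1L)) {
    bad <- lineno[which(is.na(start) | is.na(end) | start > end | start < 1L)[1L]]
    stop("malformed coordinates at annotation line ", bad)
  }

  gene_id <- extract_gene_id(m[, 9L], dialect, gene_key)
  n_flagged <- sum(is.na(gene_id))
  if (n_flagged > 0L) {
    warning(n_flagged, " record(s) with no extractable gene identifier ",
            "(tried key(s): ", paste(gene_key, collapse = ", "), ")")
  }

  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = m[, 7L],
    feature_kind = m[, 3L],
    gene_id = gene_id,
    attributes = m[, 9L]
  )
  gr
}

empty_feature_granges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_kind = character(0), gene_id = character(0),
    attributes = character(0))
  gr
}

# Pull the first matching attribute key out of the 9th column.
# GTF: key "value"; key2 "value2";   GFF3: key=value;key2=value2
extract_gene_id <- function(attrs, dialect, keys) {
  out <- rep(NA_character_, length(attrs))
  for (key in keys) {
    miss <- is.na(out)
    if (!any(miss)) break
    pat <- if (dialect == "gtf") {
      paste0("(^|;)\\s*", key, "\\s+\"([^\"]*)\"")
    } else {
      paste0("(^|;)\\s*", key, "=([^;]+)")
    }
    hit <- regmatches(attrs[miss], regexec(pat, attrs[miss]))
    val <- vapply(hit, function(h) if (length(h) >= 3L) h[[3L]] else NA_character_,
                  character(1))
    val[!is.na(val) & !nzchar(val)] <- NA_character_
    # GFF3 Parent values may be comma-joined or prefixed ("transcript:t1")
    if (dialect == "gff3") val <- sub("^[^:]+:", "", sub(",.*$", "", val))
    out[miss] <- val
  }
  out
}

#' Serialize features back to GTF text
#'
#' Inverse of [parse_annotation()] for round-trip checks and debugging;
#' coordinates are written 1-based inclusive as in the input.
#'
#' @param features `GRanges` from [parse_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
features_to_gtf <- function(features, path) {
  df <- as.data.frame(features)
  lines <- paste(df$seqnames, "sirtail", df$feature_kind, df$start, df$end,
                 ".", df$strand, ".", df$attributes, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Build the strand-resolved candidate region set
#'
#' Per strand, overlapping features are merged into maximal covered runs
#' (merging requires at least one shared base: bookended features stay
#' separate). Then every base covered on both strands is excised from both
#' strands' regions; an excision may split a region in two, and every
#' surviving fragment keeps the full gene-id set of the merged cluster it
#' came from. The result is the search space for antisense reads.
#'
#' @param features `GRanges` of features, e.g. from [parse_annotation()].
#' @return A `GRanges` of disjoint candidate regions (disjoint within and
#'   across strands) with a `gene_ids` `CharacterList` metadata column.
#' @export
build_candidate_regions <- function(features) {
  empty <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_ids <- IRanges::CharacterList()
    gr
  }
  if (length(features) == 0L) return(empty())
  stopifnot(all(as.character(BiocGenerics::strand(features)) %in% c("+", "-")))

  # the algebra runs on plain IRanges per chromosome: the GRanges set
  # methods carry seqinfo-validation overhead that dominates at this scale
  fchrom <- as.character(GenomicRanges::seqnames(features))
  fstrand <- as.character(BiocGenerics::strand(features))
  fstart <- BiocGenerics::start(features)
  fend <- BiocGenerics::end(features)
  fgene <- S4Vectors::mcols(features)$gene_id

  out <- list()
  for (chrom in unique(fchrom)) {
    on_chrom <- fchrom == chrom
    cov <- lapply(c("+", "-"), function(str) {
      i <- which(on_chrom & fstrand == str)
      list(idx = i,
           merged = IRanges::reduce(IRanges::IRanges(fstart[i], fend[i]),
                                    min.gapwidth = 0L))
    })
    names(cov) <- c("+", "-")
    both <- IRanges::intersect(cov[["+"]]$merged, cov[["-"]]$merged)

    for (str in c("+", "-")) {
      parents <- cov[[str]]$merged
      if (length(parents) == 0L) next
      # gene sets of each merged parent region
      fr <- IRanges::IRanges(fstart[cov[[str]]$idx], fend[cov[[str]]$idx])
      pov <- IRanges::findOverlaps(parents, fr)
      ids <- fgene[cov[[str]]$idx][S4Vectors::subjectHits(pov)]
      gsets <- split(ids, factor(S4Vectors::queryHits(pov),
                                 levels = seq_along(parents)))
      gsets <- lapply(gsets, function(g) sort(unique(g[!is.na(g)])))

      # subtract double-covered bases, then re-split survivors at parent
      # boundaries (a global setdiff would merge bookended survivors) so
      # every fragment inherits exactly its parent's gene set
      kept <- IRanges::setdiff(parents, both)
      if (length(kept) == 0L) next
      ov <- IRanges::findOverlaps(kept, parents)
      frag <- IRanges::pintersect(kept[S4Vectors::queryHits(ov)],
                                  parents[S4Vectors::subjectHits(ov)])
      out[[length(out) + 1L]] <- list(
        chrom = chrom, start = BiocGenerics::start(frag),
        end = BiocGenerics::end(frag), strand = str,
        genes = gsets[S4Vectors::subjectHits(ov)])
    }
  }
  if (length(out) == 0L) return(empty())
  gr <- GenomicRanges::GRanges(
    seqnames = rep(vapply(out, `[[`, character(1), "chrom"),
                   vapply(out, function(o) length(o$start), integer(1))),
    ranges = IRanges::IRanges(unlist(lapply(out, `[[`, "start")),
                              unlist(lapply(out, `[[`, "end"))),
    strand = rep(vapply(out, `[[`, character(1), "strand"),
                 vapply(out, function(o) length(o$start), integer(1))))
  S4Vectors::mcols(gr)$gene_ids <-
    IRanges::CharacterList(do.call(c, lapply(out, `[[`, "genes")))
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Write candidate regions as BED6
#'
#' Debug hand-off of the candidate region set: chrom, 0-based half-open
#' start/end, semicolon-joined gene ids, score 0, strand.
#'
#' @param regions `GRanges` from [build_candidate_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_bed <- function(regions, path) {
  write_bed6(regions,
             name = vapply(S4Vectors::mcols(regions)$gene_ids,
                           paste, character(1), collapse = ";"),
             score = rep(0L, length(regions)),
             path = path)
}
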