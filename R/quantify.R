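#' Count reads per siRNA region or per gene
#'
#' Region-level counting keeps each putative siRNA region as its own row;
#' gene-level counting sums, for every gene id, the supporting-read counts
#' of all regions attributed to it (a region merged across several genes
#' contributes its count to each of them). Gene level is the default
#' reporting unit downstream because validation counts are per target gene.
#'
#' @param regions siRNA `GRanges` with `read_count` and `gene_ids` (from
#'   [merge_into_sirna_regions()]) or with `name`/`score` (from
#'   [read_bed6()] on a sirna-mode BED, where the name encodes the genes).
#' @param aggregation `"gene"` or `"region"`.
#' @return A `data.frame` of class `count_table`: `id`, `raw_count`.
#' @export
count_per_gene <- function(regions, aggregation = c("gene", "region")) {
  aggregation <- match.arg(aggregation)
  mc <- S4Vectors::mcols(regions)
  if (!is.null(mc$read_count)) {
    counts <- as.numeric(mc$read_count)
    genes <- as.list(mc$gene_ids)
    names <- paste0(vapply(genes, paste, character(1), collapse = ";"),
                    ".sir", seq_along(regions))
  } else if (!is.null(mc$name)) {
    counts <- as.numeric(mc$score)
    names <- mc$name
    genes <- strsplit(sub("\\.sir[0-9]+$", "", names), ";", fixed = TRUE)
  } else {
    stop("regions carry neither read_count/gene_ids nor name/score columns")
  }

  if (aggregation == "region") {
    out <- data.frame(id = names, raw_count = counts, stringsAsFactors = FALSE)
  } else {
    long <- data.frame(id = unlist(genes),
                       raw_count = rep(counts, lengths(genes)),
                       stringsAsFactors = FALSE)
    if (nrow(long) == 0L) {
      out <- data.frame(id = character(0), raw_count = numeric(0),
                        stringsAsFactors = FALSE)
    } else {
      out <- stats::aggregate(raw_count ~ id, data = long, FUN = sum)
      out <- out[order(out$id), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("count_table", "data.frame"))
}

#' Normalize a count table to counts per million
#'
#' `cpm = raw_count / library_size * 1e6`. In `"sirna-only"` mode the
#' denominator is the sum of the siRNA counts themselves; in
#' `"exon-background"` mode the siRNA counts are combined with a separate
#' count of exon-mapped reads (`exon_reads`), i.e. the library is siRNA +
#' exonic background. An explicit `library_size` overrides both.
#'
#' @param table `count_table` from [count_per_gene()].
#' @param mode `"sirna-only"` or `"exon-background"`.
#' @param exon_reads Exon-mapped read total, required in
#'   `"exon-background"` mode.
#' @param library_size Optional explicit denominator (reads); must be > 0.
#' @return The table with `cpm` and `library_size` columns.
#' @export
cpm_normalize <- function(table, mode = c("sirna-only", "exon-background"),
                          exon_reads = NULL, library_size = NULL) {
  mode <- match.arg(mode)
  if (is.null(library_size)) {
    library_size <- sum(table$raw_count)
    if (mode == "exon-background") {
      if (is.null(exon_reads)) {
        stop("exon-background normalization needs exon_reads")
      }
      library_size <- library_size + exon_reads
    }
  }
  if (length(library_size) != 1L || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  table$cpm <- table$raw_count / library_size * 1e6
  table$library_size <- library_size
  table
}

#' Filter a count table by a CPM threshold
#'
#' Retains rows with `cpm >= threshold` (inclusive, matching the
#' conventional ">= 25 reads per million" abundance filter); preserves row
#' order. Idempotent and monotone in the threshold.
#'
#' @param table `count_table` with a `cpm` column.
#' @param threshold CPM cutoff (default 25).
#' @return The filtered table.
#' @export
filter_by_cpm <- function(table, threshold = 25) {
  if (is.null(table$cpm)) stop("cpm column missing; run cpm_normalize() first")
  out <- table[table$cpm >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a count table as TSV
#'
#' @param table `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
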