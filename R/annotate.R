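#' Read a local gene annotation (GFF3 or BED)
#'
#' GFF3 files are imported with `rtracklayer` and filtered to `gene`
#' features (falling back to all features if none are typed `gene`); BED
#' files (0-based half-open) are converted to 1-based inclusive coordinates
#' by the importer. Gene names are taken from `Name`, `ID`, `gene_id` or the
#' BED name column, in that order of preference.
#'
#' @param path Annotation file; format inferred from the extension
#'   (`.gff`/`.gff3` or `.bed`) unless given.
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @return A `GRanges` with a `gene` metadata column.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(mc) && any(mc$type == "gene")) {
      gr <- gr[mc$type == "gene"]
      mc <- S4Vectors::mcols(gr)
    }
  }
  gene <- rep(NA_character_, length(gr))
  for (field in c("Name", "ID", "gene_id", "name")) {
    if (field %in% names(mc)) {
      val <- as.character(mc[[field]])
      gene[is.na(gene) & !is.na(val)] <- val[is.na(gene) & !is.na(val)]
    }
  }
  gene[is.na(gene)] <- paste0("feature_", which(is.na(gene)))
  S4Vectors::mcols(gr)$gene <- gene
  gr
}

#' Annotate association hits with nearby genes
#'
#' For each hit, reports genes whose (1-based inclusive) interval overlaps
#' `[pos - window, pos + window]`. Distance is 0 when the SNP lies within
#' the gene, otherwise the bp gap to the nearest gene edge; genes are sorted
#' by distance. Hits on chromosomes absent from the annotation get an empty
#' gene list with a warning.
#'
#' @param hits `data.frame` with at least `chr` and `pos` (e.g. significant
#'   rows of [lmm_gwas()] output).
#' @param genes `GRanges` from [read_gene_annotation()] (or any `GRanges`
#'   with a `gene` metadata column).
#' @param window Flanking window in bp (default 200000, i.e. 200 kb).
#' @return `data.frame` with one row per (hit, gene) pair: `chr`, `pos`,
#'   `gene`, `gene_start`, `gene_end`, `distance`. Hits without genes in
#'   range are retained with `NA` gene fields.
#' @export
annotate_hits <- function(hits, genes, window = 200000L) {
  stopifnot(all(c("chr", "pos") %in% names(hits)))
  hit_chr <- as.character(hits$chr)
  ann_chr <- as.character(GenomicRanges::seqnames(genes))
  if (!any(hit_chr %in% ann_chr)) {
    warning("no hit chromosome found in the annotation (name mismatch?)",
            call. = FALSE)
  }
  q <- GenomicRanges::GRanges(
    hit_chr,
    IRanges::IRanges(start = pmax(1L, hits$pos - window),
                     end = hits$pos + window))
  # the explicit mismatch warning above replaces GRanges' seqlevel warning
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, genes))
  res <- lapply(seq_len(nrow(hits)), function(i) {
    j <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    if (!length(j)) {
      return(data.frame(chr = hit_chr[i], pos = hits$pos[i],
                        gene = NA_character_, gene_start = NA_integer_,
                        gene_end = NA_integer_, distance = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    gs <- GenomicRanges::start(genes)[j]
    ge <- GenomicRanges::end(genes)[j]
    p <- hits$pos[i]
    dist <- ifelse(p >= gs & p <= ge, 0L,
                   ifelse(p < gs, gs - p, p - ge))
    o <- order(dist)
    data.frame(chr = hit_chr[i], pos = p,
               gene = S4Vectors::mcols(genes)$gene[j][o],
               gene_start = gs[o], gene_end = ge[o], distance = dist[o],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
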