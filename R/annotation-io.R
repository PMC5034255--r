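## GFF3/GTF input goes through rtracklayer; a cheap line pre-scan supplies
## parse errors with line numbers, which rtracklayer does not report.

.prescanAnnotationFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    if (nf != 9L)
      stop(sprintf("malformed annotation line %d in %s: expected 9 tab-separated fields, found %d",
                   i, path, nf), call. = FALSE)
  }
  invisible(length(lines))
}

#' Read a gene annotation (GFF3 or GTF) into GeneModel objects
#'
#' Parses a gene/transcript/exon annotation and assembles one
#' [GeneModel-class] per gene. GFF3 input must carry a
#' gene -> mRNA -> exon/CDS hierarchy via `ID`/`Parent` attributes; GTF
#' input (assembler dialect) groups exon rows by `transcript_id` and
#' `gene_id` attributes, with gene spans taken as the union of each gene's
#' transcripts. On-disk coordinates (1-based inclusive) are converted to
#' the package-internal 0-based half-open convention.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return list of [GeneModel-class], ordered by chromosome then start.
#'   GTF-derived transcripts are marked `source = "predicted"`.
#' @export
readAnnotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  .prescanAnnotationFile(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  if (length(gr) == 0L) return(list())
  if (dialect == "gff3") .assembleGff3(gr) else .assembleGtf(gr)
}

.grFields <- function(gr) {
  list(chrom  = as.character(GenomicRanges::seqnames(gr)),
       start0 = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
       end0   = BiocGenerics::end(gr),
       strand = as.character(BiocGenerics::strand(gr)),
       type   = as.character(gr$type))
}

.assembleGff3 <- function(gr) {
  f <- .grFields(gr)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))

  gi <- which(f$type == "gene")
  mi <- which(f$type %in% c("mRNA", "transcript"))
  geneOf <- setNames(parents[mi], ids[mi])

  exn <- which(f$type == "exon")
  cdsn <- which(f$type == "CDS")
  orphan <- setdiff(unique(parents[c(exn, cdsn)]), ids[mi])
  if (length(orphan) && any(!is.na(orphan)))
    stop("orphan exon/CDS feature(s) with unknown parent transcript: ",
         paste(stats::na.omit(orphan), collapse = ", "))

  genes <- list()
  geneRow <- setNames(gi, ids[gi])
  for (mId in ids[mi]) {
    gId <- geneOf[[mId]]
    if (is.na(gId) || !gId %in% names(geneRow))
      stop("transcript ", mId, " has no parent gene feature")
    ei <- exn[parents[exn] == mId]
    if (length(ei) == 0L) stop("transcript ", mId, " has no exon features")
    exm <- cbind(start = f$start0[ei], end = f$end0[ei])
    ci <- cdsn[parents[cdsn] == mId]
    cdsSpan <- if (length(ci)) c(min(f$start0[ci]), max(f$end0[ci])) else integer(0)
    gRow <- geneRow[[gId]]
    if (min(exm[, 1L]) < f$start0[gRow] || max(exm[, 2L]) > f$end0[gRow])
      stop("structural error in gene ", gId,
           ": exon of transcript ", mId, " lies outside the gene span")
    tx <- transcript(mId, gId, f$chrom[gRow], f$strand[gRow], exm,
                     cds = cdsSpan, source = "annotated")
    genes[[gId]] <- c(genes[[gId]], list(tx))
  }
  out <- lapply(names(genes), function(gId) {
    gRow <- geneRow[[gId]]
    geneModel(gId, f$chrom[gRow], f$strand[gRow],
              f$start0[gRow], f$end0[gRow], genes[[gId]])
  })
  .sortGenes(out)
}

.assembleGtf <- function(gr) {
  f <- .grFields(gr)
  keep <- which(f$type == "exon")
  if (length(keep) == 0L) return(list())
  txIds <- as.character(gr$transcript_id)[keep]
  gIds <- as.character(gr$gene_id)[keep]
  if (any(is.na(txIds)) || any(is.na(gIds)))
    stop("GTF exon row missing transcript_id or gene_id attribute")
  out <- list()
  for (gId in unique(gIds)) {
    rows <- keep[gIds == gId]
    gchrom <- f$chrom[rows[1L]]
    gstrand <- f$strand[rows[1L]]
    txs <- lapply(unique(txIds[gIds == gId]), function(tId) {
      ei <- rows[txIds[gIds == gId] == tId]
      transcript(tId, gId, gchrom, gstrand,
                 cbind(f$start0[ei], f$end0[ei]), source = "predicted")
    })
    gstart <- min(vapply(txs, function(t) min(t@exons[, 1L]), integer(1)))
    gend <- max(vapply(txs, function(t) max(t@exons[, 2L]), integer(1)))
    out[[gId]] <- geneModel(gId, gchrom, gstrand, gstart, gend, txs)
  }
  .sortGenes(unname(out))
}

.sortGenes <- function(genes) {
  if (length(genes) < 2L) return(genes)
  ord <- order(vapply(genes, function(g) g@chrom, character(1)),
               vapply(genes, function(g) g@start, integer(1)))
  genes[ord]
}

#' Write GeneModels as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with 1-based inclusive coordinates.
#' `readAnnotation(writeAnnotation(x), "gff3")` reproduces `x` (up to the
#' `source` slot, which the format does not carry).
#'
#' @param genes list of [GeneModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(genes, path) {
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  row <- function(chrom, type, s0, e0, strand, attrs)
    paste(chrom, "consplice", type, s0 + 1L, e0, ".", strand, ".", attrs, sep = "\t")
  for (g in genes) {
    writeLines(row(g@chrom, "gene", g@start, g@end, g@strand,
                   sprintf("ID=%s", g@id)), con)
    for (tx in g@transcripts) {
      writeLines(row(g@chrom, "mRNA", min(tx@exons[, 1L]), max(tx@exons[, 2L]),
                     g@strand, sprintf("ID=%s;Parent=%s", tx@id, g@id)), con)
      for (i in seq_len(nrow(tx@exons)))
        writeLines(row(g@chrom, "exon", tx@exons[i, 1L], tx@exons[i, 2L],
                       g@strand, sprintf("Parent=%s", tx@id)), con)
      if (length(tx@cds)) {
        ## CDS rows clipped to exons so the file stays structurally valid
        for (i in seq_len(nrow(tx@exons))) {
          cs <- max(tx@exons[i, 1L], tx@cds[1L])
          ce <- min(tx@exons[i, 2L], tx@cds[2L])
          if (cs < ce)
            writeLines(row(g@chrom, "CDS", cs, ce, g@strand,
                           sprintf("Parent=%s", tx@id)), con)
        }
      }
    }
  }
  invisible(path)
}
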