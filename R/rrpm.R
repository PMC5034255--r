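## Region-restricted transcript discovery support: the genome is split at
## annotated gene boundaries into one fragment per gene, per-gene assembly
## happens externally in fragment coordinates, and results are projected
## back. Restricting reads and assembly to a single gene's span prevents
## the transcript fusion that overlapping UTRs cause in gene-dense genomes.

#' Split a genome into per-gene fragments
#'
#' Produces exactly one fragment per gene, covering the annotated gene
#' span, with sequence in genome orientation (never reverse-complemented).
#'
#' @param genes list of [GeneModel-class].
#' @param genome named `DNAStringSet` keyed by chromosome.
#' @return list with `fragments` (list keyed by gene id; each has
#'   `gene_id`, `chrom`, `offset`, `length`, `strand`, `sequence`) and
#'   `offsets` (the same as a data.frame, the persistable offset map).
#' @export
fragmentGenome <- function(genes, genome) {
  frags <- lapply(genes, function(g) {
    if (!g@chrom %in% names(genome))
      stop("chromosome ", g@chrom, " absent from genome sequence")
    chromLen <- length(genome[[g@chrom]])
    if (g@start < 0L || g@end > chromLen)
      stop("gene ", g@id, " span [", g@start, ",", g@end,
           ") exceeds chromosome ", g@chrom, " bounds [0,", chromLen, ")")
    list(gene_id = g@id, chrom = g@chrom, offset = g@start,
         length = g@end - g@start, strand = g@strand,
         sequence = as.character(Biostrings::subseq(genome[[g@chrom]],
                                                    start = g@start + 1L,
                                                    end = g@end)))
  })
  names(frags) <- vapply(frags, `[[`, character(1), "gene_id")
  offsets <- data.frame(
    gene_id = names(frags),
    chrom = vapply(frags, `[[`, character(1), "chrom"),
    offset = vapply(frags, `[[`, integer(1), "offset"),
    length = vapply(frags, `[[`, integer(1), "length"),
    strand = vapply(frags, `[[`, character(1), "strand"),
    row.names = NULL)
  list(fragments = frags, offsets = offsets)
}

#' Write per-gene fragments as FASTA plus a TSV offset map
#'
#' @param frag result of [fragmentGenome()].
#' @param fastaPath,offsetsPath output files (FASTA headers are gene ids).
#' @return invisibly, the two paths.
#' @export
writeFragments <- function(frag, fastaPath, offsetsPath) {
  seqs <- Biostrings::DNAStringSet(vapply(frag$fragments, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- names(frag$fragments)
  Biostrings::writeXStringSet(seqs, fastaPath)
  write.table(frag$offsets, offsetsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fastaPath, offsetsPath))
}

#' Project a fragment-space transcript back onto the genome
#'
#' Shifts every coordinate by the fragment offset and restores the
#' chromosome name; strand is unchanged because fragments keep genome
#' orientation.
#'
#' @param tx [Transcript-class] in fragment coordinates (chrom is the
#'   fragment/gene id or arbitrary).
#' @param fragment one fragment entry from [fragmentGenome()].
#' @return the transcript in genome coordinates.
#' @export
projectToGenome <- function(tx, fragment) {
  if (min(tx@exons[, 1L]) < 0L || max(tx@exons[, 2L]) > fragment$length)
    stop("projection error: transcript ", tx@id,
         " exceeds fragment ", fragment$gene_id,
         " length ", fragment$length, " (possible read/assembly leak)")
  tx@exons <- tx@exons + as.integer(fragment$offset)
  if (length(tx@cds)) tx@cds <- tx@cds + as.integer(fragment$offset)
  tx@chrom <- fragment$chrom
  tx@geneId <- fragment$gene_id
  validObject(tx)
  tx
}

#' Read-containment predicate for fragment alignments
#'
#' The region-restriction contract requires reads to align entirely within
#' a gene fragment; this predicate validates externally produced alignment
#' records (SAM semantics) against that rule.
#'
#' @param pos 0-based leftmost alignment position on the fragment.
#' @param cigar CIGAR string of the alignment.
#' @param fragmentLength fragment length in nt.
#' @return `TRUE` iff the reference footprint lies within
#'   `[0, fragmentLength)`.
#' @export
alignmentWithinFragment <- function(pos, cigar, fragmentLength) {
  ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1L]]
  if (ops[1L] == -1L) stop("malformed CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1L]])
  chars <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  refLen <- sum(lens[chars %in% c("M", "D", "N", "=", "X")])
  pos >= 0L && (pos + refLen) <= fragmentLength
}

#' Filter predicted transcripts of a gene
#'
#' Applies the three noise filters in order, reporting the first failure
#' per transcript: (1) strand — a predicted transcript must lie on the
#' gene's strand; (2) support — it must have nonzero estimated abundance
#' in some sample and every splice junction must be supported by reads;
#' (3) ORF — its longest ORF must be at least `minOrfNt` nucleotides
#' (start through stop codon inclusive).
#'
#' @param gene the [GeneModel-class] (its annotated span and strand).
#' @param candidates list of candidate [Transcript-class] objects
#'   (fragment-projected assembler output; may include the annotated
#'   transcript).
#' @param support list with `expressed` (named logical, by transcript id)
#'   and `junctions` (data.frame `chrom`, `start`, `end`, `count` with
#'   0-based half-open intron coordinates). Every junction of every
#'   candidate must be present; a missing junction is an error, not a
#'   silent pass.
#' @param genome named `DNAStringSet`, for the ORF rule.
#' @param minOrfNt minimum ORF length (default 40).
#' @return list with `gene` (a [GeneModel-class] holding the kept
#'   transcripts, or `NULL` when none survive), `reasons` (named character,
#'   `"kept"`, `"strand"`, `"support"` or `"orf"` per candidate) and
#'   `flag` (`"ok"` or `"not_expressed_or_unsupported"`).
#' @export
filterTranscripts <- function(gene, candidates, support, genome, minOrfNt = 40L) {
  jKey <- function(chrom, s, e) paste(chrom, s, e, sep = ":")
  jcounts <- setNames(support$junctions$count,
                      jKey(support$junctions$chrom, support$junctions$start,
                           support$junctions$end))
  reasons <- character(0)
  kept <- list()
  for (tx in candidates) {
    if (tx@strand != gene@strand) {
      reasons[tx@id] <- "strand"
      next
    }
    expressed <- isTRUE(support$expressed[[tx@id]])
    jn <- introns(tx)
    jsupp <- TRUE
    if (nrow(jn) > 0L) {
      keys <- jKey(tx@chrom, jn[, 1L], jn[, 2L])
      missing <- setdiff(keys, names(jcounts))
      if (length(missing))
        stop("missing-support error: junction(s) of transcript ", tx@id,
             " absent from support table: ", paste(missing, collapse = ", "))
      jsupp <- all(jcounts[keys] > 0L)
    }
    if (!expressed || !jsupp) {
      reasons[tx@id] <- "support"
      next
    }
    orf <- longestOrf(splicedSeq(tx, genome))
    if (is.null(orf) || orf$length_nt < minOrfNt) {
      reasons[tx@id] <- "orf"
      next
    }
    reasons[tx@id] <- "kept"
    kept <- c(kept, list(tx))
  }
  if (length(kept) == 0L)
    return(list(gene = NULL, reasons = reasons,
                flag = "not_expressed_or_unsupported"))
  g <- geneModel(gene@id, gene@chrom, gene@strand, gene@start, gene@end, kept)
  list(gene = g, reasons = reasons, flag = "ok")
}
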