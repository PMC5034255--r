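.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of a spliced sequence
#'
#' Scans all three forward frames of the sense-strand transcript sequence
#' for complete ATG..stop ORFs and returns the longest one, measured from
#' the A of the start codon through the stop codon inclusive. Ties are
#' broken by the 5'-most start. Codons containing `N` match neither a
#' start nor a stop.
#'
#' @param seq nucleotide string (or `DNAString`) over `A,C,G,T,N`,
#'   sense strand of the transcript.
#' @return `NULL` if no complete ORF exists, else a list with
#'   `tx_offset` (0-based start within the spliced sequence),
#'   `length_nt` (ATG through stop, divisible by 3) and `protein`
#'   (amino acids, stop excluded, untranslatable codons as `X`).
#' @export
longestOrf <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 6L) return(NULL)
  best <- NULL
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    pos <- f + 3L * (seq_len(ncod) - 1L) + 1L   # 1-based codon starts
    codons <- substring(s, pos, pos + 2L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% .STOP_CODONS)
    if (!length(starts) || !length(stops)) next
    ## first stop strictly after each start, in this frame
    j <- stops[findInterval(starts, stops) + 1L]
    ok <- !is.na(j)
    for (k in which(ok)) {
      len <- (j[k] - starts[k] + 1L) * 3L
      off <- f + (starts[k] - 1L) * 3L
      if (is.null(best) || len > best$length_nt ||
          (len == best$length_nt && off < best$tx_offset)) {
        best <- list(tx_offset = off, length_nt = len,
                     codons = codons[starts[k]:(j[k] - 1L)])
      }
    }
  }
  if (is.null(best)) return(NULL)
  aa <- Biostrings::GENETIC_CODE[best$codons]
  aa[is.na(aa)] <- "X"
  list(tx_offset = best$tx_offset, length_nt = best$length_nt,
       protein = paste(aa, collapse = ""))
}

#' Spliced sequence of a transcript
#'
#' Concatenates the exonic genome sequence in transcript orientation
#' (reverse-complemented for minus-strand transcripts).
#'
#' @param tx a [Transcript-class].
#' @param genome a named `DNAStringSet` (or coercible) keyed by chromosome.
#' @return character string, 5' to 3' of the mature transcript.
#' @export
splicedSeq <- function(tx, genome) {
  if (!tx@chrom %in% names(genome))
    stop("chromosome ", tx@chrom, " absent from genome sequence")
  chromSeq <- genome[[tx@chrom]]
  pieces <- vapply(seq_len(nrow(tx@exons)), function(i)
    as.character(Biostrings::subseq(chromSeq,
                                    start = tx@exons[i, 1L] + 1L,
                                    end = tx@exons[i, 2L])),
    character(1))
  s <- paste(pieces, collapse = "")
  if (tx@strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

## Map a transcript-space half-open interval [from, to) (transcript
## orientation) to its genomic exonic intervals, sorted by genomic start.
.txIntervalToGenomic <- function(tx, from, to) {
  ex <- tx@exons
  if (tx@strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  lens <- ex[, 2L] - ex[, 1L]
  cum <- cumsum(c(0L, lens))
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(nrow(ex))) {
    lo <- max(from, cum[i]); hi <- min(to, cum[i + 1L])
    if (lo >= hi) next
    if (tx@strand == "+") {
      g <- c(ex[i, 1L] + (lo - cum[i]), ex[i, 1L] + (hi - cum[i]))
    } else {
      g <- c(ex[i, 2L] - (hi - cum[i]), ex[i, 2L] - (lo - cum[i]))
    }
    out <- rbind(out, g)
  }
  out <- out[order(out[, 1L]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Compute the CDS and UTRs of a transcript
#'
#' Finds the longest ORF of the spliced sequence (reverse-strand
#' transcripts are reverse-complemented before the scan), projects it back
#' to genomic coordinates, and splits the remaining exonic sequence into
#' 5' and 3' UTRs by transcript orientation. The CDS stays unset when the
#' longest ORF is shorter than `minOrfNt` (start through stop inclusive).
#'
#' @param tx a [Transcript-class].
#' @param genome named `DNAStringSet` keyed by chromosome.
#' @param minOrfNt minimum ORF length in nucleotides (default 40).
#' @return list with `tx` (the transcript, `cds` slot set when an ORF of
#'   sufficient length exists), `utr5`/`utr3` (matrices of genomic exonic
#'   intervals, zero rows when absent or no CDS), and `orf` (the
#'   [longestOrf()] result or `NULL`).
#' @export
computeCdsUtrs <- function(tx, genome, minOrfNt = 40L) {
  emptyIv <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  s <- splicedSeq(tx, genome)
  orf <- longestOrf(s)
  if (is.null(orf) || orf$length_nt < minOrfNt) {
    tx@cds <- integer(0)
    return(list(tx = tx, utr5 = emptyIv, utr3 = emptyIv, orf = orf))
  }
  total <- splicedLength(tx)
  a <- orf$tx_offset; b <- orf$tx_offset + orf$length_nt
  cdsIv <- .txIntervalToGenomic(tx, a, b)
  tx@cds <- c(min(cdsIv[, 1L]), max(cdsIv[, 2L]))
  utr5 <- if (a > 0L) .txIntervalToGenomic(tx, 0L, a) else emptyIv
  utr3 <- if (b < total) .txIntervalToGenomic(tx, b, total) else emptyIv
  list(tx = tx, utr5 = utr5, utr3 = utr3, orf = orf)
}
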