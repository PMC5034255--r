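#' @import methods
#' @importFrom stats rlnorm runif setNames p.adjust phyper
#' @importFrom utils read.delim write.table head tail
NULL

## Internal coordinate convention, used everywhere in this package:
## 0-based, half-open [start, end). File I/O (GFF3/GTF, 1-based inclusive)
## converts at the boundary and nowhere else.

.validExonMatrix <- function(exons) {
  if (!is.matrix(exons) || ncol(exons) != 2L)
    return("exons must be a two-column matrix (start, end)")
  if (nrow(exons) == 0L)
    return("a transcript needs at least one exon")
  if (any(exons[, 1L] >= exons[, 2L]))
    return("every exon must satisfy start < end")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1L], strictly = TRUE))
      return("exons must be sorted by start")
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
      return("exons of one transcript must be pairwise non-overlapping")
  }
  TRUE
}

#' Transcript: one isoform of a gene
#'
#' Holds the exon chain of a single transcript together with an optional
#' genomic CDS span. All coordinates are 0-based half-open; exons are stored
#' as a two-column integer matrix sorted by start, pairwise non-overlapping.
#'
#' @slot id transcript identifier.
#' @slot geneId identifier of the parent gene.
#' @slot chrom sequence (chromosome/scaffold) name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons integer matrix with columns `start`, `end`.
#' @slot cds `integer(0)` when no coding region is set, otherwise
#'   `c(start, end)` of the genomic CDS span (0-based half-open).
#' @slot source `"annotated"` (reference annotation) or `"predicted"`
#'   (assembler output).
#' @exportClass Transcript
setClass("Transcript",
  representation(
    id     = "character",
    geneId = "character",
    chrom  = "character",
    strand = "character",
    exons  = "matrix",
    cds    = "integer",
    source = "character"
  ),
  prototype(cds = integer(0), source = "annotated")
)

setValidity("Transcript", function(object) {
  msgs <- character(0)
  ok <- .validExonMatrix(object@exons)
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(object@cds) > 0L) {
    if (length(object@cds) != 2L || object@cds[1L] >= object@cds[2L])
      msgs <- c(msgs, "cds must be integer(0) or c(start, end) with start < end")
    else if (isTRUE(ok)) {
      ex <- object@exons
      if (object@cds[1L] < min(ex[, 1L]) || object@cds[2L] > max(ex[, 2L]))
        msgs <- c(msgs, "cds span must lie within the exon union")
    }
  }
  if (!object@source %in% c("annotated", "predicted"))
    msgs <- c(msgs, "source must be 'annotated' or 'predicted'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Transcript
#'
#' @param id,geneId,chrom,strand,source see [Transcript-class].
#' @param exons two-column matrix (or something coercible) of 0-based
#'   half-open exon intervals; rows are sorted by start internally.
#' @param cds optional `c(start, end)` genomic CDS span.
#' @return a validated [Transcript-class] object.
#' @export
transcript <- function(id, geneId, chrom, strand, exons,
                       cds = integer(0), source = "annotated") {
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  new("Transcript", id = as.character(id), geneId = as.character(geneId),
      chrom = as.character(chrom), strand = strand, exons = exons,
      cds = as.integer(cds), source = source)
}

#' GeneModel: a gene with its transcript set
#'
#' @slot id gene identifier.
#' @slot chrom,strand location of the gene.
#' @slot start,end annotated gene boundary, 0-based half-open.
#' @slot transcripts list of [Transcript-class] objects, all lying within
#'   `[start, end)`.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    id          = "character",
    chrom       = "character",
    strand      = "character",
    start       = "integer",
    end         = "integer",
    transcripts = "list"
  )
)

setValidity("GeneModel", function(object) {
  msgs <- character(0)
  if (object@start >= object@end)
    msgs <- c(msgs, "gene start must be < end")
  if (length(object@transcripts) < 1L)
    msgs <- c(msgs, "a GeneModel needs at least one transcript")
  for (tx in object@transcripts) {
    if (!is(tx, "Transcript")) {
      msgs <- c(msgs, "transcripts must be Transcript objects")
      break
    }
    if (tx@chrom != object@chrom || tx@strand != object@strand)
      msgs <- c(msgs, sprintf("transcript %s disagrees with gene %s on chrom/strand",
                              tx@id, object@id))
    if (min(tx@exons[, 1L]) < object@start || max(tx@exons[, 2L]) > object@end)
      msgs <- c(msgs, sprintf("transcript %s extends outside gene %s span",
                              tx@id, object@id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModel
#'
#' @param id,chrom,strand,start,end see [GeneModel-class].
#' @param transcripts list of [Transcript-class].
#' @return a validated [GeneModel-class] object.
#' @export
geneModel <- function(id, chrom, strand, start, end, transcripts) {
  new("GeneModel", id = as.character(id), chrom = as.character(chrom),
      strand = strand, start = as.integer(start), end = as.integer(end),
      transcripts = transcripts)
}

#' ConsensusAnnotation: the per-gene event-calling reference
#'
#' The consensus annotation of a gene holds all distinctly observed exons,
#' with retained-intron exons removed, clustered by genomic overlap into
#' exon groups. Each group carries a representative boundary pair (the one
#' observed in the most transcripts) plus every observed boundary variant.
#' It is the baseline against which splice events are called; it is not
#' necessarily any one transcript of the gene.
#'
#' @slot geneId gene identifier.
#' @slot chrom,strand location.
#' @slot groups ordered list (by genomic position); each element is a list
#'   with `rep` (`c(start, end)` representative), `variants` (matrix of
#'   observed boundary pairs with a `votes` column), and `members`
#'   (character vector of transcript ids observing the group).
#' @exportClass ConsensusAnnotation
setClass("ConsensusAnnotation",
  representation(
    geneId = "character",
    chrom  = "character",
    strand = "character",
    groups = "list"
  )
)

setValidity("ConsensusAnnotation", function(object) {
  if (length(object@groups) == 0L) return(TRUE)
  reps <- t(vapply(object@groups, `[[`, integer(2), "rep"))
  if (any(reps[, 1L] >= reps[, 2L]))
    return("group representatives must satisfy start < end")
  if (nrow(reps) > 1L &&
      any(reps[-1L, 1L] < reps[-nrow(reps), 2L]))
    return("group representatives must be sorted and non-overlapping")
  TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn Transcript-class transcript identifier
#' @param x a Transcript or GeneModel
#' @export
txId <- function(x) x@id

#' @describeIn Transcript-class exon matrix (0-based half-open)
#' @export
exons <- function(x) x@exons

#' @describeIn Transcript-class genomic CDS span or `integer(0)`
#' @export
cds <- function(x) x@cds

#' @describeIn GeneModel-class list of transcripts
#' @export
transcripts <- function(x) x@transcripts

#' @describeIn GeneModel-class gene identifier
#' @export
geneId <- function(x) if (is(x, "GeneModel")) x@id else x@geneId

#' Introns of a transcript
#'
#' @param tx a [Transcript-class].
#' @return integer matrix of the gaps between consecutive exons
#'   (0-based half-open), zero rows for a single-exon transcript.
#' @export
introns <- function(tx) {
  ex <- tx@exons
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
}

#' Spliced (mature) length of a transcript
#' @param tx a [Transcript-class].
#' @return total exonic length in nucleotides.
#' @export
splicedLength <- function(tx) sum(tx@exons[, 2L] - tx@exons[, 1L])

## ---- show methods ----------------------------------------------------------

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript %s (gene %s) %s:%d-%d(%s) %d exon(s), %d nt spliced%s\n",
              object@id, object@geneId, object@chrom,
              min(object@exons[, 1L]), max(object@exons[, 2L]), object@strand,
              nrow(object@exons), splicedLength(object),
              if (length(object@cds)) sprintf(", CDS %d-%d", object@cds[1L], object@cds[2L])
              else ", no CDS"))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s %s:%d-%d(%s) with %d transcript(s)\n",
              object@id, object@chrom, object@start, object@end,
              object@strand, length(object@transcripts)))
})

setMethod("show", "ConsensusAnnotation", function(object) {
  cat(sprintf("ConsensusAnnotation for gene %s: %d exon group(s)\n",
              object@geneId, length(object@groups)))
  for (i in seq_along(object@groups)) {
    g <- object@groups[[i]]
    cat(sprintf("  group %d: rep [%d,%d), %d variant(s), %d member tx\n",
                i, g$rep[1L], g$rep[2L], nrow(g$variants), length(g$members)))
  }
})
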