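## Consensus annotation: the per-gene event-calling reference. It contains
## all distinctly observed exons of the gene, with retained-intron exons
## removed, clustered by overlap into exon groups; it need not equal any
## transcript of the gene (and need not contain a valid ORF).

#' Build the consensus annotation of a gene
#'
#' An observed exon is a retained-intron exon iff some splice junction
#' (intron) of another transcript of the same gene lies strictly inside
#' it; such exons are excluded, iterating to a fixpoint so nested
#' retentions are handled. The remaining exons are clustered into groups
#' by genomic overlap (single linkage). Each group's representative
#' boundary pair is the one observed in the most transcripts; ties go to
#' the longest variant, then the 5'-most (transcript orientation).
#'
#' @param gene a [GeneModel-class] with at least one transcript.
#' @return a [ConsensusAnnotation-class].
#' @export
buildConsensus <- function(gene) {
  txs <- gene@transcripts
  if (length(txs) == 0L) stop("gene ", gene@id, " has no transcripts")

  recs <- do.call(rbind, lapply(txs, function(tx)
    data.frame(tx = tx@id, start = tx@exons[, 1L], end = tx@exons[, 2L])))
  jn <- do.call(rbind, lapply(txs, function(tx) {
    j <- introns(tx)
    if (nrow(j) == 0L) return(NULL)
    data.frame(tx = tx@id, start = j[, 1L], end = j[, 2L])
  }))

  ## iterated retained-intron removal (the junction set is taken from all
  ## transcripts; iteration guards nested retentions)
  repeat {
    isIR <- rep(FALSE, nrow(recs))
    if (!is.null(jn) && nrow(jn) > 0L) {
      for (i in seq_len(nrow(recs))) {
        inside <- jn$tx != recs$tx[i] &
          recs$start[i] < jn$start & jn$end < recs$end[i]
        isIR[i] <- any(inside)
      }
    }
    if (!any(isIR)) break
    recs <- recs[!isIR, , drop = FALSE]
    if (nrow(recs) == 0L) break
  }

  groups <- list()
  if (nrow(recs) > 0L) {
    ir <- IRanges::IRanges(start = recs$start + 1L, end = recs$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # merge on true overlap only
    hit <- IRanges::findOverlaps(ir, red)
    grpIdx <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (gi in seq_along(red)) {
      sel <- recs[grpIdx == gi, , drop = FALSE]
      key <- paste(sel$start, sel$end)
      tab <- table(key)
      variants <- unique(sel[, c("start", "end")])
      variants$votes <- as.integer(tab[paste(variants$start, variants$end)])
      ## representative: majority vote; tie -> longest; tie -> 5'-most
      len <- variants$end - variants$start
      five <- if (gene@strand == "+") -variants$start else variants$end
      ord <- order(-variants$votes, -len, -five)
      rep_ <- c(variants$start[ord[1L]], variants$end[ord[1L]])
      groups[[gi]] <- list(
        rep = as.integer(rep_),
        variants = as.matrix(variants[order(variants$start, variants$end),
                                      c("start", "end", "votes")]),
        members = unique(sel$tx))
    }
    groups <- groups[order(vapply(groups, function(g) g$rep[1L], integer(1)))]
  }
  new("ConsensusAnnotation", geneId = gene@id, chrom = gene@chrom,
      strand = gene@strand, groups = groups)
}

#' Align a transcript's exons to the consensus annotation
#'
#' Maps each exon of the transcript to every consensus exon group whose
#' representative it overlaps (falling back to the group's variant span
#' when no representative is hit). An exon covering two or more groups
#' plus the gap between them marks a fusion (retained intron); a group
#' left unmapped between mapped groups marks an absence (skipped exon).
#'
#' @param tx a [Transcript-class] of the consensus's gene.
#' @param consensus a [ConsensusAnnotation-class].
#' @return list with `map` (per exon, the integer indices of overlapped
#'   groups), `present` (logical per group) and `anomalies` (character;
#'   exons overlapping no group territory are reported, not dropped).
#' @export
alignExons <- function(tx, consensus) {
  groups <- consensus@groups
  nG <- length(groups)
  reps <- if (nG) t(vapply(groups, `[[`, integer(2), "rep"))
          else matrix(integer(0), ncol = 2L)
  spans <- if (nG) t(vapply(groups, function(g)
    c(min(g$variants[, "start"]), max(g$variants[, "end"])), integer(2)))
    else matrix(integer(0), ncol = 2L)

  overlaps <- function(s, e, m)
    which(pmax(s, m[, 1L]) < pmin(e, m[, 2L]))

  map <- vector("list", nrow(tx@exons))
  anomalies <- character(0)
  for (i in seq_len(nrow(tx@exons))) {
    s <- tx@exons[i, 1L]; e <- tx@exons[i, 2L]
    hits <- overlaps(s, e, reps)
    if (length(hits) == 0L) hits <- overlaps(s, e, spans)
    if (length(hits) == 0L)
      anomalies <- c(anomalies, sprintf(
        "exon [%d,%d) of transcript %s overlaps no consensus group", s, e, tx@id))
    map[[i]] <- hits
  }
  present <- rep(FALSE, nG)
  present[unique(unlist(map))] <- TRUE
  list(map = map, present = present, anomalies = anomalies)
}
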