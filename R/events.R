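.EVENT_TYPES <- c("IR", "ES", "A5SS", "A3SS", "MXE", "MA5SS", "MA3SS")

.emptyEvents <- function() {
  data.frame(gene_id = character(0), transcript_ids = character(0),
             etype = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             region = character(0), frame_neutral = logical(0),
             delta_nt = integer(0), stringsAsFactors = FALSE)
}

.eventRow <- function(gene_id, transcript_ids, etype, chrom, start, end,
                      strand, delta_nt) {
  data.frame(gene_id = gene_id, transcript_ids = transcript_ids,
             etype = etype, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             region = NA_character_, frame_neutral = NA,
             delta_nt = as.integer(delta_nt), stringsAsFactors = FALSE)
}

#' Call primitive splicing events of one transcript
#'
#' Compares a transcript to its gene's consensus annotation. An internal
#' consensus group absent from the transcript is an exon skipping (ES);
#' an exon fusing consecutive groups is an intron retention (IR, one event
#' per retained intron); an exon boundary differing from the group
#' representative at the exon's 5' end (transcript orientation) is an
#' alternative 5' splice site (A5SS), at the 3' end an A3SS. Outer
#' boundaries of the transcript-terminal exons are transcription
#' start/end variation, not splicing, and are never called; a missing
#' terminal group is likewise reported as an anomaly, not as ES.
#'
#' @param tx a [Transcript-class].
#' @param consensus the gene's [ConsensusAnnotation-class].
#' @return data.frame of events (`gene_id`, `transcript_ids`, `etype`,
#'   `chrom`, `start`, `end`, `strand`, `region`, `frame_neutral`,
#'   `delta_nt`); `region`/`frame_neutral` are filled by
#'   [classifyEventContext()]. `delta_nt` is the signed spliced-length
#'   change versus the consensus representative (retention/extension
#'   positive).
#' @export
callPrimitiveEvents <- function(tx, consensus) {
  aln <- alignExons(tx, consensus)
  groups <- consensus@groups
  ev <- list()
  chrom <- consensus@chrom; strand <- consensus@strand
  gid <- consensus@geneId

  mapped <- which(aln$present)
  if (length(mapped) >= 2L) {
    internalAbsent <- setdiff(seq(min(mapped), max(mapped)), mapped)
    for (g in internalAbsent) {
      r <- groups[[g]]$rep
      ev <- c(ev, list(.eventRow(gid, tx@id, "ES", chrom, r[1L], r[2L],
                                 strand, -(r[2L] - r[1L]))))
    }
  }

  nEx <- nrow(tx@exons)
  for (i in seq_len(nEx)) {
    hits <- sort(aln$map[[i]])
    if (length(hits) == 0L) next
    s <- tx@exons[i, 1L]; e <- tx@exons[i, 2L]

    ## fusion of consecutive covered groups -> one IR per retained intron
    if (length(hits) >= 2L) {
      for (k in seq_len(length(hits) - 1L)) {
        gapS <- groups[[hits[k]]]$rep[2L]
        gapE <- groups[[hits[k + 1L]]]$rep[1L]
        if (s <= gapS && gapE <= e && gapS < gapE)
          ev <- c(ev, list(.eventRow(gid, tx@id, "IR", chrom, gapS, gapE,
                                     strand, gapE - gapS)))
      }
    }

    ## boundary events at junction-adjacent ends only
    repL <- groups[[hits[1L]]]$rep[1L]
    repR <- groups[[hits[length(hits)]]]$rep[2L]
    leftInner <- i > 1L      # genomic-left boundary is junction-adjacent
    rightInner <- i < nEx
    if (leftInner && s != repL) {
      etype <- if (strand == "+") "A5SS" else "A3SS"
      ev <- c(ev, list(.eventRow(gid, tx@id, etype, chrom,
                                 min(s, repL), max(s, repL), strand,
                                 repL - s)))
    }
    if (rightInner && e != repR) {
      etype <- if (strand == "+") "A3SS" else "A5SS"
      ev <- c(ev, list(.eventRow(gid, tx@id, etype, chrom,
                                 min(e, repR), max(e, repR), strand,
                                 e - repR)))
    }
  }
  if (length(ev) == 0L) return(.emptyEvents())
  do.call(rbind, ev)
}

#' Call composite splicing events of a gene
#'
#' Mutually exclusive exons (MXE): an unordered pair of consensus exon
#' groups each observed in at least one transcript of the gene but never
#' together in any transcript. Multiple alternative 5'/3' splice sites
#' (MA5SS/MA3SS): an exon group whose observed boundary variants hold
#' three or more distinct 5' (resp. 3') boundaries, in transcript
#' orientation.
#'
#' @param gene a [GeneModel-class] with at least two transcripts.
#' @param consensus its [ConsensusAnnotation-class].
#' @return events data.frame as for [callPrimitiveEvents()];
#'   `transcript_ids` is the comma-separated member set and `delta_nt`
#'   is 0 for composite events.
#' @export
callCompositeEvents <- function(gene, consensus) {
  txs <- gene@transcripts
  if (length(txs) < 2L) return(.emptyEvents())
  groups <- consensus@groups
  nG <- length(groups)
  if (nG == 0L) return(.emptyEvents())
  chrom <- consensus@chrom; strand <- consensus@strand
  gid <- consensus@geneId

  pres <- matrix(FALSE, nrow = length(txs), ncol = nG,
                 dimnames = list(vapply(txs, txId, character(1)), NULL))
  for (t in seq_along(txs))
    pres[t, ] <- alignExons(txs[[t]], consensus)$present

  ev <- list()
  if (nG >= 2L) {
    for (i in seq_len(nG - 1L)) for (j in seq(i + 1L, nG)) {
      if (any(pres[, i]) && any(pres[, j]) && !any(pres[, i] & pres[, j])) {
        members <- rownames(pres)[pres[, i] | pres[, j]]
        ev <- c(ev, list(.eventRow(
          gid, paste(members, collapse = ","), "MXE", chrom,
          groups[[i]]$rep[1L], groups[[j]]$rep[2L], strand, 0L)))
      }
    }
  }
  for (g in seq_len(nG)) {
    v <- groups[[g]]$variants
    fiveB <- if (strand == "+") v[, "start"] else v[, "end"]
    threeB <- if (strand == "+") v[, "end"] else v[, "start"]
    members <- paste(groups[[g]]$members, collapse = ",")
    if (length(unique(fiveB)) >= 3L)
      ev <- c(ev, list(.eventRow(gid, members, "MA5SS", chrom,
                                 min(fiveB), max(fiveB), strand, 0L)))
    if (length(unique(threeB)) >= 3L)
      ev <- c(ev, list(.eventRow(gid, members, "MA3SS", chrom,
                                 min(threeB), max(threeB), strand, 0L)))
  }
  if (length(ev) == 0L) return(.emptyEvents())
  do.call(rbind, ev)
}

#' Assign coding/UTR context and reading-frame neutrality to events
#'
#' An event is `coding` iff its genomic interval overlaps the bearing
#' transcript's genomic CDS span, else `utr`; it is frame-neutral iff the
#' length of that overlap is a multiple of 3. A transcript without a CDS
#' puts all its events in the UTR (and such events are trivially
#' frame-neutral: zero coding nucleotides change).
#'
#' @param events events data.frame (rows borne by `tx`).
#' @param tx the bearing [Transcript-class], with `cds` computed.
#' @return the events with `region` and `frame_neutral` filled.
#' @export
classifyEventContext <- function(events, tx) {
  if (nrow(events) == 0L) return(events)
  for (r in seq_len(nrow(events))) {
    ov <- 0L
    if (length(tx@cds) == 2L)
      ov <- max(0L, min(events$end[r], tx@cds[2L]) -
                    max(events$start[r], tx@cds[1L]))
    events$region[r] <- if (ov > 0L) "coding" else "utr"
    events$frame_neutral[r] <- (ov %% 3L) == 0L
  }
  events
}

#' Call and contextualize all splicing events of one gene
#'
#' Builds the consensus annotation, calls primitive events per transcript
#' and composite events across transcripts, and assigns coding/UTR and
#' frame context. When `genome` is supplied, each transcript's CDS is
#' (re)computed from its longest ORF first. Composite events take the
#' any-member rule: coding if the event interval is coding in any member
#' transcript.
#'
#' @param gene a [GeneModel-class].
#' @param genome optional named `DNAStringSet` for CDS computation.
#' @param minOrfNt minimum ORF length for CDS assignment.
#' @return events data.frame (see [callPrimitiveEvents()]).
#' @export
callGeneEvents <- function(gene, genome = NULL, minOrfNt = 40L) {
  txs <- gene@transcripts
  if (!is.null(genome))
    txs <- lapply(txs, function(tx) computeCdsUtrs(tx, genome, minOrfNt)$tx)
  byId <- setNames(txs, vapply(txs, txId, character(1)))
  gene@transcripts <- txs
  consensus <- buildConsensus(gene)

  prim <- do.call(rbind, c(list(.emptyEvents()), lapply(txs, function(tx)
    classifyEventContext(callPrimitiveEvents(tx, consensus), tx))))

  comp <- callCompositeEvents(gene, consensus)
  if (nrow(comp) > 0L) {
    for (r in seq_len(nrow(comp))) {
      members <- strsplit(comp$transcript_ids[r], ",", fixed = TRUE)[[1L]]
      rows <- lapply(members, function(m)
        classifyEventContext(comp[r, , drop = FALSE], byId[[m]]))
      regions <- vapply(rows, function(x) x$region, character(1))
      coding <- which(regions == "coding")
      pick <- if (length(coding)) rows[[coding[1L]]] else rows[[1L]]
      comp$region[r] <- pick$region
      comp$frame_neutral[r] <- pick$frame_neutral
    }
  }
  out <- rbind(prim, comp)
  rownames(out) <- NULL
  out
}

#' Count splicing events at the event, transcript or gene level
#'
#' Event level counts every event; transcript level counts each
#' transcript once per event type (a transcript skipping two exons counts
#' once; composite events are keyed by their member-transcript set); gene
#' level counts each gene once per event type. Counts are kept per
#' (type, region) cell — deduplication applies within a region — so the
#' coding and UTR columns always sum to the totals.
#'
#' @param events events data.frame.
#' @param level `"event"`, `"transcript"` or `"gene"`.
#' @return data.frame `etype` x `region` (`coding`, `utr`) of counts,
#'   with a `total` column; all seven event types are always present.
#' @export
countEvents <- function(events, level = c("event", "transcript", "gene")) {
  level <- match.arg(level)
  grid <- expand.grid(etype = .EVENT_TYPES, region = c("coding", "utr"),
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  if (nrow(events) > 0L) {
    if (level == "transcript") {
      ## composite events are keyed by their whole transcript set, so the
      ## event >= transcript >= gene hierarchy holds for every type
      uk <- unique(data.frame(tx = events$transcript_ids,
                              etype = events$etype, region = events$region,
                              stringsAsFactors = FALSE))
      tab <- table(paste(uk$etype, uk$region))
    } else if (level == "gene") {
      uk <- unique(data.frame(gene = events$gene_id, etype = events$etype,
                              region = events$region))
      tab <- table(paste(uk$etype, uk$region))
    } else {
      tab <- table(paste(events$etype, events$region))
    }
    m <- match(paste(grid$etype, grid$region), names(tab))
    grid$count <- ifelse(is.na(m), 0L, as.integer(tab[m]))
  }
  wide <- data.frame(etype = .EVENT_TYPES,
                     coding = grid$count[grid$region == "coding"],
                     utr = grid$count[grid$region == "utr"])
  wide$total <- wide$coding + wide$utr
  wide
}

#' Select genes isolated by zero-coverage intergenic flanks
#'
#' The control set for neighbor-read interference: genes flanked on both
#' sides by intergenic regions with zero read coverage at every base.
#' Chromosome-terminal genes qualify on their single flank (`NULL` marks
#' a flank that does not exist).
#'
#' @param genes list of [GeneModel-class].
#' @param intergenicCoverage named list (by gene id) of
#'   `list(left = <numeric vector or NULL>, right = ...)` per-base
#'   coverage over the flanking intergenic intervals.
#' @return character vector of isolated gene ids.
#' @export
selectIsolatedGenes <- function(genes, intergenicCoverage) {
  out <- character(0)
  for (g in genes) {
    cov <- intergenicCoverage[[g@id]]
    if (is.null(cov) || !all(c("left", "right") %in% names(cov)))
      stop("missing flank coverage for gene ", g@id)
    flanks <- Filter(Negate(is.null), cov[c("left", "right")])
    if (all(vapply(flanks, function(x) all(x == 0), logical(1))))
      out <- c(out, g@id)
  }
  out
}
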