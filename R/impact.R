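## Functional consequences of alternative splicing per gene: domain
## gain/loss/exchange across isoforms after location re-indexing,
## subcellular-localization change edges, functional-group assignment and
## group enrichment among alternatively spliced genes.

## Transcript-orientation offset of a genomic position within the spliced
## transcript (position must be exonic).
.genomicToTxOffset <- function(tx, gpos) {
  ex <- tx@exons
  if (tx@strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2L] - ex[i, 1L]
    if (gpos >= ex[i, 1L] && gpos < ex[i, 2L]) {
      return(if (tx@strand == "+") cum + (gpos - ex[i, 1L])
             else cum + (ex[i, 2L] - 1L - gpos))
    }
    cum <- cum + w
  }
  stop("position ", gpos, " is not exonic in transcript ", tx@id)
}

#' Re-index domain hits of a gene by location
#'
#' The same domain accession occurring at two different locations in a
#' gene represents two distinct functional elements. Each isoform's
#' protein-coordinate hits are projected through its CDS onto genomic
#' (gene) coordinates, hits of one accession are clustered by genomic
#' overlap (single linkage) across all isoforms jointly, and the cluster
#' index is appended to form the located identifier
#' (`accession#index`, indices ordered by genomic position).
#'
#' @param hits data.frame `transcript_id`, `domain_id`, `aa_start`,
#'   `aa_end` (1-based inclusive amino-acid coordinates) for one gene.
#' @param transcripts list of the gene's [Transcript-class] objects with
#'   CDS set (a hit on a transcript without CDS is an error).
#' @return `hits` with added `gene_start`, `gene_end` (genomic span of
#'   the hit, 0-based half-open) and `located_id`.
#' @export
reindexDomains <- function(hits, transcripts) {
  byId <- setNames(transcripts, vapply(transcripts, txId, character(1)))
  n <- nrow(hits)
  gs <- integer(n); ge <- integer(n)
  for (i in seq_len(n)) {
    tx <- byId[[hits$transcript_id[i]]]
    if (is.null(tx))
      stop("unknown transcript in domain hits: ", hits$transcript_id[i])
    if (length(tx@cds) != 2L)
      stop("domain hit on transcript without CDS: ", tx@id)
    ## CDS start offset within the spliced transcript
    cdsStartG <- if (tx@strand == "+") tx@cds[1L] else tx@cds[2L] - 1L
    off <- .genomicToTxOffset(tx, cdsStartG)
    a <- off + 3L * (hits$aa_start[i] - 1L)
    b <- off + 3L * hits$aa_end[i]
    iv <- .txIntervalToGenomic(tx, a, b)
    gs[i] <- min(iv[, 1L]); ge[i] <- max(iv[, 2L])
  }
  hits$gene_start <- gs; hits$gene_end <- ge
  hits$located_id <- NA_character_
  for (d in unique(hits$domain_id)) {
    sel <- which(hits$domain_id == d)
    ir <- IRanges::IRanges(start = gs[sel] + 1L, end = ge[sel])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    cl <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    hits$located_id[sel] <- paste0(d, "#", cl)
  }
  hits
}

#' Classify the domain change of a gene across its isoforms
#'
#' `unannotated` if no isoform carries any located domain; `identical`
#' if all isoforms carry the same located-domain set; `exchange` if some
#' isoform pair shows a mutual asymmetric difference (each has a located
#' domain the other lacks); else `gain_loss` (a strict subset relation
#' somewhere). The outcome does not depend on isoform order.
#'
#' @param isoformDomains list (one element per isoform) of character
#'   vectors of located domain identifiers.
#' @return one of `"unannotated"`, `"identical"`, `"exchange"`,
#'   `"gain_loss"`.
#' @export
classifyDomainChange <- function(isoformDomains) {
  if (length(isoformDomains) < 2L)
    stop("domain change needs at least two isoforms")
  sets <- lapply(isoformDomains, function(x) sort(unique(as.character(x))))
  if (all(lengths(sets) == 0L)) return("unannotated")
  if (all(vapply(sets, identical, logical(1), sets[[1L]]))) return("identical")
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i >= j) next
    dij <- setdiff(sets[[i]], sets[[j]])
    dji <- setdiff(sets[[j]], sets[[i]])
    if (length(dij) && length(dji)) return("exchange")
  }
  "gain_loss"
}

#' Classify the subcellular-localization change of a gene
#'
#' @param isoformLocations character vector (or list) of the predicted
#'   location per isoform, `NA` where no prediction survived score
#'   filtering.
#' @return list with `status` (`"no_prediction"`, `"uniform"` or
#'   `"changed"`) and `edges` (data.frame `loc1`, `loc2` of distinct
#'   unordered location pairs observed between isoforms; empty unless
#'   changed).
#' @export
classifyLocalizationChange <- function(isoformLocations) {
  locs <- as.character(unlist(isoformLocations))
  pred <- locs[!is.na(locs)]
  noEdges <- data.frame(loc1 = character(0), loc2 = character(0))
  if (length(pred) == 0L)
    return(list(status = "no_prediction", edges = noEdges))
  u <- sort(unique(pred))
  if (length(u) == 1L) return(list(status = "uniform", edges = noEdges))
  pairs <- t(utils::combn(u, 2L))
  list(status = "changed",
       edges = data.frame(loc1 = pairs[, 1L], loc2 = pairs[, 2L],
                          stringsAsFactors = FALSE))
}

#' Assign functional groups to a gene
#'
#' Transcription factor iff any domain accession is in the supplied
#' DNA-binding/regulatory domain list; metabolic iff GO:0008152 is
#' annotated; cytochrome P450 iff IPR001128 is annotated; cazyme from the
#' external predictor flag; secreted iff (signal peptide or secretory
#' targeting) and at most one transmembrane domain and extracellular
#' localization score strictly greater than `psortSecretedGt`.
#'
#' @param domains character vector of domain accessions of the gene.
#' @param goTerms character vector of GO ids of the gene.
#' @param predictors list with `signal_peptide` (logical),
#'   `targeting_loc` (character; `"S"` = secretory), `tm_domain_count`
#'   (integer) and `extracellular_score` (numeric). A secretion candidate
#'   (signal peptide or secretory targeting) with missing transmembrane
#'   or extracellular values is an error.
#' @param tfDomainList character vector of transcription-factor domain
#'   accessions (config data).
#' @param cazyme logical predictor flag.
#' @param psortSecretedGt extracellular score threshold (strict `>`,
#'   default 17).
#' @return character vector, a subset of
#'   `c("TF", "cazyme", "secreted", "metabolic", "P450")`.
#' @export
assignFunctionalGroups <- function(domains, goTerms, predictors,
                                   tfDomainList = character(0),
                                   cazyme = FALSE, psortSecretedGt = 17) {
  groups <- character(0)
  if (length(intersect(domains, tfDomainList))) groups <- c(groups, "TF")
  if (isTRUE(cazyme)) groups <- c(groups, "cazyme")
  candidate <- isTRUE(predictors$signal_peptide) ||
    identical(predictors$targeting_loc, "S")
  if (candidate) {
    tm <- predictors$tm_domain_count
    sc <- predictors$extracellular_score
    if (is.null(tm) || is.null(sc) || is.na(tm) || is.na(sc))
      stop("secretion candidate gene lacks transmembrane count or extracellular score")
    if (tm <= 1L && sc > psortSecretedGt) groups <- c(groups, "secreted")
  }
  if ("GO:0008152" %in% goTerms) groups <- c(groups, "metabolic")
  if ("IPR001128" %in% domains) groups <- c(groups, "P450")
  groups
}

#' Filter localization predictions by score
#'
#' Keeps, per transcript, the best-scoring location with score at or
#' above `keepGe`; returns `NA` when nothing passes.
#'
#' @param scores named numeric vector (location -> score) for one
#'   transcript.
#' @param keepGe minimum score kept (default 17, inclusive).
#' @return location name or `NA_character_`.
#' @export
filterLocalization <- function(scores, keepGe = 17) {
  scores <- scores[!is.na(scores) & scores >= keepGe]
  if (length(scores) == 0L) return(NA_character_)
  names(scores)[which.max(scores)]
}

#' Enrichment of a functional group among alternatively spliced genes
#'
#' One-sided hypergeometric tail probability of observing at least the
#' seen overlap between the group and the alternatively spliced gene set
#' within the universe, plus the sample odds ratio.
#'
#' @param asGenes,groupGenes,universe character vectors of gene ids;
#'   `asGenes` and `groupGenes` must be subsets of `universe`.
#' @return list `overlap`, `expected`, `odds_ratio`, `p_value`.
#' @export
groupEnrichment <- function(asGenes, groupGenes, universe) {
  if (length(universe) == 0L) stop("empty universe")
  asGenes <- unique(asGenes); groupGenes <- unique(groupGenes)
  if (length(setdiff(asGenes, universe)) || length(setdiff(groupGenes, universe)))
    stop("asGenes and groupGenes must be subsets of the universe")
  N <- length(unique(universe)); K <- length(groupGenes); n <- length(asGenes)
  k <- length(intersect(asGenes, groupGenes))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  orat <- (k * (N - K - n + k)) / ((K - k) * (n - k))
  list(overlap = k, expected = n * K / N, odds_ratio = orat, p_value = p)
}

#' Enrichment table over several groups with BH correction
#'
#' @param asGenes alternatively spliced genes.
#' @param groupList named list of group gene-id vectors.
#' @param universe all expressed genes.
#' @return data.frame `group`, `size`, `overlap`, `expected`,
#'   `odds_ratio`, `p_value`, `p_adj` (Benjamini-Hochberg).
#' @export
groupEnrichmentTable <- function(asGenes, groupList, universe) {
  rows <- lapply(names(groupList), function(nm) {
    e <- groupEnrichment(asGenes, groupList[[nm]], universe)
    data.frame(group = nm, size = length(unique(groupList[[nm]])),
               overlap = e$overlap, expected = e$expected,
               odds_ratio = e$odds_ratio, p_value = e$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
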