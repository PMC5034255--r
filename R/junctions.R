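## Splice-junction cluster analysis: a semi-quantitative view of splicing
## in both modeled and unmodeled (UTR/intergenic) regions, independent of
## transcript reconstruction. Junctions observed only once across all
## samples are treated as splicing/sequencing noise and removed.

#' Load aligner junction tables, merge samples, drop singletons
#'
#' Reads one or more spliced-aligner junction tables (tab-separated:
#' chrom, 1-based first/last intronic base, strand code 0/1/2 or
#' `./+/-`, then optional motif/annotated columns with the unique-read
#' count in column 7 — or a minimal 4-column chrom/start/end/count
#' dialect). Counts are summed across files per distinct junction, then
#' junctions with a total count of one are removed.
#'
#' @param paths character vector of junction table files.
#' @param keepSingletons keep count-1 junctions (for diagnostics).
#' @return data.frame `chrom`, `donor` (0-based first intronic base),
#'   `acceptor` (one past the last intronic base), `strand`
#'   (`+`, `-` or `*`), `count`.
#' @export
loadJunctions <- function(paths, keepSingletons = FALSE) {
  parts <- lapply(paths, .readJunctionFile)
  all <- do.call(rbind, parts)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      count = integer(0)))
  key <- paste(all$chrom, all$donor, all$acceptor, all$strand)
  agg <- rowsum(all$count, key)
  first <- all[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(agg[match(paste(first$chrom, first$donor,
                                            first$acceptor, first$strand),
                                      rownames(agg)), 1L])
  out <- first[order(first$chrom, first$donor, first$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  if (!keepSingletons) out <- out[out$count > 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.readJunctionFile <- function(path) {
  if (!file.exists(path)) stop("junction table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop(sprintf("malformed junction row at %s line %d: expected >= 4 fields",
                 path, bad[1L]))
  decodeStrand <- function(x)
    c("0" = "*", "1" = "+", "2" = "-", "+" = "+", "-" = "-", "." = "*",
      "*" = "*")[x]
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    s <- suppressWarnings(as.integer(f[2L])); e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e) || s > e)
      stop(sprintf("malformed junction row at %s line %d", path, i))
    if (length(f) >= 7L) {           # aligner dialect: strand code col 4, unique reads col 7
      strand <- decodeStrand(f[4L]); cnt <- suppressWarnings(as.integer(f[7L]))
    } else {                         # minimal dialect: chrom start end count [strand]
      cnt <- suppressWarnings(as.integer(f[4L]))
      strand <- if (length(f) >= 5L) decodeStrand(f[5L]) else "*"
    }
    if (is.na(strand)) strand <- "*"
    if (is.na(cnt))
      stop(sprintf("malformed junction count at %s line %d", path, i))
    data.frame(chrom = f[1L], donor = s - 1L, acceptor = e,
               strand = strand, count = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster junctions by genomic overlap
#'
#' Single-linkage clustering of junction intervals per (chrom, strand);
#' junctions of unknown strand cluster with both strands of their
#' chromosome. Cluster spans are pairwise disjoint within a (chrom,
#' strand) track; singleton clusters are allowed.
#'
#' @param junctions data.frame from [loadJunctions()].
#' @return the junctions with an added integer `cluster` column.
#' @export
clusterJunctions <- function(junctions) {
  junctions$cluster <- NA_integer_
  if (nrow(junctions) == 0L) return(junctions)
  nextId <- 1L
  for (ch in unique(junctions$chrom)) {
    for (st in c("+", "-")) {
      sel <- which(junctions$chrom == ch &
                   junctions$strand %in% c(st, "*"))
      sel <- sel[is.na(junctions$cluster[sel]) |
                 junctions$strand[sel] != "*"]
      if (length(sel) == 0L) next
      ir <- IRanges::IRanges(start = junctions$donor[sel] + 1L,
                             end = junctions$acceptor[sel])
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      hit <- IRanges::findOverlaps(ir, red)
      cl <- S4Vectors::subjectHits(hit)
      assign_ <- nextId + cl - 1L
      keep <- is.na(junctions$cluster[sel])
      junctions$cluster[sel[keep]] <- assign_[keep]
      nextId <- nextId + length(red)
    }
  }
  junctions
}

#' Classify junction-level splicing events within clusters
#'
#' Within each junction cluster: (i) junctions sharing a donor but not an
#' acceptor form alternative-splice-site events, one per distinct
#' alternative boundary (k junctions sharing a donor yield k-1 events),
#' and symmetrically for shared acceptors; the event is labeled at the
#' exon end that varies, in transcript orientation (`ASS5` = exon 5' end,
#' `ASS3` = exon 3' end). (ii) A junction J is an exon-skipping event if
#' the cluster holds J1, J2 with `J1$donor == J$donor`,
#' `J2$acceptor == J$acceptor` and `J1$acceptor <= J2$donor` — an exon
#' lies inside J. Events are assigned `coding` if their interval overlaps
#' any CDS span, else `utr` if it overlaps any gene span, else
#' `intergenic`.
#'
#' @param junctions clustered junctions from [clusterJunctions()].
#' @param genes optional list of [GeneModel-class] with CDS computed, for
#'   region labels (omit for `region = NA`).
#' @return data.frame `etype` (`ASS`, `ES`), `site_end` (`5prime`,
#'   `3prime`, `NA` for ES), `region`, `chrom`, `start`, `end`, `strand`,
#'   `cluster`, `n_junctions`, `count`.
#' @export
classifyJunctionEvents <- function(junctions, genes = NULL) {
  out <- list()
  if (nrow(junctions) > 0L) {
    for (cl in unique(junctions$cluster)) {
      jc <- junctions[junctions$cluster == cl, , drop = FALSE]
      if (nrow(jc) < 2L) next
      strand <- setdiff(unique(jc$strand), "*")
      strand <- if (length(strand) == 1L) strand else "+"
      ## shared donor, varying acceptor: the downstream (genomic right)
      ## exon's start varies -> its transcript-5' end on +, 3' end on -
      for (d in unique(jc$donor)) {
        grp <- jc[jc$donor == d, , drop = FALSE]
        accs <- sort(unique(grp$acceptor))
        if (length(accs) < 2L) next
        for (k in seq(2L, length(accs)))
          out <- c(out, list(data.frame(
            etype = "ASS",
            site_end = if (strand == "+") "5prime" else "3prime",
            region = NA_character_, chrom = grp$chrom[1L],
            start = min(accs[k - 1L], accs[k]),
            end = max(accs[k - 1L], accs[k]),
            strand = strand, cluster = cl,
            n_junctions = length(accs), count = sum(grp$count),
            stringsAsFactors = FALSE)))
      }
      ## shared acceptor, varying donor: upstream exon's end varies
      for (a in unique(jc$acceptor)) {
        grp <- jc[jc$acceptor == a, , drop = FALSE]
        dons <- sort(unique(grp$donor))
        if (length(dons) < 2L) next
        for (k in seq(2L, length(dons)))
          out <- c(out, list(data.frame(
            etype = "ASS",
            site_end = if (strand == "+") "3prime" else "5prime",
            region = NA_character_, chrom = grp$chrom[1L],
            start = min(dons[k - 1L], dons[k]),
            end = max(dons[k - 1L], dons[k]),
            strand = strand, cluster = cl,
            n_junctions = length(dons), count = sum(grp$count),
            stringsAsFactors = FALSE)))
      }
      ## exon skipping: an exon lies strictly inside a junction
      for (r in seq_len(nrow(jc))) {
        J <- jc[r, ]
        hasJ1 <- jc$donor == J$donor & jc$acceptor < J$acceptor
        hasJ2 <- jc$acceptor == J$acceptor & jc$donor > J$donor
        skip <- FALSE
        for (i1 in which(hasJ1)) for (i2 in which(hasJ2))
          if (jc$acceptor[i1] <= jc$donor[i2]) skip <- TRUE
        if (skip)
          out <- c(out, list(data.frame(
            etype = "ES", site_end = NA_character_,
            region = NA_character_, chrom = J$chrom,
            start = J$donor, end = J$acceptor, strand = strand,
            cluster = cl, n_junctions = nrow(jc), count = J$count,
            stringsAsFactors = FALSE)))
      }
    }
  }
  events <- if (length(out)) do.call(rbind, out) else
    data.frame(etype = character(0), site_end = character(0),
               region = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               cluster = integer(0), n_junctions = integer(0),
               count = integer(0))
  if (!is.null(genes) && nrow(events) > 0L)
    events$region <- .junctionRegions(events, genes)
  events
}

.junctionRegions <- function(events, genes) {
  cdsIv <- list(); geneIv <- list()
  for (g in genes) {
    geneIv[[length(geneIv) + 1L]] <- c(g@chrom, g@start, g@end)
    for (tx in g@transcripts)
      if (length(tx@cds) == 2L)
        cdsIv[[length(cdsIv) + 1L]] <- c(tx@chrom, tx@cds[1L], tx@cds[2L])
  }
  overlapAny <- function(ivs, chrom, s, e) {
    for (iv in ivs)
      if (iv[1L] == chrom && max(s, as.integer(iv[2L])) <
          min(e, as.integer(iv[3L]))) return(TRUE)
    FALSE
  }
  vapply(seq_len(nrow(events)), function(r) {
    if (overlapAny(cdsIv, events$chrom[r], events$start[r], events$end[r]))
      "coding"
    else if (overlapAny(geneIv, events$chrom[r], events$start[r], events$end[r]))
      "utr"
    else "intergenic"
  }, character(1))
}
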