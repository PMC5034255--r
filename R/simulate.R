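## Deterministic synthetic-data generator with planted ground truth.
## It emits assembler-style transcript models, expression tables, junction
## tables and predictor tables directly (no read-level simulation): the
## aligner/assembler stages are external to this package, so the generator
## reproduces their output shapes, not their inputs.

.NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Simulation configuration
#'
#' Defaults mirror the study conditions the generator emulates: the
#' primitive event mix IR 33% / A5SS 25% / A3SS 21% / ES 21%, an
#' alternatively-spliced gene fraction of 0.18, five developmental
#' stages, a TCS fraction of 0.19 among AS genes, a singleton junction
#' rate of 0.29 and a domain-change mix of identical 18% / gain-loss 70%
#' / exchange 12%. Composite events (MXE, MA5SS, MA3SS) default to zero
#' and are planted via the event mix when requested.
#'
#' @param seed integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` (min >= 4 so every
#'   event type has an eligible internal target).
#' @param exon_len,intron_len nt ranges.
#' @param intergenic integer range of gene spacing.
#' @param event_mix named proportions over IR, A5SS, A3SS, ES, MXE,
#'   MA5SS, MA3SS (must sum to 1).
#' @param fraction_as_genes fraction of genes given alternative
#'   transcripts.
#' @param frame_neutral_fraction target fraction of planted IR/A5SS/A3SS
#'   coding deltas that are multiples of 3.
#' @param stages ordered stage names (>= 2).
#' @param fraction_tcs fraction of AS genes planted as time-course
#'   switches.
#' @param noise_sd lognormal sdlog of expression noise (0 = noise-free).
#' @param singleton_junction_rate fraction of emitted junctions that are
#'   spurious singletons.
#' @param domain_change_mix named proportions over identical, gain_loss,
#'   exchange.
#' @param loc_change_mix named proportions over no_prediction, uniform,
#'   changed.
#' @param genes_per_chrom genes per simulated scaffold.
#' @return validated config list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_genes = 500L,
                             exons_per_gene = c(4L, 8L),
                             exon_len = c(60L, 240L),
                             intron_len = c(48L, 90L),
                             intergenic = c(300L, 800L),
                             event_mix = c(IR = 0.33, A5SS = 0.25,
                                           A3SS = 0.21, ES = 0.21,
                                           MXE = 0, MA5SS = 0, MA3SS = 0),
                             fraction_as_genes = 0.18,
                             frame_neutral_fraction = 1 / 3,
                             stages = .DEFAULT_STAGES,
                             fraction_tcs = 0.19,
                             noise_sd = 0.1,
                             singleton_junction_rate = 0.29,
                             domain_change_mix = c(identical = 0.18,
                                                   gain_loss = 0.70,
                                                   exchange = 0.12),
                             loc_change_mix = c(no_prediction = 0.41,
                                                uniform = 0.56,
                                                changed = 0.03),
                             genes_per_chrom = 100L) {
  full <- c(IR = 0, A5SS = 0, A3SS = 0, ES = 0, MXE = 0, MA5SS = 0, MA3SS = 0)
  full[names(event_mix)] <- event_mix
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              intergenic = as.integer(intergenic),
              event_mix = full,
              fraction_as_genes = fraction_as_genes,
              frame_neutral_fraction = frame_neutral_fraction,
              stages = stages, fraction_tcs = fraction_tcs,
              noise_sd = noise_sd,
              singleton_junction_rate = singleton_junction_rate,
              domain_change_mix = domain_change_mix,
              loc_change_mix = loc_change_mix,
              genes_per_chrom = as.integer(genes_per_chrom))
  if (abs(sum(cfg$event_mix) - 1) > 1e-9)
    stop("event_mix proportions must sum to 1")
  if (abs(sum(cfg$domain_change_mix) - 1) > 1e-9)
    stop("domain_change_mix proportions must sum to 1")
  if (cfg$n_genes < 1L || cfg$exons_per_gene[1L] < 4L)
    stop("config error: need n_genes >= 1 and at least 4 exons per gene")
  if (length(cfg$stages) < 2L) stop("config error: need at least 2 stages")
  if (cfg$exon_len[1L] < 30L || cfg$intron_len[1L] < 6L)
    stop("config error: exon/intron ranges too small for planted events")
  class(cfg) <- "SimulationConfig"
  cfg
}

.sampleLen <- function(range, neutral = NA) {
  x <- sample(seq(range[1L], range[2L]), 1L)
  if (is.na(neutral)) return(x)
  ## force length to be (or not be) a multiple of 3
  if (neutral) x <- x - (x %% 3L)
  else if (x %% 3L == 0L) x <- x + 1L
  max(x, range[1L] - 2L)
}

#' Simulate gene models with planted splicing events
#'
#' Builds a genome and gene annotation in which every alternatively
#' spliced gene carries one planted event of a sampled type. The
#' reference transcript of each gene is a single full-length ORF, so
#' CDS/UTR context is well defined. Mutually exclusive exons are realized
#' as two transcripts each skipping one of the pair (which also plants
#' the two underlying exon-skipping primitives); multiple alternative
#' splice sites are realized as two additional boundary variants.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `genes` (list of [GeneModel-class]), `genome`
#'   (named `DNAStringSet`) and `truth` (data.frame `gene_id`,
#'   `transcript_ids`, `etype`, `chrom`, `start`, `end` of every planted
#'   event).
#' @export
simulateGeneModels <- function(cfg) {
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  nChrom <- ceiling(cfg$n_genes / cfg$genes_per_chrom)
  chromSeqs <- vector("list", nChrom)
  names(chromSeqs) <- paste0("scaffold_", seq_len(nChrom))

  nAS <- round(cfg$n_genes * cfg$fraction_as_genes)
  asGenes <- sort(sample.int(cfg$n_genes, nAS))
  etypes <- if (nAS > 0L)
    sample(names(cfg$event_mix), nAS, replace = TRUE, prob = cfg$event_mix)
  else character(0)

  genes <- vector("list", cfg$n_genes)
  truth <- list()
  gi <- 0L
  for (ch in seq_len(nChrom)) {
    parts <- list()   # character chunks of this chromosome
    cursor <- 0L
    nHere <- min(cfg$genes_per_chrom, cfg$n_genes - (ch - 1L) * cfg$genes_per_chrom)
    chromName <- names(chromSeqs)[ch]
    for (k in seq_len(nHere)) {
      gi <- gi + 1L
      gid <- sprintf("g%05d", gi)
      strand <- sample(c("+", "-"), 1L)
      isAS <- gi %in% asGenes
      etype <- if (isAS) etypes[match(gi, asGenes)] else NA_character_
      wantNeutral <- runif(1L) < cfg$frame_neutral_fraction

      nEx <- sample(seq(cfg$exons_per_gene[1L], cfg$exons_per_gene[2L]), 1L)
      exLens <- vapply(seq_len(nEx), function(i) .sampleLen(cfg$exon_len),
                       integer(1))
      inLens <- vapply(seq_len(nEx - 1L), function(i)
        .sampleLen(cfg$intron_len), integer(1))

      ## choose the planted element and impose frame parity on its length
      target <- NA_integer_; target2 <- NA_integer_; d1 <- NA_integer_; d2 <- NA_integer_
      if (isAS) {
        if (etype == "IR") {
          target <- sample(seq_len(nEx - 1L), 1L)        # intron index
          inLens[target] <- .sampleLen(cfg$intron_len, wantNeutral)
        } else if (etype == "ES") {
          target <- sample(seq(2L, nEx - 1L), 1L)        # internal exon
          exLens[target] <- .sampleLen(cfg$exon_len, wantNeutral)
        } else if (etype %in% c("A5SS", "A3SS", "MA5SS", "MA3SS")) {
          target <- sample(seq(2L, nEx - 1L), 1L)
          d1 <- .sampleLen(c(6L, 30L), wantNeutral)
          d2 <- d1 + sample(c(3L, 5L, 7L), 1L)           # second variant, MA only
        } else if (etype == "MXE") {
          pair <- sort(sample(seq(2L, nEx - 1L), 2L))
          target <- pair[1L]; target2 <- pair[2L]
        }
      }

      ## gene layout
      intergap <- sample(seq(cfg$intergenic[1L], cfg$intergenic[2L]), 1L)
      parts[[length(parts) + 1L]] <-
        paste(sample(bases, intergap, replace = TRUE), collapse = "")
      cursor <- cursor + intergap
      exStart <- integer(nEx); exEnd <- integer(nEx)
      pos <- cursor
      for (i in seq_len(nEx)) {
        exStart[i] <- pos; exEnd[i] <- pos + exLens[i]
        pos <- exEnd[i] + if (i < nEx) inLens[i] else 0L
      }
      ## pad spliced length to a codon multiple
      L <- sum(exLens)
      pad <- (3L - L %% 3L) %% 3L
      exEnd[nEx] <- exEnd[nEx] + pad; exLens[nEx] <- exLens[nEx] + pad
      L <- L + pad
      geneStart <- exStart[1L]; geneEnd <- exEnd[nEx]

      ## coding sequence: one ORF spanning the whole reference transcript
      ncod <- L %/% 3L
      spliced <- paste(c("ATG",
                         sample(.NONSTOP_CODONS, ncod - 2L, replace = TRUE),
                         "TAA"), collapse = "")
      genomicExonic <- if (strand == "+") spliced else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
      ## interleave exon chunks with intron sequence
      cut <- cumsum(c(0L, exLens))
      for (i in seq_len(nEx)) {
        parts[[length(parts) + 1L]] <-
          substring(genomicExonic, cut[i] + 1L, cut[i + 1L])
        if (i < nEx)
          parts[[length(parts) + 1L]] <-
            paste(sample(bases, inLens[i], replace = TRUE), collapse = "")
      }
      cursor <- geneEnd

      ## transcripts + ground truth
      refExons <- cbind(exStart, exEnd)
      t1 <- transcript(paste0(gid, ".t1"), gid, chromName, strand, refExons,
                       source = "predicted")
      txs <- list(t1)
      addTruth <- function(ids, ety, s, e)
        truth[[length(truth) + 1L]] <<- data.frame(
          gene_id = gid, transcript_ids = ids, etype = ety,
          chrom = chromName, start = as.integer(s), end = as.integer(e),
          stringsAsFactors = FALSE)

      if (isAS) {
        if (etype == "IR") {
          alt <- refExons
          alt[target, 2L] <- alt[target + 1L, 2L]
          alt <- alt[-(target + 1L), , drop = FALSE]
          txs <- c(txs, list(transcript(paste0(gid, ".t2"), gid, chromName,
                                        strand, alt, source = "predicted")))
          addTruth(paste0(gid, ".t2"), "IR", exEnd[target], exStart[target + 1L])
        } else if (etype == "ES") {
          alt <- refExons[-target, , drop = FALSE]
          txs <- c(txs, list(transcript(paste0(gid, ".t2"), gid, chromName,
                                        strand, alt, source = "predicted")))
          addTruth(paste0(gid, ".t2"), "ES", exStart[target], exEnd[target])
        } else if (etype %in% c("A5SS", "A3SS")) {
          ## contraction at the named exon end, transcript orientation
          shiftLeft <- (etype == "A5SS") == (strand == "+")
          alt <- refExons
          if (shiftLeft) alt[target, 1L] <- alt[target, 1L] + d1
          else alt[target, 2L] <- alt[target, 2L] - d1
          txs <- c(txs, list(transcript(paste0(gid, ".t2"), gid, chromName,
                                        strand, alt, source = "predicted")))
          iv <- if (shiftLeft) c(exStart[target], exStart[target] + d1)
                else c(exEnd[target] - d1, exEnd[target])
          addTruth(paste0(gid, ".t2"), etype, iv[1L], iv[2L])
        } else if (etype == "MXE") {
          a <- refExons[-target2, , drop = FALSE]   # keeps exon `target`
          b <- refExons[-target, , drop = FALSE]    # keeps exon `target2`
          txs <- list(
            transcript(paste0(gid, ".t1"), gid, chromName, strand, a,
                       source = "predicted"),
            transcript(paste0(gid, ".t2"), gid, chromName, strand, b,
                       source = "predicted"))
          addTruth(paste0(gid, ".t1,", gid, ".t2"), "MXE",
                   exStart[target], exEnd[target2])
          addTruth(paste0(gid, ".t1"), "ES", exStart[target2], exEnd[target2])
          addTruth(paste0(gid, ".t2"), "ES", exStart[target], exEnd[target])
        } else if (etype %in% c("MA5SS", "MA3SS")) {
          shiftLeft <- (etype == "MA5SS") == (strand == "+")
          altA <- refExons; altB <- refExons
          if (shiftLeft) {
            altA[target, 1L] <- altA[target, 1L] + d1
            altB[target, 1L] <- altB[target, 1L] + d2
            b5 <- c(exStart[target], exStart[target] + d1, exStart[target] + d2)
            ivA <- c(exStart[target], exStart[target] + d1)
            ivB <- c(exStart[target], exStart[target] + d2)
          } else {
            altA[target, 2L] <- altA[target, 2L] - d1
            altB[target, 2L] <- altB[target, 2L] - d2
            b5 <- c(exEnd[target], exEnd[target] - d1, exEnd[target] - d2)
            ivA <- c(exEnd[target] - d1, exEnd[target])
            ivB <- c(exEnd[target] - d2, exEnd[target])
          }
          prim <- substr(etype, 2L, 5L)   # A5SS / A3SS
          txs <- c(txs, list(
            transcript(paste0(gid, ".t2"), gid, chromName, strand, altA,
                       source = "predicted"),
            transcript(paste0(gid, ".t3"), gid, chromName, strand, altB,
                       source = "predicted")))
          addTruth(paste0(gid, ".t2"), prim, ivA[1L], ivA[2L])
          addTruth(paste0(gid, ".t3"), prim, ivB[1L], ivB[2L])
          addTruth(paste(vapply(txs, txId, character(1)), collapse = ","),
                   etype, min(b5), max(b5))
        }
      }
      genes[[gi]] <- geneModel(gid, chromName, strand, geneStart, geneEnd, txs)
    }
    chromSeqs[[ch]] <- paste(unlist(parts), collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(chromSeqs))
  names(genome) <- names(chromSeqs)
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), transcript_ids = character(0),
               etype = character(0), chrom = character(0),
               start = integer(0), end = integer(0))
  list(genes = genes, genome = genome, truth = truthDf)
}

#' Simulate developmental expression profiles with planted switches
#'
#' TCS genes receive an alternative profile that overtakes the primary at
#' a sampled stage (dominance flipping from about 0.1 to about 0.9);
#' non-TCS alternatives are scaled copies of the primary profile,
#' multiplied by per-stage lognormal noise of sdlog `noise_sd`.
#'
#' @param cfg a [simulationConfig()].
#' @param genes gene models from [simulateGeneModels()].
#' @return list with `profiles` (data.frame `transcript_id`, `gene_id`,
#'   stage columns) and `tcsGenes` (character vector of planted switch
#'   gene ids).
#' @export
simulateExpression <- function(cfg, genes) {
  set.seed(cfg$seed + 1L)
  nS <- length(cfg$stages)
  multi <- Filter(function(g) length(g@transcripts) > 1L, genes)
  nTcs <- round(length(multi) * cfg$fraction_tcs)
  tcsIds <- if (length(multi))
    vapply(multi[sample.int(length(multi), nTcs)], geneId, character(1))
  else character(0)

  rows <- list()
  noise <- function(n) if (cfg$noise_sd > 0) rlnorm(n, 0, cfg$noise_sd) else rep(1, n)
  for (g in genes) {
    txIds <- vapply(g@transcripts, txId, character(1))
    primary <- rlnorm(nS, log(20), 0.4)
    vals <- list(primary)
    if (length(txIds) > 1L) {
      isTcs <- g@id %in% tcsIds
      switchStage <- sample.int(nS, 1L)
      for (j in seq(2L, length(txIds))) {
        if (isTcs && j == 2L) {
          alt <- primary * 0.08
          alt[switchStage] <- primary[switchStage] * 9
          alt <- alt * noise(nS)
        } else {
          alt <- primary * runif(1L, 0.2, 0.8) * noise(nS)
        }
        vals <- c(vals, list(alt))
      }
    }
    for (j in seq_along(txIds)) {
      row <- data.frame(transcript_id = txIds[j], gene_id = g@id,
                        stringsAsFactors = FALSE)
      row[cfg$stages] <- as.list(vals[[j]])
      rows <- c(rows, list(row))
    }
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  list(profiles = profiles, tcsGenes = sort(tcsIds))
}

## Largest genomic interval that is coding-exonic in every transcript.
.sharedCodingWindow <- function(txs) {
  ivs <- lapply(txs, function(tx) {
    if (length(tx@cds) != 2L) return(NULL)
    s <- pmax(tx@exons[, 1L], tx@cds[1L])
    e <- pmin(tx@exons[, 2L], tx@cds[2L])
    keep <- s < e
    IRanges::IRanges(start = s[keep] + 1L, end = e[keep])
  })
  if (any(vapply(ivs, is.null, logical(1)))) return(NULL)
  common <- Reduce(IRanges::intersect, ivs)
  if (length(common) == 0L) return(NULL)
  w <- which.max(IRanges::width(common))
  if (IRanges::width(common)[w] < 24L) return(NULL)
  c(BiocGenerics::start(common)[w] - 1L, BiocGenerics::end(common)[w])
}

## Convert a genomic interval (within one exon, inside the CDS) to 1-based
## inclusive amino-acid coordinates on a transcript's protein.
.genomicToAa <- function(tx, g1, g2) {
  cdsStartG <- if (tx@strand == "+") tx@cds[1L] else tx@cds[2L] - 1L
  off <- .genomicToTxOffset(tx, cdsStartG)
  o1 <- .genomicToTxOffset(tx, g1)
  o2 <- .genomicToTxOffset(tx, g2 - 1L)
  nt <- sort(c(o1, o2) - off)
  c(nt[1L] %/% 3L + 1L, nt[2L] %/% 3L + 1L)
}

#' Simulate junction, domain and predictor tables with planted changes
#'
#' Junctions are derived from every transcript's introns with read counts
#' of at least 2, plus spurious singleton junctions at the configured
#' rate. Domain tables plant identical / gain-loss / exchange categories
#' on multi-isoform genes whose isoforms share a coding window; predictor
#' tables plant localization uniformity or change per the configured mix.
#'
#' @param cfg a [simulationConfig()].
#' @param genes gene models from [simulateGeneModels()].
#' @param genome the matching genome (`DNAStringSet`), used to compute
#'   each transcript's CDS for domain placement.
#' @return list with `junctions` (data.frame `chrom`, `first`, `last`
#'   1-based intronic bounds, `strand`, `count`, `singleton`),
#'   `domainHits`, `locScores` (per transcript location scores),
#'   `domainTruth` (named category per planted gene) and `locTruth`
#'   (data.frame of planted localization edges).
#' @export
simulateAuxTables <- function(cfg, genes, genome) {
  set.seed(cfg$seed + 2L)
  ## --- junction table -------------------------------------------------
  jrows <- list()
  for (g in genes) for (tx in g@transcripts) {
    jn <- introns(tx)
    if (nrow(jn) == 0L) next
    for (i in seq_len(nrow(jn)))
      jrows <- c(jrows, list(data.frame(
        chrom = g@chrom, first = jn[i, 1L] + 1L, last = jn[i, 2L],
        strand = g@strand, count = sample(2:50, 1L), singleton = FALSE,
        stringsAsFactors = FALSE)))
  }
  real <- do.call(rbind, jrows)
  ## collapse duplicates (shared introns across isoforms)
  key <- paste(real$chrom, real$first, real$last)
  agg <- rowsum(real$count, key)
  real <- real[!duplicated(key), , drop = FALSE]
  real$count <- as.integer(agg[match(paste(real$chrom, real$first, real$last),
                                     rownames(agg)), 1L])
  rate <- cfg$singleton_junction_rate
  nSing <- round(rate / (1 - rate) * nrow(real))
  if (nSing > 0L) {
    base <- real[sample.int(nrow(real), nSing, replace = TRUE), , drop = FALSE]
    shift <- sample(c(-40:-10, 10:40), nSing, replace = TRUE)
    base$first <- pmax(2L, base$first + shift)
    base$last <- base$first + sample(40:80, nSing, replace = TRUE)
    base$count <- 1L
    base$singleton <- TRUE
    ## spurious junctions must not coincide with a real one
    clash <- paste(base$chrom, base$first, base$last) %in%
      paste(real$chrom, real$first, real$last)
    base$first[clash] <- base$first[clash] + 1L
    junctions <- rbind(real, base)
  } else junctions <- real
  rownames(junctions) <- NULL

  ## --- domain + localization tables ------------------------------------
  multi <- Filter(function(g) length(g@transcripts) > 1L, genes)
  dRows <- list(); domainTruth <- character(0)
  locRows <- list(); locTruth <- list()
  locations <- c("extracellular", "mitochondrion", "nucleus",
                 "cytoplasm", "plasma_membrane")
  for (g in multi) {
    txs <- lapply(g@transcripts, function(tx)
      computeCdsUtrs(tx, genome)$tx)
    win <- .sharedCodingWindow(txs)
    if (!is.null(win)) {
      cat_ <- sample(names(cfg$domain_change_mix), 1L,
                     prob = cfg$domain_change_mix)
      w <- c(win[1L], win[1L] + 24L)
      aa <- lapply(txs, .genomicToAa, w[1L], w[2L])
      doms <- sprintf("IPR%06d", sample.int(999999L, 2L))  # two distinct accessions
      dom1 <- doms[1L]; dom2 <- doms[2L]
      addHit <- function(tx, dom, aaIv)
        dRows[[length(dRows) + 1L]] <<- data.frame(
          gene_id = g@id, transcript_id = txId(tx), domain_id = dom,
          aa_start = aaIv[1L], aa_end = aaIv[2L], stringsAsFactors = FALSE)
      if (cat_ == "identical") {
        for (i in seq_along(txs)) addHit(txs[[i]], dom1, aa[[i]])
      } else if (cat_ == "gain_loss") {
        for (i in seq_along(txs)) addHit(txs[[i]], dom1, aa[[i]])
        addHit(txs[[1L]], dom2, aa[[1L]])
      } else {  # exchange
        addHit(txs[[1L]], dom1, aa[[1L]])
        for (i in seq(2L, length(txs))) addHit(txs[[i]], dom2, aa[[i]])
      }
      domainTruth[g@id] <- cat_
    }
    ## localization planting is independent of CDS geometry
    lcat <- sample(names(cfg$loc_change_mix), 1L, prob = cfg$loc_change_mix)
    ids <- vapply(g@transcripts, txId, character(1))
    if (lcat == "no_prediction") {
      for (id in ids)
        locRows[[length(locRows) + 1L]] <- data.frame(
          gene_id = g@id, transcript_id = id,
          location = sample(locations, 1L), score = 10,
          stringsAsFactors = FALSE)
    } else if (lcat == "uniform") {
      loc <- sample(locations, 1L)
      for (id in ids)
        locRows[[length(locRows) + 1L]] <- data.frame(
          gene_id = g@id, transcript_id = id, location = loc, score = 20,
          stringsAsFactors = FALSE)
    } else {
      pair <- sample(locations, 2L)
      locRows[[length(locRows) + 1L]] <- data.frame(
        gene_id = g@id, transcript_id = ids[1L], location = pair[1L],
        score = 20, stringsAsFactors = FALSE)
      for (id in ids[-1L])
        locRows[[length(locRows) + 1L]] <- data.frame(
          gene_id = g@id, transcript_id = id, location = pair[2L],
          score = 20, stringsAsFactors = FALSE)
      locTruth[[length(locTruth) + 1L]] <- data.frame(
        gene_id = g@id, loc1 = min(pair), loc2 = max(pair),
        stringsAsFactors = FALSE)
    }
  }
  list(junctions = junctions,
       domainHits = if (length(dRows)) do.call(rbind, dRows) else
         data.frame(gene_id = character(0), transcript_id = character(0),
                    domain_id = character(0), aa_start = integer(0),
                    aa_end = integer(0)),
       locScores = if (length(locRows)) do.call(rbind, locRows) else
         data.frame(gene_id = character(0), transcript_id = character(0),
                    location = character(0), score = numeric(0)),
       domainTruth = domainTruth,
       locTruth = if (length(locTruth)) do.call(rbind, locTruth) else
         data.frame(gene_id = character(0), loc1 = character(0),
                    loc2 = character(0)))
}

#' Write a full synthetic bundle to disk
#'
#' Emits the formats the analysis consumes: genome FASTA, annotation as
#' both GFF3 and assembler-style GTF, expression TSV, an aligner-dialect
#' junction table, domain and localization TSVs, and the ground truth as
#' JSON. Identical configs produce byte-identical files.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths plus the
#'   in-memory objects.
#' @export
simulateBundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- simulateGeneModels(cfg)
  expr <- simulateExpression(cfg, gm$genes)
  aux <- simulateAuxTables(cfg, gm$genes, gm$genome)
  p <- function(f) file.path(dir, f)

  Biostrings::writeXStringSet(gm$genome, p("genome.fa"))
  writeAnnotation(gm$genes, p("annotation.gff3"))
  .writeGtf(gm$genes, p("annotation.gtf"))
  write.table(expr$profiles, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jt <- aux$junctions
  jdf <- data.frame(chrom = jt$chrom, first = jt$first, last = jt$last,
                    strand = ifelse(jt$strand == "+", 1L, 2L),
                    motif = 0L, annotated = 0L, unique = jt$count,
                    multi = 0L, overhang = 20L)
  write.table(jdf, p("junctions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(aux$domainHits, p("domains.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(aux$locScores, p("localization.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(events = gm$truth, tcs_genes = expr$tcsGenes,
                domain_change = as.list(aux$domainTruth),
                loc_edges = aux$locTruth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(paths = vapply(c("genome.fa", "annotation.gff3",
                                  "annotation.gtf", "expression.tsv",
                                  "junctions.tsv", "domains.tsv",
                                  "localization.tsv", "truth.json"),
                                p, character(1)),
                 genes = gm$genes, genome = gm$genome, truth = gm$truth,
                 expression = expr, aux = aux))
}

.writeGtf <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in genes) for (tx in g@transcripts)
    for (i in seq_len(nrow(tx@exons)))
      writeLines(paste(g@chrom, "consplice", "exon",
                       tx@exons[i, 1L] + 1L, tx@exons[i, 2L], ".",
                       g@strand, ".",
                       sprintf('gene_id "%s"; transcript_id "%s";',
                               g@id, tx@id), sep = "\t"), con)
  invisible(path)
}

#' Precision and recall of planted-event recovery
#'
#' Matches called events against the generator's ground truth on
#' (gene, event type, genomic interval).
#'
#' @param called events data.frame (e.g. rbind of [callGeneEvents()]).
#' @param truth ground-truth events from [simulateGeneModels()].
#' @return list `precision`, `recall`, `n_called`, `n_truth`.
#' @export
evaluateEventRecovery <- function(called, truth) {
  keyC <- paste(called$gene_id, called$etype, called$start, called$end)
  keyT <- paste(truth$gene_id, truth$etype, truth$start, truth$end)
  tp <- sum(keyC %in% keyT)
  list(precision = if (length(keyC)) tp / length(keyC) else NA_real_,
       recall = if (length(keyT)) sum(keyT %in% keyC) / length(keyT) else NA_real_,
       n_called = length(keyC), n_truth = length(keyT))
}
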