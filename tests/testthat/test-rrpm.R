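makeGenome <- function(len = 5000L, seed = 1L) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(randomDna(len))
  names(seqs) <- "chrZ"
  seqs
}

test_that("fragmentation yields one fragment per gene at the gene span", {
  genome <- makeGenome()
  g1 <- makeGene("g1", at = 1000L)
  g2 <- makeGene("g2", at = 2000L)
  fr <- fragmentGenome(list(g1, g2), genome)
  expect_length(fr$fragments, 2L)
  expect_equal(fr$fragments$g1$offset, 1000L)
  expect_equal(fr$fragments$g1$length, g1@end - g1@start)
  expect_equal(nchar(fr$fragments$g1$sequence), fr$fragments$g1$length)
  ## overlapping genes each get their full span independently
  g3 <- makeGene("g3", at = 1200L)
  fr2 <- fragmentGenome(list(g1, g3), genome)
  expect_equal(substr(fr2$fragments$g1$sequence, 201, 250),
               substr(fr2$fragments$g3$sequence, 1, 50))
})

test_that("fragment sequences keep genome orientation regardless of strand", {
  genome <- makeGenome()
  gm <- makeGene("gm", at = 500L, strand = "-")
  fr <- fragmentGenome(list(gm), genome)
  expect_equal(fr$fragments$gm$sequence,
               as.character(Biostrings::subseq(genome[[1]], 501, gm@end)))
})

test_that("gene span exceeding the chromosome is a bounds error", {
  genome <- makeGenome(len = 600L)
  g <- makeGene("gX", at = 200L)      # ends past 600
  expect_error(fragmentGenome(list(g), genome), "bounds")
})

test_that("projection shifts by the offset and round-trips", {
  frag <- list(gene_id = "g1", chrom = "chr9", offset = 1000L, length = 1000L,
               strand = "+", sequence = "")
  tx <- transcript("t", "g1", "frag", "+", rbind(c(50, 150), c(300, 400)))
  p <- projectToGenome(tx, frag)
  expect_equal(unname(exons(p)), cbind(c(1050L, 1300L), c(1150L, 1400L)))
  expect_equal(p@chrom, "chr9")
  ## identity at offset 0
  frag0 <- frag; frag0$offset <- 0L; frag0$chrom <- "frag"
  expect_equal(unname(exons(projectToGenome(tx, frag0))), unname(exons(tx)))
  ## lengths and gaps preserved on random fixtures
  set.seed(5)
  for (i in 1:10) {
    off <- sample(0:10000, 1)
    fragR <- list(gene_id = "g", chrom = "c", offset = off, length = 5000L,
                  strand = "+", sequence = "")
    s <- sort(sample(0:4000, 4)); ex <- cbind(s, s + sample(10:100, 4))
    ex <- ex[ex[, 2] <= 5000, , drop = FALSE]
    ex <- ex[c(TRUE, ex[-1, 1] >= head(ex[, 2], -1)), , drop = FALSE]
    txr <- transcript("t", "g", "f", "+", ex)
    pr <- projectToGenome(txr, fragR)
    expect_equal(exons(pr)[, 2] - exons(pr)[, 1], exons(txr)[, 2] - exons(txr)[, 1])
    expect_equal(unname(exons(pr) - off), unname(exons(txr)))
  }
})

test_that("transcripts exceeding the fragment signal a projection error", {
  frag <- list(gene_id = "g1", chrom = "c", offset = 0L, length = 100L,
               strand = "+", sequence = "")
  tx <- transcript("t", "g1", "f", "+", rbind(c(50, 150)))
  expect_error(projectToGenome(tx, frag), "projection error")
})

test_that("read containment accepts spliced reads inside the fragment only", {
  expect_true(alignmentWithinFragment(0L, "100M", 100L))
  expect_false(alignmentWithinFragment(1L, "100M", 100L))
  expect_true(alignmentWithinFragment(10L, "40M200N40M", 300L))
  expect_false(alignmentWithinFragment(10L, "40M500N40M", 300L))
})

test_that("transcript filters apply strand, support, then ORF", {
  ## genome carrying a long ORF across the gene body
  orf <- paste(c("ATG", rep("GCT", 60), "TAA"), collapse = "")
  seqs <- Biostrings::DNAStringSet(paste0(randomDna(100), orf, randomDna(100)))
  names(seqs) <- "chrZ"
  gene <- geneModel("g", "chrZ", "+", 100L, 100L + nchar(orf),
                    list(transcript("g.t0", "g", "chrZ", "+",
                                    rbind(c(100, 100 + nchar(orf))))))
  txOk <- transcript("g.ok", "g", "chrZ", "+", rbind(c(100, 200), c(230, 286)))
  txStrand <- transcript("g.rev", "g", "chrZ", "-", rbind(c(100, 286)))
  txNoExpr <- transcript("g.ne", "g", "chrZ", "+", rbind(c(100, 286)))
  txShort <- transcript("g.short", "g", "chrZ", "+", rbind(c(150, 180)))
  support <- list(
    expressed = c(g.ok = TRUE, g.rev = TRUE, g.ne = FALSE, g.short = TRUE,
                  g.badj = TRUE),
    junctions = data.frame(chrom = "chrZ", start = 200L, end = 230L,
                           count = 5L))
  res <- filterTranscripts(gene, list(txOk, txStrand, txNoExpr, txShort),
                           support, seqs)
  expect_equal(res$reasons[["g.ok"]], "kept")
  expect_equal(res$reasons[["g.rev"]], "strand")
  expect_equal(res$reasons[["g.ne"]], "support")
  expect_equal(res$reasons[["g.short"]], "orf")
  expect_length(transcripts(res$gene), 1L)

  ## unsupported junction count 0 -> support rejection
  support0 <- support
  support0$junctions$count <- 0L
  res0 <- filterTranscripts(gene, list(txOk), support0, seqs)
  expect_equal(res0$reasons[["g.ok"]], "support")
  expect_equal(res0$flag, "not_expressed_or_unsupported")

  ## junction missing from the table is an error, not a silent pass
  txBadJ <- transcript("g.badj", "g", "chrZ", "+", rbind(c(100, 150), c(170, 286)))
  expect_error(filterTranscripts(gene, list(txBadJ), support, seqs),
               "missing-support")
})

test_that("the ORF filter threshold is inclusive of the stop codon", {
  ## ORF lengths are codon multiples: 39 nt sits below the 40 nt floor,
  ## 42 nt is the smallest passing length
  mk <- function(orfNt) {
    ncod <- orfNt / 3
    paste(c("ATG", rep("GCT", ncod - 2), "TAA"), collapse = "")
  }
  o39 <- longestOrf(mk(39L)); o42 <- longestOrf(mk(42L))
  expect_equal(o39$length_nt, 39L)
  expect_false(o39$length_nt >= 40L)
  expect_true(o42$length_nt >= 40L)
})

test_that("filtering is idempotent", {
  orf <- paste(c("ATG", rep("GCT", 60), "TAA"), collapse = "")
  seqs <- Biostrings::DNAStringSet(paste0(randomDna(100), orf, randomDna(100)))
  names(seqs) <- "chrZ"
  gene <- geneModel("g", "chrZ", "+", 100L, 100L + nchar(orf),
                    list(transcript("g.t0", "g", "chrZ", "+",
                                    rbind(c(100, 100 + nchar(orf))))))
  cand <- list(transcript("g.a", "g", "chrZ", "+", rbind(c(100, 286))),
               transcript("g.b", "g", "chrZ", "-", rbind(c(100, 286))))
  support <- list(expressed = c(g.a = TRUE, g.b = TRUE),
                  junctions = data.frame(chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         count = integer(0)))
  r1 <- filterTranscripts(gene, cand, support, seqs)
  r2 <- filterTranscripts(gene, transcripts(r1$gene), support, seqs)
  expect_equal(vapply(transcripts(r2$gene), txId, character(1)),
               vapply(transcripts(r1$gene), txId, character(1)))
})
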