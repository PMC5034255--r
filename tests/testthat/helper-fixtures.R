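## Shared fixture builders; everything is constructed in code at test time.

## A plus-strand gene with n equal exons of width w separated by introns of
## width iw, starting at `at`.
makeGene <- function(id = "g1", n = 4L, w = 100L, iw = 50L, at = 0L,
                     strand = "+", chrom = "chrZ", txIds = "t1",
                     dropExon = NULL) {
  starts <- at + (seq_len(n) - 1L) * (w + iw)
  ex <- cbind(starts, starts + w)
  txs <- lapply(seq_along(txIds), function(i) {
    keep <- ex
    if (!is.null(dropExon) && !is.na(dropExon[i]))
      keep <- ex[-dropExon[i], , drop = FALSE]
    transcript(txIds[i], id, chrom, strand, keep)
  })
  geneModel(id, chrom, strand, min(ex[, 1]), max(ex[, 2]), txs)
}

## Random valid GeneModel for round-trip property tests.
randomGeneModel <- function(id) {
  n <- sample(2:6, 1)
  w <- sample(50:200, n, replace = TRUE)
  iw <- sample(30:120, n - 1, replace = TRUE)
  at <- sample(0:5000, 1)
  strand <- sample(c("+", "-"), 1)
  starts <- at + cumsum(c(0L, head(w, -1) + iw))
  ex <- cbind(starts, starts + w)
  nTx <- sample(1:3, 1)
  txs <- lapply(seq_len(nTx), function(i) {
    keep <- sort(sample(seq_len(n), max(2, n - sample(0:1, 1))))
    transcript(sprintf("%s.t%d", id, i), id, "chr1", strand,
               ex[keep, , drop = FALSE])
  })
  geneModel(id, "chr1", strand, min(ex[, 1]), max(ex[, 2]), txs)
}

expect_same_genes <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    ga <- a[[i]]; gb <- b[[i]]
    expect_equal(geneId(ga), geneId(gb))
    expect_equal(ga@chrom, gb@chrom)
    expect_equal(ga@strand, gb@strand)
    expect_equal(c(ga@start, ga@end), c(gb@start, gb@end))
    ta <- transcripts(ga); tb <- transcripts(gb)
    expect_equal(sort(vapply(ta, txId, character(1))),
                 sort(vapply(tb, txId, character(1))))
    tb <- tb[match(vapply(ta, txId, character(1)),
                   vapply(tb, txId, character(1)))]
    for (j in seq_along(ta)) {
      expect_equal(unname(exons(ta[[j]])), unname(exons(tb[[j]])))
      expect_equal(unname(cds(ta[[j]])), unname(cds(tb[[j]])))
    }
  }
}

## Independent brute-force ORF oracle: every (frame, ATG) pair, scan codon
## by codon to the first stop.
bruteForceOrf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- NULL
  for (start in seq_len(max(0, n - 5))) {
    if (substr(s, start, start + 2) != "ATG") next
    pos <- start + 3
    while (pos + 2 <= n) {
      cod <- substr(s, pos, pos + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- pos + 3 - start
        if (is.null(best) || len > best$length_nt ||
            (len == best$length_nt && start - 1 < best$tx_offset))
          best <- list(tx_offset = start - 1, length_nt = len)
        break
      }
      pos <- pos + 3
    }
  }
  best
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
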