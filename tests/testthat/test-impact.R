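## Two isoforms sharing a coding window, for domain re-indexing tests.
makeCodingPair <- function() {
  orf <- paste(c("ATG", rep("GCT", 80), "TAA"), collapse = "")  # 246 nt
  seqs <- Biostrings::DNAStringSet(paste0(randomDna(50), orf, randomDna(50)))
  names(seqs) <- "c"
  t1 <- transcript("t1", "g", "c", "+", rbind(c(50, 296)))
  t2 <- transcript("t2", "g", "c", "+", rbind(c(50, 296)))
  list(genome = seqs,
       txs = lapply(list(t1, t2), function(tx) computeCdsUtrs(tx, seqs)$tx))
}

test_that("domain hits re-index by gene location", {
  cp <- makeCodingPair()
  hits <- data.frame(
    transcript_id = c("t1", "t1", "t2"),
    domain_id = c("IPR000001", "IPR000001", "IPR000001"),
    aa_start = c(2L, 60L, 3L), aa_end = c(20L, 75L, 21L),
    stringsAsFactors = FALSE)
  out <- reindexDomains(hits, cp$txs)
  ## same accession at two gene-disjoint locations -> distinct ids
  expect_false(out$located_id[1] == out$located_id[2])
  ## overlapping hits in two isoforms share one id
  expect_equal(out$located_id[1], out$located_id[3])
  expect_equal(sort(unique(out$located_id)),
               c("IPR000001#1", "IPR000001#2"))
  ## single hit gets index 1
  one <- reindexDomains(hits[1, ], cp$txs)
  expect_equal(one$located_id, "IPR000001#1")
  ## a hit on a CDS-less transcript is an error
  noCds <- transcript("t1", "g", "c", "+", rbind(c(50, 296)))
  expect_error(reindexDomains(hits[1, ], list(noCds, cp$txs[[2]])),
               "without CDS")
})

test_that("domain change classification follows the set rules", {
  expect_equal(classifyDomainChange(list(c("A#1"), c("A#1"))), "identical")
  expect_equal(classifyDomainChange(list(c("A#1", "B#1"), c("A#1"))),
               "gain_loss")
  expect_equal(classifyDomainChange(list(c("A#1"), c("B#1"))), "exchange")
  expect_equal(classifyDomainChange(list(character(0), character(0))),
               "unannotated")
  expect_equal(classifyDomainChange(list(character(0), c("A#1"))),
               "gain_loss")
  ## permutation invariance and mutual exclusivity
  set.seed(41)
  pool <- paste0(LETTERS[1:5], "#1")
  for (i in 1:25) {
    sets <- lapply(1:3, function(j) sample(pool, sample(0:4, 1)))
    got <- classifyDomainChange(sets)
    for (p in 1:3)
      expect_equal(classifyDomainChange(sample(sets)), got)
    expect_length(got, 1L)
  }
})

test_that("localization changes become symmetric edges", {
  expect_equal(classifyLocalizationChange(c("mitochondrion",
                                            "mitochondrion"))$status,
               "uniform")
  r <- classifyLocalizationChange(c("extracellular", "mitochondrion"))
  expect_equal(r$status, "changed")
  expect_equal(nrow(r$edges), 1L)
  expect_setequal(unlist(r$edges), c("extracellular", "mitochondrion"))
  expect_equal(classifyLocalizationChange(c(NA, NA))$status, "no_prediction")
  ## k distinct locations -> at most C(k,2) edges
  r3 <- classifyLocalizationChange(c("a", "b", "c", "b"))
  expect_lte(nrow(r3$edges), choose(3, 2))
})

test_that("localization score filtering keeps >= 17 and the best location", {
  expect_equal(filterLocalization(c(extracellular = 18, nucleus = 3)),
               "extracellular")
  expect_equal(filterLocalization(c(extracellular = 17)), "extracellular")
  expect_true(is.na(filterLocalization(c(extracellular = 16.9))))
})

test_that("functional group rules apply the annotation constants", {
  pr <- list(signal_peptide = TRUE, targeting_loc = "M",
             tm_domain_count = 0L, extracellular_score = 18)
  expect_setequal(
    assignFunctionalGroups(c("IPR001128"), "GO:0008152", pr,
                           tfDomainList = "IPR999999", cazyme = TRUE),
    c("P450", "metabolic", "secreted", "cazyme"))
  ## extracellular score exactly 17 is not secreted (strict >)
  pr17 <- pr; pr17$extracellular_score <- 17
  expect_false("secreted" %in%
               assignFunctionalGroups(character(0), character(0), pr17))
  ## two or more transmembrane domains block secretion
  prTm <- pr; prTm$tm_domain_count <- 2L
  expect_false("secreted" %in%
               assignFunctionalGroups(character(0), character(0), prTm))
  ## TF requires a listed accession
  expect_equal(assignFunctionalGroups("IPR000007", character(0),
                                      list(signal_peptide = FALSE),
                                      tfDomainList = "IPR000007"), "TF")
  ## candidate without the downstream predictor columns errors
  prBad <- list(signal_peptide = TRUE, targeting_loc = "S")
  expect_error(assignFunctionalGroups(character(0), character(0), prBad),
               "secretion candidate")
})

test_that("hypergeometric enrichment matches exhaustive counting", {
  bruteTail <- function(N, K, n, k) {
    tot <- choose(N, n)
    sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), numeric(1))) / tot
  }
  set.seed(55)
  for (i in 1:25) {
    N <- sample(8:30, 1)
    universe <- sprintf("u%02d", 1:N)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    grp <- sample(universe, K); as_ <- sample(universe, n)
    e <- groupEnrichment(as_, grp, universe)
    expect_equal(e$p_value,
                 bruteTail(N, K, n, length(intersect(as_, grp))),
                 tolerance = 1e-12)
  }
  ## the worked case: universe 100, group 10, AS 50, overlap forced to 10
  universe <- sprintf("u%03d", 1:100)
  grp <- universe[1:10]
  as_ <- universe[1:50]
  e <- groupEnrichment(as_, grp, universe)
  expect_equal(e$overlap, 10L)
  expect_equal(e$p_value, choose(10, 10) * choose(90, 40) / choose(100, 50),
               tolerance = 1e-12)
  ## zero overlap has tail probability 1
  e0 <- groupEnrichment(universe[11:20], universe[1:10], universe)
  expect_gte(e0$p_value, stats::phyper(-1, 10, 90, 10, lower.tail = FALSE) - 1)
  expect_equal(groupEnrichment(universe[1:10], universe[11:20],
                               universe)$overlap, 0L)
  expect_error(groupEnrichment("a", "a", character(0)), "empty universe")
})

test_that("enrichment tables carry BH-adjusted p-values", {
  universe <- sprintf("u%03d", 1:60)
  groups <- list(big = universe[1:20], small = universe[21:25])
  tab <- groupEnrichmentTable(universe[1:30], groups, universe)
  expect_equal(tab$p_adj, stats::p.adjust(tab$p_value, "BH"))
  expect_equal(tab$group, c("big", "small"))
})

test_that("planted domain and localization changes are recovered", {
  cfg <- simulationConfig(seed = 23, n_genes = 100, noise_sd = 0,
                          fraction_as_genes = 0.5,
                          loc_change_mix = c(no_prediction = .2,
                                             uniform = .3, changed = .5))
  gm <- simulateGeneModels(cfg)
  aux <- simulateAuxTables(cfg, gm$genes, gm$genome)
  byGene <- split(aux$domainHits, aux$domainHits$gene_id)
  txByGene <- setNames(lapply(gm$genes, transcripts),
                       vapply(gm$genes, geneId, character(1)))
  expect_gt(length(aux$domainTruth), 20L)
  for (gid in names(aux$domainTruth)) {
    txs <- lapply(txByGene[[gid]], function(tx)
      computeCdsUtrs(tx, gm$genome)$tx)
    located <- reindexDomains(byGene[[gid]], txs)
    sets <- lapply(vapply(txs, txId, character(1)), function(id)
      located$located_id[located$transcript_id == id])
    expect_equal(classifyDomainChange(sets), unname(aux$domainTruth[gid]))
  }
  ## localization edges
  expect_gt(nrow(aux$locTruth), 5L)
  for (r in seq_len(nrow(aux$locTruth))) {
    lg <- aux$locScores[aux$locScores$gene_id == aux$locTruth$gene_id[r], ]
    perTx <- vapply(unique(lg$transcript_id), function(id)
      filterLocalization(setNames(lg$score[lg$transcript_id == id],
                                  lg$location[lg$transcript_id == id])),
      character(1))
    cl <- classifyLocalizationChange(perTx)
    expect_equal(cl$status, "changed")
    expect_true(paste(aux$locTruth$loc1[r], aux$locTruth$loc2[r]) %in%
                paste(cl$edges$loc1, cl$edges$loc2))
  }
})
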