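test_that("single-transcript consensus is the transcript itself", {
  g <- makeGene("g1", n = 3L)
  cons <- buildConsensus(g)
  expect_length(cons@groups, 3L)
  expect_equal(t(vapply(cons@groups, `[[`, integer(2), "rep")),
               unname(exons(transcripts(g)[[1]])))
})

test_that("retained-intron exons are excluded from the consensus", {
  t1 <- transcript("t1", "g", "c", "+", rbind(c(0, 100), c(200, 300)))
  t2 <- transcript("t2", "g", "c", "+", rbind(c(0, 300)))
  g <- geneModel("g", "c", "+", 0L, 300L, list(t1, t2))
  cons <- buildConsensus(g)
  expect_length(cons@groups, 2L)
  expect_equal(cons@groups[[1]]$rep, c(0L, 100L))
  expect_equal(cons@groups[[2]]$rep, c(200L, 300L))
  ## no representative contains any observed junction
  for (grp in cons@groups)
    expect_false(grp$rep[1] < 100L && 200L < grp$rep[2])
})

test_that("representative boundaries follow the majority vote", {
  t1 <- transcript("t1", "g", "c", "+", rbind(c(0, 100), c(200, 300)))
  t2 <- transcript("t2", "g", "c", "+", rbind(c(0, 120), c(200, 300)))
  t3 <- transcript("t3", "g", "c", "+", rbind(c(0, 100), c(200, 300)))
  g <- geneModel("g", "c", "+", 0L, 300L, list(t1, t2, t3))
  cons <- buildConsensus(g)
  expect_equal(cons@groups[[1]]$rep, c(0L, 100L))     # 2 votes vs 1
  expect_equal(nrow(cons@groups[[1]]$variants), 2L)
  expect_setequal(cons@groups[[1]]$members, c("t1", "t2", "t3"))
})

test_that("nested intron retentions resolve by iteration", {
  t1 <- transcript("t1", "g", "c", "+",
                   rbind(c(0, 100), c(200, 300), c(400, 500)))
  t2 <- transcript("t2", "g", "c", "+", rbind(c(0, 300), c(400, 500)))
  t3 <- transcript("t3", "g", "c", "+", rbind(c(0, 500)))
  g <- geneModel("g", "c", "+", 0L, 500L, list(t1, t2, t3))
  cons <- buildConsensus(g)
  expect_length(cons@groups, 3L)
  expect_equal(t(vapply(cons@groups, `[[`, integer(2), "rep")),
               unname(exons(t1)))
})

test_that("exon alignment reports fusions, absences and anomalies", {
  t1 <- transcript("t1", "g", "c", "+",
                   rbind(c(0, 100), c(200, 300), c(400, 500)))
  g <- geneModel("g", "c", "+", 0L, 500L, list(t1))
  cons <- buildConsensus(g)

  exact <- alignExons(t1, cons)
  expect_equal(exact$map, list(1L, 2L, 3L))
  expect_length(exact$anomalies, 0L)

  fused <- transcript("t2", "g", "c", "+", rbind(c(0, 300), c(400, 500)))
  af <- alignExons(fused, cons)
  expect_equal(af$map[[1]], c(1L, 2L))

  skipping <- transcript("t3", "g", "c", "+", rbind(c(0, 100), c(400, 500)))
  as_ <- alignExons(skipping, cons)
  expect_false(as_$present[2])

  stray <- transcript("t4", "g", "c", "+", rbind(c(120, 180), c(400, 500)))
  expect_length(alignExons(stray, cons)$anomalies, 1L)
})

test_that("primitive events: identity, IR interval, boundary deltas", {
  t1 <- transcript("t1", "g", "c", "+",
                   rbind(c(0, 100), c(200, 300), c(400, 500)))
  g1 <- geneModel("g", "c", "+", 0L, 500L, list(t1))
  cons <- buildConsensus(g1)
  expect_equal(nrow(callPrimitiveEvents(t1, cons)), 0L)

  fused <- transcript("t2", "g", "c", "+", rbind(c(0, 300), c(400, 500)))
  ir <- callPrimitiveEvents(fused, cons)
  expect_equal(ir$etype, "IR")
  expect_equal(c(ir$start, ir$end, ir$delta_nt), c(100L, 200L, 100L))

  ## 5' extension of an internal exon on the plus strand
  ext <- transcript("t3", "g", "c", "+",
                    rbind(c(0, 100), c(180, 300), c(400, 500)))
  ## a duplicate of t1 makes (200,300) the majority representative
  cons3 <- buildConsensus(geneModel("g", "c", "+", 0L, 500L,
                                    list(t1, transcript("t1b", "g", "c", "+",
                                                        exons(t1)), ext)))
  a5 <- callPrimitiveEvents(ext, cons3)
  expect_equal(a5$etype, "A5SS")
  expect_equal(c(a5$start, a5$end, a5$delta_nt), c(180L, 200L, 20L))

  ## the same extension on the minus strand is the exon's 3' end
  tm <- transcript("m1", "g", "c", "-",
                   rbind(c(0, 100), c(200, 300), c(400, 500)))
  em <- transcript("m3", "g", "c", "-",
                   rbind(c(0, 100), c(180, 300), c(400, 500)))
  consM <- buildConsensus(geneModel("g", "c", "-", 0L, 500L,
                                    list(tm, transcript("m1b", "g", "c", "-",
                                                        exons(tm)), em)))
  a3 <- callPrimitiveEvents(em, consM)
  expect_equal(a3$etype, "A3SS")
})

test_that("outer boundaries of terminal exons are never boundary events", {
  t1 <- transcript("t1", "g", "c", "+",
                   rbind(c(0, 100), c(200, 300), c(400, 500)))
  tShift <- transcript("t2", "g", "c", "+",
                       rbind(c(20, 100), c(200, 300), c(400, 480)))
  cons <- buildConsensus(geneModel("g", "c", "+", 0L, 500L,
                                   list(t1, transcript("t1b", "g", "c", "+",
                                                       exons(t1)), tShift)))
  ev <- callPrimitiveEvents(tShift, cons)
  expect_equal(nrow(ev), 0L)
})

test_that("MXE calls match brute-force pair co-occurrence enumeration", {
  bruteMxe <- function(gene, cons) {
    nG <- length(cons@groups)
    pres <- lapply(transcripts(gene), function(tx)
      which(alignExons(tx, cons)$present))
    pairs <- list()
    if (nG >= 2) for (i in 1:(nG - 1)) for (j in (i + 1):nG) {
      seenI <- any(vapply(pres, function(p) i %in% p, logical(1)))
      seenJ <- any(vapply(pres, function(p) j %in% p, logical(1)))
      together <- any(vapply(pres, function(p) all(c(i, j) %in% p), logical(1)))
      if (seenI && seenJ && !together) pairs <- c(pairs, list(c(i, j)))
    }
    pairs
  }
  set.seed(99)
  cfg <- simulationConfig(seed = 99, n_genes = 60, noise_sd = 0,
                          event_mix = c(IR = .1, A5SS = .1, A3SS = .1,
                                        ES = .2, MXE = .5),
                          fraction_as_genes = 0.6,
                          exons_per_gene = c(4L, 6L))
  gm <- simulateGeneModels(cfg)
  checked <- 0L
  for (g in gm$genes) {
    cons <- buildConsensus(g)
    if (length(cons@groups) > 6L) next
    want <- bruteMxe(g, cons)
    got <- callCompositeEvents(g, cons)
    got <- got[got$etype == "MXE", , drop = FALSE]
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      wantIv <- t(vapply(want, function(p)
        c(cons@groups[[p[1]]]$rep[1], cons@groups[[p[2]]]$rep[2]), integer(2)))
      expect_setequal(paste(got$start, got$end),
                      paste(wantIv[, 1], wantIv[, 2]))
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 30L)
})

test_that("three distinct boundaries make a multiple-alternative-site event", {
  t1 <- transcript("t1", "g", "c", "+",
                   rbind(c(0, 100), c(200, 300), c(400, 500)))
  t2 <- transcript("t2", "g", "c", "+",
                   rbind(c(0, 100), c(210, 300), c(400, 500)))
  t3 <- transcript("t3", "g", "c", "+",
                   rbind(c(0, 100), c(220, 300), c(400, 500)))
  g <- geneModel("g", "c", "+", 0L, 500L, list(t1, t2, t3))
  comp <- callCompositeEvents(g, buildConsensus(g))
  ma <- comp[comp$etype == "MA5SS", , drop = FALSE]
  expect_equal(nrow(ma), 1L)
  expect_equal(c(ma$start, ma$end), c(200L, 220L))
  expect_equal(nrow(comp[comp$etype == "MA3SS", , drop = FALSE]), 0L)
})

test_that("event context splits coding from UTR with frame arithmetic", {
  tx <- transcript("t", "g", "c", "+", rbind(c(0, 1000)), cds = c(50L, 950L))
  ev <- consplice:::.eventRow("g", "t", "IR", "c", 100L, 200L, "+", 100L)
  out <- classifyEventContext(ev, tx)
  expect_equal(out$region, "coding")
  expect_false(out$frame_neutral)          # 100 %% 3 != 0

  ev81 <- consplice:::.eventRow("g", "t", "IR", "c", 100L, 181L, "+", 81L)
  expect_true(classifyEventContext(ev81, tx)$frame_neutral)

  ## event entirely in the 3' UTR: zero coding nt, frame-neutral
  evU <- consplice:::.eventRow("g", "t", "ES", "c", 960L, 990L, "+", -30L)
  outU <- classifyEventContext(evU, tx)
  expect_equal(outU$region, "utr")
  expect_true(outU$frame_neutral)

  ## no CDS at all -> UTR by definition
  txN <- transcript("t", "g", "c", "+", rbind(c(0, 1000)))
  expect_equal(classifyEventContext(ev, txN)$region, "utr")
})

test_that("three-level counting reproduces the worked examples", {
  ## two of three transcripts skip the same third exon: two events,
  ## two transcripts, one gene
  g <- makeGene("gA", n = 4L, txIds = c("t1", "t2", "t3"),
                dropExon = c(NA, 3L, 3L))
  ev <- callGeneEvents(g)
  es <- ev[ev$etype == "ES", ]
  expect_equal(nrow(es), 2L)
  expect_equal(countEvents(ev, "event")[2, "total"], 2L)
  expect_equal(countEvents(ev, "transcript")[2, "total"], 2L)
  expect_equal(countEvents(ev, "gene")[2, "total"], 1L)

  ## one transcript skipping two exons counts once at transcript level
  t1 <- transcript("t1", "gB", "c", "+",
                   rbind(c(0, 100), c(200, 300), c(400, 500), c(600, 700),
                         c(800, 900)))
  t2 <- transcript("t2", "gB", "c", "+",
                   rbind(c(0, 100), c(600, 700), c(800, 900)))
  gB <- geneModel("gB", "c", "+", 0L, 900L, list(t1, t2))
  evB <- callGeneEvents(gB)
  expect_equal(sum(evB$etype == "ES"), 2L)
  expect_equal(countEvents(evB, "transcript")[2, "total"], 1L)

  ## two transcripts skipping different exons count as one gene-level event
  gC <- makeGene("gC", n = 5L, txIds = c("t1", "t2", "t3"),
                 dropExon = c(NA, 2L, 4L))
  evC <- callGeneEvents(gC)
  expect_equal(sum(evC$etype == "ES"), 2L)
  expect_equal(countEvents(evC, "gene")[2, "total"], 1L)
})

test_that("counts are hierarchical and regions sum to totals", {
  set.seed(3)
  cfg <- simulationConfig(seed = 3, n_genes = 80, noise_sd = 0,
                          event_mix = c(IR = .3, A5SS = .2, A3SS = .2,
                                        ES = .2, MXE = .1),
                          fraction_as_genes = 0.5)
  gm <- simulateGeneModels(cfg)
  ev <- do.call(rbind, lapply(gm$genes, callGeneEvents, genome = gm$genome))
  cE <- countEvents(ev, "event"); cT <- countEvents(ev, "transcript")
  cG <- countEvents(ev, "gene")
  expect_true(all(cE$total >= cT$total))
  expect_true(all(cT$total >= cG$total))
  for (cc in list(cE, cT, cG))
    expect_equal(cc$coding + cc$utr, cc$total)
  expect_true(all(ev$region %in% c("coding", "utr")))
})

test_that("isolated genes require strictly zero-covered flanks", {
  g1 <- makeGene("g1"); g2 <- makeGene("g2", at = 2000L)
  g3 <- makeGene("g3", at = 4000L)
  cov <- list(
    g1 = list(left = NULL, right = rep(0, 50)),            # chromosome-terminal
    g2 = list(left = rep(0, 50), right = c(rep(0, 49), 1)),
    g3 = list(left = rep(0, 10), right = rep(0, 10)))
  sel <- selectIsolatedGenes(list(g1, g2, g3), cov)
  expect_setequal(sel, c("g1", "g3"))
  expect_error(selectIsolatedGenes(list(makeGene("g4")), cov), "g4")
  expect_length(selectIsolatedGenes(list(), cov), 0L)
})
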