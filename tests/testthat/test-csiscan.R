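test_that("gap-free alignments contain no indel blocks", {
  x <- msa(setNames(rep(randomProtein(50), 4), paste0("g", 1:4)))
  expect_equal(nrow(findIndelBlocks(x)), 0)
})

test_that("a single gapped run forms one maximal block", {
  rows <- c(g1 = "MKVLTPEW", g2 = "MKVLTPEW", g3 = "MKVL--EW")
  b <- findIndelBlocks(msa(rows))
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(5L, 6L))
  expect_identical(b$gapped[[1]], "g3")
  expect_setequal(b$residue[[1]], c("g1", "g2"))
})

test_that("block finding equals exhaustive enumeration on random alignments", {
  set.seed(131)
  for (trial in 1:60) {
    x <- randomAlignment(nrow = sample(3:12, 1), ncol = sample(20:120, 1),
                         nBlocks = sample(0:4, 1))
    got <- findIndelBlocks(x, minLen = 1, maxLen = 10)
    want <- bruteIndelBlocks(x, minLen = 1, maxLen = 10)
    expect_equal(got[c("start", "end")],
                 want[order(want$start), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("clade specificity follows the unanimity-and-contrast rules", {
  set.seed(141)
  fx <- blockFixture(nClade = 4, nOut = 9)
  b <- findIndelBlocks(fx$msa)[1, ]
  v <- classifyBlock(b, fx$seqGenome, fx$cladeMap, "target")
  expect_true(v$pass)
  expect_identical(v$indelType, "insertion")
  expect_length(v$exceptions, 0)

  # an isolated exception outside the clade: rejected at 0, reported at 1
  rows <- msaRows(fx$msa)
  ch <- strsplit(rows[["o09"]], "")[[1]]
  ch[41:42] <- strsplit(substr(rows[["c01"]], 41, 42), "")[[1]]
  rows[["o09"]] <- paste0(ch, collapse = "")
  x2 <- msa(rows, familyId = "F0001")
  b2 <- findIndelBlocks(x2)[1, ]
  v0 <- classifyBlock(b2, fx$seqGenome, fx$cladeMap, "target",
                      scanParams(maxExceptions = 0))
  expect_false(v0$pass)
  v1 <- classifyBlock(b2, fx$seqGenome, fx$cladeMap, "target",
                      scanParams(maxExceptions = 1))
  expect_true(v1$pass)
  expect_identical(v1$exceptions, "o09")

  # within-clade disagreement always fails, exceptions cannot rescue it
  fx3 <- blockFixture(cladeSplit = TRUE)
  b3 <- findIndelBlocks(fx3$msa)
  verdicts <- lapply(seq_len(nrow(b3)), function(k)
    classifyBlock(b3[k, ], fx3$seqGenome, fx3$cladeMap, "target",
                  scanParams(maxExceptions = 5)))
  expect_false(any(vapply(verdicts, `[[`, logical(1), "pass")))
})

test_that("missing clade homologues are tolerated only with two rows left", {
  set.seed(151)
  fx <- blockFixture(nClade = 3, nOut = 5)
  rows <- msaRows(fx$msa)[-1]   # c01 has no homologue
  x <- msa(rows, familyId = "F0001")
  b <- findIndelBlocks(x)[1, ]
  v <- classifyBlock(b, fx$seqGenome, fx$cladeMap, "target")
  expect_true(v$pass)
  expect_identical(v$missing, "c01")
  vno <- classifyBlock(b, fx$seqGenome, fx$cladeMap, "target",
                       scanParams(allowMissing = FALSE))
  expect_false(vno$pass)
  # only one clade row left: never a CSI
  x1 <- msa(msaRows(fx$msa)[-(1:2)], familyId = "F0001")
  b1 <- findIndelBlocks(x1)[1, ]
  expect_false(classifyBlock(b1, fx$seqGenome, fx$cladeMap,
                             "target")$pass)
})

test_that("flank conservation counts columns exactly and is sharp at four", {
  set.seed(161)
  full <- blockFixture()
  b <- findIndelBlocks(full$msa)[1, ]
  fc <- flankConservation(full$msa, b)
  expect_equal(c(fc$left, fc$right), c(40L, 40L))
  expect_true(fc$pass)

  three <- blockFixture(leftConserved = 3)
  b3 <- findIndelBlocks(three$msa)[1, ]
  fc3 <- flankConservation(three$msa, b3)
  expect_equal(fc3$left, 3L)
  expect_false(fc3$pass)

  four <- blockFixture(leftConserved = 4)
  b4 <- findIndelBlocks(four$msa)[1, ]
  fc4 <- flankConservation(four$msa, b4)
  expect_equal(fc4$left, 4L)
  expect_true(fc4$pass)
})

test_that("flank counts match a brute-force census on random alignments", {
  set.seed(171)
  for (trial in 1:20) {
    x <- randomAlignment(nrow = sample(3:8, 1), ncol = sample(90, 1) + 30,
                         nBlocks = 2)
    blocks <- findIndelBlocks(x)
    if (!nrow(blocks)) next
    params <- scanParams(conservedFraction = sample(c(1, 0.8), 1))
    for (k in seq_len(nrow(blocks))) {
      fc <- flankConservation(x, blocks[k, ], params)
      want <- bruteFlank(x, blocks$start[k], blocks$end[k], params)
      expect_equal(c(fc$left, fc$right), unname(want))
    }
  }
})

test_that("the scanner recovers planted indels and only for the right clade", {
  sim <- simulateProteomes(nFamilies = 30, seed = 181)
  plan <- data.frame(family_id = c("F0003", "F0011"),
                     clade = c("clade_A", "clade_B"),
                     indel_type = c("insertion", "deletion"),
                     length = c(2L, 1L), position = c(90L, 75L))
  pl <- plantCsis(sim, plan, seed = 182)
  recsA <- scanCladeCsis(pl$alignments, "clade_A", ps = pl$proteomes)
  expect_length(recsA, 1)
  expect_identical(recsA[[1]]@familyId, "F0003")
  expect_identical(recsA[[1]]@indelType, "insertion")
  expect_identical(recsA[[1]]@indelLength, 2L)
  manifestA <- truthRecords(pl$manifest)[[1]]
  expect_equal(recsA[[1]], manifestA)

  # the one-residue deletion case
  recsB <- scanCladeCsis(pl$alignments, "clade_B", ps = pl$proteomes)
  expect_length(recsB, 1)
  expect_identical(recsB[[1]]@indelType, "deletion")
  expect_identical(recsB[[1]]@indelLength, 1L)

  # scanning an uninvolved clade yields nothing
  recsC <- scanCladeCsis(pl$alignments, "clade_C", ps = pl$proteomes)
  expect_length(recsC, 0)
})

test_that("stricter parameters never add records", {
  sim <- simulateProteomes(nFamilies = 40, seed = 191)
  plan <- sampleCsiPlan(sim, n = 10, nMissing = 2, seed = 192)
  pl <- plantCsis(sim, plan, seed = 193)
  base <- unlist(lapply(unique(cladeMap(pl$proteomes)), function(cl)
    recordKeys(scanCladeCsis(pl$alignments, cl, ps = pl$proteomes))))
  stricter <- list(scanParams(minConservedFlank = 8),
                   scanParams(maxExceptions = 0),
                   scanParams(minConservedFlank = 6, maxIndelLen = 3))
  for (p in stricter) {
    keys <- unlist(lapply(unique(cladeMap(pl$proteomes)), function(cl)
      recordKeys(scanCladeCsis(pl$alignments, cl, ps = pl$proteomes,
                               params = p))))
    expect_true(all(keys %in% base))
  }
})

test_that("the validator accepts scan output and rejects tampered records", {
  set.seed(201)
  fx <- blockFixture()
  recs <- scanCladeCsis(list(fx$msa), "target", cladeMap = fx$cladeMap,
                        seqGenome = fx$seqGenome)
  expect_length(recs, 1)
  v <- validateCsi(fx$msa, recs[[1]], cladeMap = fx$cladeMap,
                   seqGenome = fx$seqGenome)
  expect_true(v$valid)

  tampered <- recs[[1]]
  tampered@blockEnd <- tampered@blockEnd + 1L
  tampered@indelLength <- tampered@indelLength + 1L
  vt <- validateCsi(fx$msa, tampered, cladeMap = fx$cladeMap,
                    seqGenome = fx$seqGenome)
  expect_false(vt$valid)
  expect_match(paste(vt$reasons, collapse = "; "), "block|length")
})
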