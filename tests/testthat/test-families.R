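test_that("pairwise identity and coverage behave on known pairs", {
  expect_equal(pairwiseIdentity("MKVLTPEW", "MKVLTPEW"),
               c(identity = 1, coverage = 1))
  # one substitution over four aligned columns
  expect_equal(pairwiseIdentity("MKVL", "MKIL")[["identity"]], 0.75)
  # 'X' never counts as a match
  expect_lt(pairwiseIdentity("MKXL", "MKXL")[["identity"]], 1)
})

test_that("identity/coverage agree with exhaustive alignment on a nested pair", {
  # brute force over all global alignments of MKVL vs MK: the optimum aligns
  # MK to MK, so both-residue columns cover the shorter sequence entirely
  brute <- enumGlobalAlign("MKVL", "MK")
  stats <- lapply(brute$aligns, function(al) {
    both <- al$a != "-" & al$b != "-"
    c(identity = sum(both & al$a == al$b) / sum(both),
      coverage = sum(both) / 2)
  })
  got <- pairwiseIdentity("MKVL", "MK")
  expect_true(any(vapply(stats, function(s)
    isTRUE(all.equal(unname(s), unname(got))), logical(1))))
  expect_equal(got[["coverage"]], 1)
})

test_that("greedy clustering groups homologues and separates strangers", {
  set.seed(21)
  shared <- randomProtein(120)
  ps <- tinyProteomeSet(
    c(a1 = shared, b1 = shared,
      a2 = randomProtein(200), b2 = randomProtein(200)),
    genomes = c(a1 = "gA", b1 = "gB", a2 = "gA", b2 = "gB"),
    clades = c(gA = "X", gB = "Y"))
  fs <- clusterGreedy(ps)
  m <- members(fs)
  # identical copies join one family of two
  famOfCopy <- m$family_id[m$seq_id %in% c("a1", "b1")]
  expect_equal(length(unique(famOfCopy)), 1)
  # unrelated random sequences stay singletons
  expect_equal(length(unique(m$family_id)), 3)
  expect_lt(pairwiseIdentity(as.character(aaSequences(ps)[["a2"]]),
                             as.character(aaSequences(ps)[["b2"]]))[["identity"]],
            0.5)
})

test_that("every member meets the thresholds against its representative", {
  sim <- simulateProteomes(cladeSpec(c(A = 3, B = 3)), nFamilies = 4,
                           lengthRange = c(120, 160), seed = 31)
  fs <- clusterGreedy(sim$proteomes)
  m <- members(fs)
  seqs <- as.character(aaSequences(sim$proteomes))
  # brute-force re-check of the cached statistics on <= 30 sequences
  for (i in seq_len(nrow(m))) {
    rep <- representatives(fs)[[m$family_id[i]]]
    ic <- pairwiseIdentity(seqs[[m$seq_id[i]]], seqs[[rep]])
    expect_gte(ic[["identity"]], 0.5)
    expect_gte(ic[["coverage"]], 0.5)
    expect_equal(unname(ic[["identity"]]), m$rep_identity[i])
    expect_equal(unname(ic[["coverage"]]), m$rep_coverage[i])
  }
  # partition property: every sequence in exactly one family
  expect_setequal(m$seq_id, names(seqs))
  expect_false(anyDuplicated(m$seq_id) > 0)
  # recovered families equal generator truth
  trueFam <- sub("_.*$", "", m$seq_id)
  expect_equal(length(unique(paste(m$family_id, trueFam))),
               length(unique(trueFam)))
})

test_that("core selection applies the 80% prevalence rule exactly", {
  # a 38-genome universe: presence in 31 genomes passes, in 30 fails
  genomes <- sprintf("g%02d", 1:38)
  mk <- function(fam, n) data.frame(
    family_id = fam, seq_id = paste0(fam, "_", genomes[seq_len(n)]),
    genome_id = genomes[seq_len(n)], seq_length = 100L,
    rep_identity = 1, rep_coverage = 1)
  m <- rbind(mk("FAM0001", 31), mk("FAM0002", 30))
  reps <- setNames(c("FAM0001_g01", "FAM0002_g01"),
                   c("FAM0001", "FAM0002"))
  fs <- new("FamilySet", members = m, representatives = reps,
            nGenomesTotal = 38L,
            genomeReps = data.frame(family_id = character(),
                                    genome_id = character(),
                                    seq_id = character()))
  core <- selectCore(fs, prevalence = 0.8)
  expect_identical(familyIds(core), "FAM0001")   # 31/38 kept, 30/38 dropped
})

test_that("per-genome representative is the paralog closest to the family representative", {
  set.seed(41)
  rep <- randomProtein(150)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(r) sample(setdiff(AA20, r), 1), "")
    paste0(ch, collapse = "")
  }
  near <- mutate(rep, 12)   # ~92% identical
  far <- mutate(rep, 44)    # ~71% identical
  ps <- tinyProteomeSet(
    c(r1 = rep, p_near = near, p_far = far, o1 = rep),
    genomes = c(r1 = "gR", p_near = "gP", p_far = "gP", o1 = "gO"),
    clades = c(gR = "X", gP = "X", gO = "Y"))
  fs <- selectCore(clusterGreedy(ps), prevalence = 0.8)
  gr <- genomeReps(fs)
  expect_identical(gr$seq_id[gr$genome_id == "gP"], "p_near")
})

test_that("BLAST-derived families are single-linkage components", {
  set.seed(51)
  seqs <- setNames(replicate(3, randomProtein(80)), c("A", "B", "C"))
  seqs <- c(seqs, D = randomProtein(80))
  seqs[["B"]] <- seqs[["A"]]; seqs[["C"]] <- seqs[["A"]]
  ps <- tinyProteomeSet(seqs,
                        genomes = setNames(paste0("g", names(seqs)),
                                           names(seqs)),
                        clades = setNames(rep(c("X", "Y"), 2),
                                          paste0("g", names(seqs))))
  hit <- function(q, s, ev) data.frame(query_id = q, subject_id = s,
                                       percent_identity = 100,
                                       align_len = 80, evalue = ev,
                                       bitscore = 150)
  hits <- rbind(hit("A", "B", 1e-50), hit("B", "C", 1e-40),
                hit("C", "D", 1e-10))  # C-D above threshold: ignored
  fs <- familiesFromBlast(hits, ps, maxEvalue = 1e-20)
  m <- members(fs)
  expect_equal(length(unique(m$family_id[m$seq_id %in% c("A", "B", "C")])), 1)
  expect_false(m$family_id[m$seq_id == "D"] %in%
               m$family_id[m$seq_id == "A"])
  expect_error(familiesFromBlast(hit("A", "nope", 1e-50), ps),
               "not present.*nope")
})

test_that("component counts match a union-find oracle on random hit graphs", {
  set.seed(61)
  for (trial in 1:50) {
    n <- sample(4:10, 1)
    ids <- sprintf("s%02d", seq_len(n))
    seqs <- setNames(rep(randomProtein(40), n), ids)  # identical: edges pass
    ps <- tinyProteomeSet(seqs,
                          genomes = setNames(ids, ids),
                          clades = setNames(rep(c("X", "Y"),
                                                length.out = n), ids))
    nEdges <- sample(0:8, 1)
    edges <- data.frame(
      query_id = ids[sample(n, nEdges, replace = TRUE)],
      subject_id = ids[sample(n, nEdges, replace = TRUE)])
    hits <- if (nrow(edges)) {
      data.frame(edges, percent_identity = 100, align_len = 40,
                 evalue = 1e-40, bitscore = 100)
    } else {
      data.frame(query_id = character(), subject_id = character(),
                 percent_identity = numeric(), align_len = integer(),
                 evalue = numeric(), bitscore = numeric())
    }
    fs <- familiesFromBlast(hits, ps)
    got <- length(unique(members(fs)$family_id))
    want <- ufComponentCount(ids,
                             edges[edges$query_id != edges$subject_id, ,
                                   drop = FALSE])
    expect_equal(got, want)
  }
})
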