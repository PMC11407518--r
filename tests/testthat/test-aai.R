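mkSm <- function(rows, parts = NULL) {
  if (is.null(parts))
    parts <- data.frame(family_id = "F1", start = 1L,
                        end = nchar(rows[[1]]))
  new("SuperMatrix", aln = Biostrings::AAStringSet(rows),
      partitions = parts)
}

test_that("pairwise AAI counts matches over informative columns only", {
  sm <- mkSm(c(gA = "MKVL-", gB = "MKVL-", gC = "MKIL-"))
  expect_equal(aaiPair(sm, "gA", "gB"), 100)
  expect_equal(aaiPair(sm, "gA", "gC"), 75)   # 3 matches / 4 columns
  # 'X' columns drop out of numerator and denominator
  smx <- mkSm(c(gA = "MKXL", gB = "MKXL"))
  expect_equal(aaiPair(smx, "gA", "gB"), 100)  # 3 qualifying columns, all match
  smz <- mkSm(c(gA = "--", gB = "MK"))
  expect_message(v <- aaiPair(smz, "gA", "gB"), "no qualifying")
  expect_true(is.na(v))
})

test_that("the AAI matrix matches a two-loop recomputation and is permutation-invariant", {
  set.seed(111)
  for (trial in 1:5) {
    rows <- setNames(vapply(1:5, function(i) {
      ch <- sample(c(AA20, "-", "X"), 60, replace = TRUE,
                   prob = c(rep(1, 20), 3, 1))
      paste0(ch, collapse = "")
    }, character(1)), sprintf("g%d", 1:5))
    sm <- mkSm(rows)
    m <- computeAaiMatrix(sm)
    v <- aaiValues(m)
    chs <- strsplit(rows, "")
    for (i in 1:4) for (j in (i + 1):5) {
      a <- chs[[i]]; b <- chs[[j]]
      ok <- a != "-" & b != "-" & a != "X" & b != "X"
      want <- if (any(ok)) 100 * sum(a[ok] == b[ok]) / sum(ok) else NA_real_
      expect_equal(v[i, j], want)
      expect_equal(v[j, i], want)
    }
    expect_equal(unname(diag(v)), rep(100, 5))
    # permuting genome order permutes rows/cols but not values
    perm <- sample(names(rows))
    m2 <- computeAaiMatrix(mkSm(rows[perm]))
    expect_equal(aaiValues(m2)[names(rows), names(rows)], v)
  }
})

test_that("concatenated AAI equals the length-weighted mean of per-family AAI", {
  sim <- simulateProteomes(cladeSpec(c(A = 3, B = 3)), nFamilies = 8,
                           lengthRange = c(120, 200), seed = 121)
  trimmed <- lapply(sim$alignments, function(a) trimAlignment(a)$msa)
  sm <- concatenateMsas(trimmed, ps = sim$proteomes)
  aai <- computeAaiMatrix(sm)
  g <- genomeIds(aai)
  p <- partitions(sm)
  rows <- lapply(msaRows(sm), function(r) strsplit(r, "")[[1]])
  for (i in seq_along(g)[-1]) {
    a <- rows[[g[1]]]; b <- rows[[g[i]]]
    num <- 0; den <- 0
    for (k in seq_len(nrow(p))) {
      cols <- p$start[k]:p$end[k]
      ok <- a[cols] != "-" & b[cols] != "-" & a[cols] != "X" & b[cols] != "X"
      num <- num + sum(a[cols][ok] == b[cols][ok])
      den <- den + sum(ok)
    }
    expect_equal(aaiValues(aai)[g[1], g[i]], 100 * num / den,
                 tolerance = 1e-12)
  }
})

test_that("clade summaries use the right pair sets", {
  rows <- setNames(c("MKVL", "MKVL", "MKIL", "WKIL", "WKIA", "AAAA"),
                   c("a1", "a2", "a3", "a4", "b1", "c1"))
  sm <- mkSm(rows)
  aai <- computeAaiMatrix(sm)
  cm <- setNames(c("A", "A", "A", "A", "B", "C"), names(rows))
  expect_message(tab <- cladeAaiSummary(aai, cm), "singleton clade")
  intraA <- tab[tab$clade_i == "A" & tab$clade_j == "A", ]
  expect_equal(intraA$n_pairs, 6)   # 4 choose 2
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
  expect_false(any(tab$clade_i == "B" & tab$clade_j == "B"))
  # a two-member clade has min = mean = max
  cm2 <- setNames(c("A", "A", "B", "B", "B", "B"), names(rows))
  tab2 <- cladeAaiSummary(aai, cm2)
  intra2 <- tab2[tab2$clade_i == "A" & tab2$clade_j == "A", ]
  expect_equal(intra2$min, intra2$max)
  expect_equal(intra2$min, intra2$mean)
})

test_that("neighbor joining recovers an additive four-taxon topology", {
  # additive distances on ((a,b),(c,d)) with internal edge 0.01
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.03
  d["c", "d"] <- d["d", "c"] <- 0.03
  d["a", "c"] <- d["c", "a"] <- 0.03
  d["a", "d"] <- d["d", "a"] <- 0.04
  d["b", "c"] <- d["c", "b"] <- 0.04
  d["b", "d"] <- d["d", "b"] <- 0.05
  aai <- new("AaiMatrix", values = 100 * (1 - d),
             overlap = matrix(1000L, 4, 4,
                              dimnames = dimnames(d)))
  nwk <- njTree(aai)
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), letters[1:4])
  rooted <- ape::root(tr, outgroup = "d", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("a", "b")))
  expect_true(all(tr$edge.length >= 0))

  withNA <- new("AaiMatrix",
                values = matrix(c(100, NA, NA, 100), 2, 2,
                                dimnames = list(c("x", "y"), c("x", "y"))),
                overlap = matrix(c(10L, 0L, 0L, 10L), 2, 2,
                                 dimnames = list(c("x", "y"), c("x", "y"))))
  expect_error(njTree(withNA), "missing AAI")
})

test_that("raising the between-clade rate never raises mean inter-clade AAI", {
  rates <- c(0.05, 0.15, 0.30)
  meanInter <- vapply(rates, function(r) {
    vals <- vapply(1:2, function(s) {
      sim <- simulateProteomes(cladeSpec(c(A = 2, B = 2), withinRate = 0.02,
                                         betweenRate = r),
                               nFamilies = 10, lengthRange = c(120, 160),
                               seed = 1000 + s)
      sm <- concatenateMsas(lapply(sim$alignments,
                                   function(a) trimAlignment(a)$msa),
                            ps = sim$proteomes)
      aai <- computeAaiMatrix(sm)
      tab <- cladeAaiSummary(aai, cladeMap(sim$proteomes))
      tab$mean[tab$clade_i != tab$clade_j]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(meanInter) < 0))
})
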