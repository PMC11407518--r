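# Independent oracles and fixture builders used across the suite. These are
# written from the definitions, not from the package internals, so that the
# implementation and the checks stay separate.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

.blosum <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

# random gapped alignment with planted rectangular gap blocks
randomAlignment <- function(nrow = 6, ncol = 60, nBlocks = 2,
                            familyId = "F0001") {
  m <- matrix(sample(AA20, nrow * ncol, replace = TRUE), nrow, ncol)
  for (b in seq_len(nBlocks)) {
    len <- sample(1:6, 1)
    s <- sample(seq_len(ncol - len + 1), 1)
    nr <- sample(seq_len(nrow - 1), 1)
    rows <- sample(nrow, nr)
    m[rows, s:(s + len - 1)] <- "-"
  }
  rownames(m) <- sprintf("g%02d", seq_len(nrow))
  msa(setNames(apply(m, 1, paste0, collapse = ""), rownames(m)),
      familyId = familyId)
}

# exhaustive maximal indel-block enumeration from the definition: an interval
# is block-consistent when every row is all-gap or all-residue across it;
# blocks are consistent, two-state, maximal intervals with admissible length
bruteIndelBlocks <- function(x, minLen = 1, maxLen = 10) {
  rows <- msaRows(x)
  G <- do.call(rbind, lapply(strsplit(rows, ""), function(ch) ch == "-"))
  nc <- ncol(G)
  cum <- cbind(0, t(apply(G, 1, cumsum)))
  # C[s, e]: every row's gap count over [s, e] is 0 or the interval length
  C <- matrix(FALSE, nc, nc)
  for (s in seq_len(nc)) {
    counts <- cum[, (s + 1):(nc + 1), drop = FALSE] - cum[, s]
    lens <- matrix(seq_len(nc - s + 1), nrow(G), nc - s + 1, byrow = TRUE)
    okm <- counts == 0 | counts == lens
    C[s, s:nc] <- apply(okm, 2, all)
  }
  out <- list()
  for (s in seq_len(nc)) for (e in s:nc) {
    if (!C[s, e]) next
    states <- G[, s]
    if (!any(states) || all(states)) next
    if (s > 1 && C[s - 1, e]) next
    if (e < nc && C[s, e + 1]) next
    len <- e - s + 1
    if (len >= minLen && len <= maxLen)
      out[[length(out) + 1]] <- data.frame(start = s, end = e)
  }
  if (!length(out)) data.frame(start = integer(), end = integer())
  else do.call(rbind, out)
}

# definitional clade-specificity check for a block at columns [s, e]
bruteClassify <- function(x, s, seqGenome, cladeMap, clade, params) {
  rows <- msaRows(x)
  isGap <- vapply(rows, function(r) substr(r, s, s) == "-", logical(1))
  gen <- unname(seqGenome[names(rows)])
  cladeGenomes <- names(cladeMap)[cladeMap == clade]
  present <- intersect(cladeGenomes, gen)
  missing <- setdiff(cladeGenomes, gen)
  if (length(present) < 2) return(NULL)
  if (length(missing) && !params@allowMissing) return(NULL)
  cladeGap <- isGap[gen %in% cladeGenomes]
  if (length(unique(cladeGap)) != 1) return(NULL)
  S <- cladeGap[1]
  outGap <- isGap[!gen %in% cladeGenomes]
  outGen <- gen[!gen %in% cladeGenomes]
  exceptions <- sort(outGen[outGap == S])
  if (!any(outGap != S)) return(NULL)
  if (length(exceptions) > params@maxExceptions) return(NULL)
  list(indelType = if (S) "deletion" else "insertion",
       exceptions = exceptions, missing = sort(missing))
}

# definitional flank-conservation census
bruteFlank <- function(x, s, e, params) {
  m <- do.call(rbind, strsplit(msaRows(x), ""))
  nc <- ncol(m)
  conserved <- function(j) {
    col <- m[, j]
    if (any(col == "-")) return(FALSE)
    col <- col[col != "X"]
    if (!length(col)) return(FALSE)
    max(table(col)) / nrow(m) >= params@conservedFraction
  }
  w <- params@flankWindow
  lc <- if (s > 1) sum(vapply(max(1, s - w):(s - 1), conserved, logical(1))) else 0
  rc <- if (e < nc) sum(vapply((e + 1):min(nc, e + w), conserved, logical(1))) else 0
  c(left = lc, right = rc)
}

# full definitional scan, as comparable key strings
bruteScanKeys <- function(x, seqGenome, cladeMap, clade, params) {
  blocks <- bruteIndelBlocks(x, params@minIndelLen, params@maxIndelLen)
  keys <- character()
  for (k in seq_len(nrow(blocks))) {
    s <- blocks$start[k]; e <- blocks$end[k]
    v <- bruteClassify(x, s, seqGenome, cladeMap, clade, params)
    if (is.null(v)) next
    fc <- bruteFlank(x, s, e, params)
    if (fc["left"] < params@minConservedFlank ||
        fc["right"] < params@minConservedFlank) next
    keys <- c(keys, paste(familyId(x), s, e, v$indelType,
                          paste(v$exceptions, collapse = "+"),
                          paste(v$missing, collapse = "+"), sep = "|"))
  }
  sort(keys)
}

recordKeys <- function(records) {
  sort(vapply(records, function(r)
    paste(r@familyId, r@blockStart, r@blockEnd, r@indelType,
          paste(sort(r@exceptions), collapse = "+"),
          paste(sort(r@missing), collapse = "+"), sep = "|"),
    character(1)))
}

plantKeys <- function(manifest) recordKeys(truthRecords(manifest))

# union-find connected-component count
ufComponentCount <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[[1]][k]); rb <- find(edges[[2]][k])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(ids, find, character(1))))
}

# exhaustive global alignment of two tiny sequences under affine scoring
# (gap of length L costs open + L * ext); returns the optimal score and all
# optimal alignments
enumGlobalAlign <- function(a, b, open = 10, ext = 1) {
  S <- .blosum()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  scoreAln <- function(pa, pb) {
    sc <- 0
    pairs <- pa != "-" & pb != "-"
    if (any(pairs)) sc <- sum(S[cbind(pa[pairs], pb[pairs])])
    for (v in list(pa, pb)) {
      r <- rle(v == "-")
      if (any(r$values)) sc <- sc - sum(open + ext * r$lengths[r$values])
    }
    sc
  }
  best <- list(score = -Inf, aligns = list())
  rec <- function(i, j, pa, pb) {
    if (i > length(A) && j > length(B)) {
      sc <- scoreAln(pa, pb)
      if (sc > best$score + 1e-9) {
        best <<- list(score = sc, aligns = list(list(a = pa, b = pb)))
      } else if (abs(sc - best$score) <= 1e-9) {
        best$aligns[[length(best$aligns) + 1]] <<- list(a = pa, b = pb)
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, c(pa, A[i]), c(pb, B[j]))
    if (i <= length(A)) rec(i + 1, j, c(pa, A[i]), c(pb, "-"))
    if (j <= length(B)) rec(i, j + 1, c(pa, "-"), c(pb, B[j]))
  }
  rec(1, 1, character(), character())
  best
}

randomProtein <- function(n) paste0(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# small proteome set built directly from named sequences
tinyProteomeSet <- function(seqs, genomes, clades) {
  proteomeSet(Biostrings::AAStringSet(seqs), genomes,
              data.frame(genome_id = unique(unname(genomes)),
                         clade = clades[unique(unname(genomes))]))
}
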