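# a hand-built alignment with a clean indel block: clade rows carry residues,
# outgroup rows carry gaps, flanks are 40 identical columns
blockFixture <- function(nClade = 4, nOut = 9, blockLen = 2,
                         flank = 40, leftConserved = flank,
                         cladeSplit = FALSE) {
  left <- randomProtein(flank)
  right <- randomProtein(flank)
  motif <- randomProtein(blockLen)
  ids <- c(sprintf("c%02d", seq_len(nClade)), sprintf("o%02d", seq_len(nOut)))
  rows <- setNames(vapply(seq_along(ids), function(i) {
    mid <- if (i <= nClade) motif else strrep("-", blockLen)
    paste0(left, mid, right)
  }, character(1)), ids)
  if (leftConserved < flank) {
    # degrade all but `leftConserved` left columns by mutating one row
    spoil <- seq_len(flank - leftConserved)
    ch <- strsplit(rows[[length(rows)]], "")[[1]]
    for (j in spoil) ch[j] <- setdiff(AA20, ch[j])[1]
    rows[[length(rows)]] <- paste0(ch, collapse = "")
  }
  if (cladeSplit) {
    ch <- strsplit(rows[[1]], "")[[1]]
    ch[(flank + 1):(flank + blockLen)] <- "-"
    rows[[1]] <- paste0(ch, collapse = "")
  }
  sg <- setNames(ids, ids)
  cm <- setNames(rep(c("target", "other"), c(nClade, nOut)), ids)
  list(msa = msa(rows, familyId = "F0001"), seqGenome = sg, cladeMap = cm)
}
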