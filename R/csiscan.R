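#' @include AllClasses.R simulate.R
NULL

# 1-based residue interval of the reference row across the block plus its
# flank windows (clamped at the alignment edges)
.refRegion <- function(rowStr, blockStart, blockEnd, flankWindow) {
  ch <- strsplit(rowStr, "", fixed = TRUE)[[1L]]
  spanStart <- max(1L, blockStart - flankWindow)
  spanEnd <- min(length(ch), blockEnd + flankWindow)
  cum <- cumsum(ch != GAP)
  refEnd <- cum[spanEnd]
  refStart <- if (spanStart == 1L) 1L else cum[spanStart - 1L] + 1L
  if (refEnd < refStart)
    stop("reference row has no residues across the flanked span",
         call. = FALSE)
  c(refStart, refEnd)
}

#' Find maximal fixed-length indel blocks
#'
#' Scans an alignment for maximal column intervals over which every row is
#' either all-gap or all-residue (block consistency), with at least one row
#' of each state, keeping intervals whose length lies in
#' \code{[minLen, maxLen]}. Blocks are maximal: extending them one column in
#' either direction breaks consistency. Output is sorted by start column.
#'
#' @param x an \linkS4class{Msa} with at least three rows.
#' @param minLen,maxLen admissible block lengths in columns.
#' @return data.frame with columns start, end and list-columns gapped,
#'   residue holding the row ids in each state.
#' @export
findIndelBlocks <- function(x, minLen = 1, maxLen = 10) {
  if (nrow(x) < 3L)
    stop("indel scanning needs at least three rows", call. = FALSE)
  m <- .msaMatrix(x)
  empty <- data.frame(start = integer(), end = integer())
  empty$gapped <- list(); empty$residue <- list()
  if (!ncol(m)) return(empty)
  G <- m == GAP
  pat <- apply(G, 2L, function(col) paste0(as.integer(col), collapse = ""))
  r <- rle(pat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- logical(length(starts))
  for (k in seq_along(starts)) {
    col <- G[, starts[k]]
    keep[k] <- any(col) && !all(col) &&
      r$lengths[k] >= minLen && r$lengths[k] <= maxLen
  }
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(start = as.integer(starts), end = as.integer(ends))
  out$gapped <- lapply(starts, function(s) rownames(m)[G[, s]])
  out$residue <- lapply(starts, function(s) rownames(m)[!G[, s]])
  out
}

#' Classify an indel block against a target clade
#'
#' Determines whether a block is clade-specific: every clade member present
#' in the family must hold the same state (residue or gap; any within-clade
#' disagreement fails outright), at least one genome outside the clade must
#' hold the opposite state, and the number of outside genomes sharing the
#' clade state (the isolated exceptions) must not exceed
#' \code{maxExceptions}. Clade genomes without a row are recorded as missing
#' and are tolerated only when \code{allowMissing} is set; at least two clade
#' rows must be present in all cases.
#'
#' @param block one row of \code{\link{findIndelBlocks}} output (or any list
#'   with elements gapped and residue of row ids).
#' @param seqGenome named character, row id -> genome id.
#' @param cladeMap named character, genome id -> clade label.
#' @param targetClade clade label under test.
#' @param params \linkS4class{ScanParams}.
#' @return list with elements pass (logical), reason (character),
#'   indelType, exceptions, missing.
#' @export
classifyBlock <- function(block, seqGenome, cladeMap, targetClade,
                          params = scanParams()) {
  if (!targetClade %in% cladeMap)
    stop("clade '", targetClade, "' absent from cladeMap", call. = FALSE)
  gappedRows <- unlist(block$gapped)
  residueRows <- unlist(block$residue)
  rows <- c(gappedRows, residueRows)
  gen <- seqGenome[rows]
  if (anyNA(gen))
    stop("unmapped row id(s): ",
         paste(rows[is.na(gen)], collapse = ", "), call. = FALSE)
  state <- stats::setNames(rep(c("gap", "residue"),
                               c(length(gappedRows), length(residueRows))),
                           unname(gen))
  cladeGenomes <- names(cladeMap)[cladeMap == targetClade]
  present <- intersect(cladeGenomes, names(state))
  missing <- setdiff(cladeGenomes, names(state))
  fail <- function(reason) list(pass = FALSE, reason = reason,
                                indelType = NA_character_,
                                exceptions = character(),
                                missing = missing)
  if (length(present) < 2L)
    return(fail("fewer than two clade rows present"))
  if (length(missing) && !params@allowMissing)
    return(fail("missing clade homologue not tolerated"))
  cladeStates <- unique(state[present])
  if (length(cladeStates) != 1L)
    return(fail("clade not unanimous"))
  S <- cladeStates
  outside <- setdiff(names(state), cladeGenomes)
  exceptions <- sort(outside[state[outside] == S], method = "radix")
  if (!any(state[outside] != S))
    return(fail("no outgroup genome with the opposite state"))
  indelType <- if (S == "residue") "insertion" else "deletion"
  if (length(exceptions) > params@maxExceptions)
    return(list(pass = FALSE, reason = "too many exceptions",
                indelType = indelType, exceptions = exceptions,
                missing = missing))
  list(pass = TRUE, reason = "ok", indelType = indelType,
       exceptions = exceptions, missing = sort(missing, method = "radix"))
}

#' Flank conservation around an indel block
#'
#' Counts conserved columns within \code{flankWindow} columns immediately to
#' the left and right of a block (clamped at the alignment edges). A column
#' is conserved when it is gap-free among the rows present and a single
#' residue other than 'X' reaches frequency \code{conservedFraction}. The
#' check passes when both counts reach \code{minConservedFlank}; a block too
#' close to an alignment edge cannot pass.
#'
#' @param x the \linkS4class{Msa} the block belongs to.
#' @param block list or data.frame row with elements start and end.
#' @param params \linkS4class{ScanParams}.
#' @return list with elements left, right (conserved column counts) and
#'   pass.
#' @export
flankConservation <- function(x, block, params = scanParams()) {
  m <- .msaMatrix(x)
  nc <- ncol(m)
  conservedCols <- function(cols) {
    if (!length(cols)) return(0L)
    sum(vapply(cols, function(j) {
      col <- m[, j]
      if (any(col == GAP)) return(FALSE)
      tab <- table(col[col != "X"])
      length(tab) > 0L &&
        max(tab) / length(col) >= params@conservedFraction
    }, logical(1L)))
  }
  leftCols <- if (block$start > 1L)
    seq.int(max(1L, block$start - params@flankWindow), block$start - 1L)
  else integer(0)
  rightCols <- if (block$end < nc)
    seq.int(block$end + 1L, min(nc, block$end + params@flankWindow))
  else integer(0)
  left <- conservedCols(leftCols)
  right <- conservedCols(rightCols)
  list(left = as.integer(left), right = as.integer(right),
       pass = left >= params@minConservedFlank &&
              right >= params@minConservedFlank)
}

.resolveMaps <- function(ps, cladeMap, seqGenome) {
  if (!is.null(ps)) {
    if (is.null(cladeMap)) cladeMap <- cladeMap(ps)
    if (is.null(seqGenome)) seqGenome <- genomeOf(ps)
  }
  if (is.null(cladeMap) || is.null(seqGenome))
    stop("supply either ps or both cladeMap and seqGenome", call. = FALSE)
  if (length(unique(unname(cladeMap))) < 2L)
    stop("CSI scanning needs at least two distinct clades", call. = FALSE)
  list(cladeMap = cladeMap, seqGenome = seqGenome)
}

#' Scan alignments for clade-specific conserved signature indels
#'
#' The full CSI pipeline over a set of family alignments: find maximal
#' fixed-length indel blocks, test clade specificity, and require conserved
#' flanks on both sides. One \linkS4class{CsiRecord} is emitted per passing
#' block, with the clade member of lexicographically smallest genome id as
#' the reference sequence and the reference-residue span of block plus flank
#' windows reported as the indel region. Records are sorted by family and
#' start column; the scan is deterministic.
#'
#' @param msas list of \linkS4class{Msa} (families with fewer than three
#'   rows are skipped).
#' @param targetClade clade label to scan for.
#' @param ps optional \linkS4class{ProteomeSet} supplying the maps.
#' @param cladeMap,seqGenome maps as in \code{\link{classifyBlock}}.
#' @param params \linkS4class{ScanParams}.
#' @return list of \linkS4class{CsiRecord}.
#' @export
scanCladeCsis <- function(msas, targetClade, ps = NULL, cladeMap = NULL,
                          seqGenome = NULL, params = scanParams()) {
  maps <- .resolveMaps(ps, cladeMap, seqGenome)
  records <- list()
  for (x in msas) {
    if (nrow(x) < 3L) next
    blocks <- findIndelBlocks(x, params@minIndelLen, params@maxIndelLen)
    if (!nrow(blocks)) next
    rows <- msaRows(x)
    rowGen <- maps$seqGenome[names(rows)]
    if (anyNA(rowGen))
      stop("unmapped row id(s) in family ", familyId(x), call. = FALSE)
    for (k in seq_len(nrow(blocks))) {
      block <- blocks[k, ]
      verdict <- classifyBlock(block, maps$seqGenome, maps$cladeMap,
                               targetClade, params)
      if (!verdict$pass) next
      fc <- flankConservation(x, block, params)
      if (!fc$pass) next
      cladeRows <- names(rows)[maps$cladeMap[rowGen] == targetClade]
      ref <- cladeRows[order(rowGen[cladeRows], method = "radix")][1L]
      rr <- .refRegion(rows[[ref]], block$start, block$end,
                       params@flankWindow)
      records[[length(records) + 1L]] <- csiRecord(
        familyId = familyId(x), referenceSeqId = ref,
        indelType = verdict$indelType, blockStart = block$start,
        blockEnd = block$end, refStart = rr[1L], refEnd = rr[2L],
        clade = targetClade, exceptions = verdict$exceptions,
        missing = verdict$missing,
        flankConserved = c(fc$left, fc$right))
    }
  }
  if (length(records)) {
    o <- order(vapply(records, function(r) r@familyId, character(1L)),
               vapply(records, function(r) r@blockStart, integer(1L)),
               method = "radix")
    records <- records[o]
  }
  records
}

#' Re-check a claimed CSI record against its alignment
#'
#' Recomputes the scan for the record's family and verifies that the claimed
#' block exists, classifies to the claimed clade with the claimed type,
#' exceptions and missing genomes, satisfies flank conservation, and carries
#' the claimed reference coordinates. Used to assert the generator's planted
#' manifest and in tests.
#'
#' @param x the family \linkS4class{Msa} the record refers to.
#' @param record a \linkS4class{CsiRecord}.
#' @param ps,cladeMap,seqGenome maps as in \code{\link{scanCladeCsis}}.
#' @param params \linkS4class{ScanParams}.
#' @return list with elements valid (logical) and reasons (character).
#' @export
validateCsi <- function(x, record, ps = NULL, cladeMap = NULL,
                        seqGenome = NULL, params = scanParams()) {
  maps <- .resolveMaps(ps, cladeMap, seqGenome)
  rows <- msaRows(x)
  if (!record@referenceSeqId %in% names(rows))
    stop("reference sequence ", record@referenceSeqId,
         " not a row of the alignment", call. = FALSE)
  reasons <- character()
  blocks <- findIndelBlocks(x, params@minIndelLen, params@maxIndelLen)
  hit <- which(blocks$start == record@blockStart &
               blocks$end == record@blockEnd)
  if (!length(hit)) {
    reasons <- c(reasons, "no maximal indel block at the stated columns")
    return(list(valid = FALSE, reasons = reasons))
  }
  block <- blocks[hit[1L], ]
  if (record@indelLength != record@blockEnd - record@blockStart + 1L)
    reasons <- c(reasons, "indel length does not match the stated columns")
  verdict <- classifyBlock(block, maps$seqGenome, maps$cladeMap,
                           record@clade, params)
  if (!verdict$pass)
    reasons <- c(reasons, paste0("specificity failed: ", verdict$reason))
  else {
    if (!identical(verdict$indelType, record@indelType))
      reasons <- c(reasons, "indel type mismatch")
    if (!setequal(verdict$exceptions, record@exceptions))
      reasons <- c(reasons, "exception set mismatch")
    if (!setequal(verdict$missing, record@missing))
      reasons <- c(reasons, "missing set mismatch")
  }
  fc <- flankConservation(x, block, params)
  if (!fc$pass)
    reasons <- c(reasons, "flank conservation failed")
  if (!anyNA(record@flankConserved) &&
      !identical(c(fc$left, fc$right), record@flankConserved))
    reasons <- c(reasons, "flank conservation counts mismatch")
  rr <- .refRegion(rows[[record@referenceSeqId]], record@blockStart,
                   record@blockEnd, params@flankWindow)
  if (rr[1L] != record@refStart || rr[2L] != record@refEnd)
    reasons <- c(reasons, "reference region mismatch")
  list(valid = !length(reasons), reasons = reasons)
}

#' Tabulate CSI records
#'
#' @param records list of \linkS4class{CsiRecord}.
#' @return data.frame, one row per record.
#' @export
csiTable <- function(records) {
  if (!length(records))
    return(data.frame(family_id = character(), reference_seq_id = character(),
                      clade = character(), indel_type = character(),
                      indel_length = integer(), block_start = integer(),
                      block_end = integer(), ref_start = integer(),
                      ref_end = integer(), n_exceptions = integer(),
                      n_missing = integer()))
  do.call(rbind, lapply(records, function(r) data.frame(
    family_id = r@familyId, reference_seq_id = r@referenceSeqId,
    clade = r@clade, indel_type = r@indelType,
    indel_length = r@indelLength, block_start = r@blockStart,
    block_end = r@blockEnd, ref_start = r@refStart, ref_end = r@refEnd,
    n_exceptions = length(r@exceptions), n_missing = length(r@missing))))
}
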