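#' @include AllClasses.R
NULL

# character matrix view of an alignment (rows x columns)
.msaMatrix <- function(x) {
  rows <- msaRows(x)
  if (!length(rows)) return(matrix(character(), 0, 0))
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

.matrixMsa <- function(m, familyId) {
  msa(stats::setNames(apply(m, 1L, paste0, collapse = ""), rownames(m)),
      familyId = familyId)
}

# per-site substitution to a uniformly chosen different residue
.mutateSeq <- function(res, rate) {
  if (rate <= 0) return(res)
  hit <- which(stats::runif(length(res)) < rate)
  if (length(hit)) {
    cur <- match(res[hit], AA20)
    res[hit] <- AA20[((cur - 1L +
                       sample.int(19L, length(hit), replace = TRUE)) %% 20L) + 1L]
  }
  res
}

#' Simulate a clade-structured proteome set
#'
#' Generates one protein family at a time on a star-of-clades tree: a root
#' sequence drawn i.i.d. uniformly over the 20 amino acids, one ancestor per
#' clade derived from the root by per-site Bernoulli substitution at the
#' between-clade rate, and one sequence per genome derived from its clade
#' ancestor at the within-clade rate. Substitutions always change the residue
#' (uniform over the 19 alternatives), so two genomes of the same clade match
#' at a site with probability (1-p)^2 + p^2/19 where p is the within-clade
#' rate. With \code{backgroundIndelRate = 0} (the default) no sequence
#' contains an indel and every true alignment is gap-free; a positive rate
#' deletes each site of each genome copy independently with that probability,
#' leaving a gap in the true alignment.
#'
#' @param clades a \linkS4class{CladeSpec}; the default is the package's
#'   standard 30-genome five-clade design.
#' @param nFamilies number of protein families.
#' @param lengthRange integer length-2, family root length range in residues
#'   (min >= 120 so flanks fit around planted indels).
#' @param seed integer seed; the run is fully deterministic given it.
#' @param backgroundIndelRate per-site deletion probability per genome copy.
#' @return A list with elements \code{proteomes}
#'   (\linkS4class{ProteomeSet}), \code{alignments} (named list of
#'   \linkS4class{Msa}, the true per-family alignments) and \code{roots}
#'   (named character vector of root sequences, the planting substrate).
#' @examples
#' sim <- simulateProteomes(cladeSpec(c(A = 3, B = 3)), nFamilies = 5,
#'                          lengthRange = c(120, 150), seed = 1)
#' sim$proteomes
#' @export
simulateProteomes <- function(clades = cladeSpec(), nFamilies = 200,
                              lengthRange = c(150, 400), seed,
                              backgroundIndelRate = 0) {
  stopifnot(is(clades, "CladeSpec"), nFamilies >= 1)
  if (lengthRange[1L] < 120L)
    stop("lengthRange minimum must be >= 120 residues", call. = FALSE)
  set.seed(as.integer(seed))
  labels <- names(clades@sizes)
  genomes <- unlist(lapply(labels, function(cl)
    sprintf("%s_g%02d", cl, seq_len(clades@sizes[[cl]]))))
  gclade <- rep(labels, clades@sizes)
  famIds <- sprintf("F%04d", seq_len(nFamilies))

  seqs <- vector("list", nFamilies)
  alns <- vector("list", nFamilies)
  roots <- character(nFamilies)
  for (k in seq_len(nFamilies)) {
    len <- sample(seq.int(lengthRange[1L], lengthRange[2L]), 1L)
    root <- sample(AA20, len, replace = TRUE)
    roots[k] <- paste0(root, collapse = "")
    anc <- lapply(labels, function(cl) .mutateSeq(root, clades@betweenRate))
    names(anc) <- labels
    rows <- character(length(genomes))
    ungapped <- character(length(genomes))
    for (i in seq_along(genomes)) {
      res <- .mutateSeq(anc[[gclade[i]]], clades@withinRate)
      if (backgroundIndelRate > 0) {
        del <- stats::runif(len) < backgroundIndelRate
        row <- res
        row[del] <- GAP
        rows[i] <- paste0(row, collapse = "")
        ungapped[i] <- paste0(res[!del], collapse = "")
      } else {
        rows[i] <- paste0(res, collapse = "")
        ungapped[i] <- rows[i]
      }
    }
    ids <- paste0(famIds[k], "_", genomes)
    seqs[[k]] <- stats::setNames(ungapped, ids)
    alns[[k]] <- msa(stats::setNames(rows, ids), familyId = famIds[k])
  }
  allSeqs <- unlist(seqs)
  sg <- stats::setNames(rep(genomes, times = nFamilies), names(allSeqs))
  ps <- proteomeSet(AAStringSet(allSeqs), sg,
                    data.frame(genome_id = genomes, display_name = genomes,
                               clade = gclade))
  names(alns) <- famIds
  list(proteomes = ps, alignments = alns,
       roots = stats::setNames(roots, famIds))
}

#' Draw a random planting plan
#'
#' Samples \code{n} families and, for each, a clade, an indel type, a length
#' and a position that leaves at least a full flank window of residues on
#' both sides. Optionally marks some plants with a missing clade homologue
#' (only in clades with at least three genomes, so two clade rows remain) and
#' some with one isolated out-of-clade exception.
#'
#' @param sim result of \code{\link{simulateProteomes}}.
#' @param n number of CSIs to plant (at most one per family).
#' @param lengths candidate indel lengths in residues.
#' @param clades clade labels eligible for planting (default: all).
#' @param nMissing number of plants that lose one clade homologue.
#' @param nExceptions number of plants that gain one isolated exception.
#' @param params \linkS4class{ScanParams} whose flank window constrains
#'   positions.
#' @param seed integer seed.
#' @return data.frame with columns family_id, clade, indel_type, length,
#'   position, missing_genome, exception_genome.
#' @export
sampleCsiPlan <- function(sim, n = 25, lengths = 1:4, clades = NULL,
                          nMissing = 3, nExceptions = 0,
                          params = scanParams(), seed) {
  set.seed(as.integer(seed))
  cm <- cladeMap(sim$proteomes)
  allClades <- unique(unname(cm))
  if (is.null(clades)) clades <- allClades
  fams <- sort(sample(names(sim$alignments), n))
  w <- params@flankWindow
  plan <- do.call(rbind, lapply(seq_along(fams), function(i) {
    f <- fams[i]
    L0 <- nchar(sim$roots[[f]])
    len <- lengths[sample.int(length(lengths), 1L)]
    pos <- sample(seq.int(w + 1L, L0 - w - len + 1L), 1L)
    data.frame(family_id = f,
               clade = clades[sample.int(length(clades), 1L)],
               indel_type = c("insertion", "deletion")[sample.int(2L, 1L)],
               length = len, position = pos,
               missing_genome = NA_character_,
               exception_genome = NA_character_)
  }))
  big <- names(which(table(cm) >= 3L))
  cand <- which(plan$clade %in% big)
  if (nMissing > 0) {
    pick <- cand[seq_len(min(nMissing, length(cand)))]
    for (i in pick) {
      mem <- names(cm)[cm == plan$clade[i]]
      plan$missing_genome[i] <- mem[sample.int(length(mem), 1L)]
    }
  }
  if (nExceptions > 0) {
    pick <- seq_len(min(nExceptions, nrow(plan)))
    for (i in pick) {
      out <- names(cm)[cm != plan$clade[i]]
      plan$exception_genome[i] <- out[sample.int(length(out), 1L)]
    }
  }
  plan
}

#' Plant clade-specific indels into a simulated set
#'
#' Applies a planting plan to the true alignments of
#' \code{\link{simulateProteomes}}: an insertion adds a single shared motif of
#' the stated length to every member of the target clade (a new all-gap block
#' for everyone else); a deletion removes the stated run from every clade
#' member. The \code{minConservedFlank} columns immediately adjacent to the
#' block on each side are reverted to the root residues in all genomes, which
#' guarantees the planted indel satisfies the flank-conservation criterion.
#' An optional exception genome outside the clade receives the clade state; an
#' optional missing genome loses its family member altogether.
#'
#' @param sim result of \code{\link{simulateProteomes}}.
#' @param plan data.frame as produced by \code{\link{sampleCsiPlan}} (columns
#'   family_id, clade, indel_type, length, position, and optionally
#'   missing_genome, exception_genome). At most one plant per family.
#' @param params \linkS4class{ScanParams} used for flank guarantees and for
#'   the manifest's bookkeeping.
#' @param seed integer seed (draws the inserted motifs).
#' @return A list with elements \code{proteomes}, \code{alignments} (mutated
#'   copies) and \code{manifest} (a \linkS4class{TruthManifest} whose records
#'   describe each planted CSI exactly as the scanner should report it).
#' @export
plantCsis <- function(sim, plan, params = scanParams(), seed) {
  set.seed(as.integer(seed))
  if (anyDuplicated(plan$family_id))
    stop("at most one planted CSI per family (duplicate family_id)",
         call. = FALSE)
  cm <- cladeMap(sim$proteomes)
  bad <- setdiff(plan$clade, unname(cm))
  if (length(bad))
    stop("clade label(s) absent from ProteomeSet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!"missing_genome" %in% names(plan)) plan$missing_genome <- NA_character_
  if (!"exception_genome" %in% names(plan)) plan$exception_genome <- NA_character_

  alns <- sim$alignments
  k <- params@minConservedFlank
  w <- params@flankWindow
  records <- vector("list", nrow(plan))
  missingTab <- list(); exceptTab <- list()

  for (i in seq_len(nrow(plan))) {
    f <- plan$family_id[i]
    if (!f %in% names(alns)) stop("unknown family: ", f, call. = FALSE)
    type <- plan$indel_type[i]
    len <- as.integer(plan$length[i])
    pos <- as.integer(plan$position[i])
    clade <- plan$clade[i]
    m <- .msaMatrix(alns[[f]])
    root <- strsplit(sim$roots[[f]], "", fixed = TRUE)[[1L]]
    L0 <- length(root)
    if (pos - 1L < w || L0 - (pos + ifelse(type == "deletion", len, 0L) - 1L) < w)
      stop("plant position in ", f,
           " leaves less than a flank window on one side", call. = FALSE)
    rowGenome <- sub(paste0("^", f, "_"), "", rownames(m))
    inClade <- cm[rowGenome] == clade
    excGenome <- plan$exception_genome[i]
    if (!is.na(excGenome)) {
      if (cm[[excGenome]] == clade)
        stop("exception genome must lie outside the target clade",
             call. = FALSE)
      exceptTab[[length(exceptTab) + 1L]] <-
        data.frame(family_id = f, genome_id = excGenome)
    }
    carrier <- inClade | (!is.na(excGenome) & rowGenome == excGenome)

    if (type == "insertion") {
      motif <- sample(AA20, len, replace = TRUE)
      block <- matrix(GAP, nrow(m), len)
      block[carrier, ] <- matrix(motif, sum(carrier), len, byrow = TRUE)
      left <- m[, seq_len(pos - 1L), drop = FALSE]
      right <- m[, seq.int(pos, L0), drop = FALSE]
      # flank reversion to root on both sides of the new block
      left[, seq.int(pos - k, pos - 1L)] <-
        matrix(root[seq.int(pos - k, pos - 1L)], nrow(m), k, byrow = TRUE)
      right[, seq_len(k)] <-
        matrix(root[seq.int(pos, pos + k - 1L)], nrow(m), k, byrow = TRUE)
      m2 <- cbind(left, block, right)
      blockStart <- pos; blockEnd <- pos + len - 1L
    } else {
      m2 <- m
      m2[carrier, seq.int(pos, pos + len - 1L)] <- GAP
      m2[, seq.int(pos - k, pos - 1L)] <-
        matrix(root[seq.int(pos - k, pos - 1L)], nrow(m), k, byrow = TRUE)
      m2[, seq.int(pos + len, pos + len + k - 1L)] <-
        matrix(root[seq.int(pos + len, pos + len + k - 1L)], nrow(m), k,
               byrow = TRUE)
      blockStart <- pos; blockEnd <- pos + len - 1L
    }
    rownames(m2) <- rownames(m)

    missGenome <- plan$missing_genome[i]
    if (!is.na(missGenome)) {
      keep <- rowGenome != missGenome
      if (cm[[missGenome]] == clade && sum(inClade & keep) < 2L)
        stop("removing ", missGenome, " from ", f,
             " would leave fewer than two clade rows", call. = FALSE)
      m2 <- m2[keep, , drop = FALSE]
      rowGenome2 <- rowGenome[keep]
      missingTab[[length(missingTab) + 1L]] <-
        data.frame(family_id = f, genome_id = missGenome)
    } else {
      rowGenome2 <- rowGenome
    }
    newMsa <- .matrixMsa(m2, familyId = f)
    alns[[f]] <- newMsa

    cladeRows <- rownames(m2)[cm[rowGenome2] == clade]
    refRow <- cladeRows[order(rowGenome2[match(cladeRows, rownames(m2))],
                              method = "radix")][1L]
    refStr <- msaRows(newMsa)[[refRow]]
    rr <- .refRegion(refStr, blockStart, blockEnd, w)
    missing <- if (!is.na(missGenome) && cm[[missGenome]] == clade)
      missGenome else character()
    fc <- flankConservation(newMsa,
                            data.frame(start = blockStart, end = blockEnd),
                            params)
    records[[i]] <- csiRecord(
      familyId = f, referenceSeqId = refRow, indelType = type,
      blockStart = blockStart, blockEnd = blockEnd,
      refStart = rr[1L], refEnd = rr[2L], clade = clade,
      exceptions = if (is.na(excGenome)) character() else excGenome,
      missing = missing, flankConserved = c(fc$left, fc$right))
  }

  # rebuild the proteome from the mutated alignments
  rows <- unlist(lapply(alns, msaRows))
  names(rows) <- unlist(lapply(alns, function(a) names(msaRows(a))))
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  famOf <- sub("_.*$", "", names(rows))
  sg <- stats::setNames(sub("^F[0-9]+_", "", names(rows)), names(rows))
  ps <- proteomeSet(AAStringSet(ungapped), sg,
                    sim$proteomes@genomeTable)
  mk <- function(lst) if (length(lst)) do.call(rbind, lst) else
    data.frame(family_id = character(), genome_id = character())
  manifest <- new("TruthManifest", seed = as.integer(seed),
                  records = records, missing = mk(missingTab),
                  exceptions = mk(exceptTab))
  list(proteomes = ps, alignments = alns, manifest = manifest,
       roots = sim$roots)
}
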