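#' @include AllClasses.R
NULL

.blosum62 <- local({
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

#' Global pairwise identity and coverage
#'
#' Aligns two protein sequences globally (Needleman-Wunsch with BLOSUM62
#' scores and affine gaps, open 10 / extend 1) and reports, for the optimal
#' alignment, the identity fraction (exactly matching columns over columns
#' where both rows carry a residue; 'X' never matches) and the coverage
#' fraction (both-residue columns over the length of the shorter sequence).
#'
#' @param a,b ungapped protein sequences (character scalars or AAString).
#' @param gapOpening,gapExtension affine gap penalties.
#' @return Named numeric vector \code{c(identity=, coverage=)}.
#' @examples
#' pairwiseIdentity("MKVL", "MKIL")   # identity 0.75
#' @export
pairwiseIdentity <- function(a, b, gapOpening = 10, gapExtension = 1) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(), gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  pv <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sv <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  both <- pv != GAP & sv != GAP
  matches <- both & pv == sv & pv != "X"
  id <- if (any(both)) sum(matches) / sum(both) else 0
  cov <- sum(both) / min(nchar(a), nchar(b))
  c(identity = id, coverage = cov)
}

.newFamilySet <- function(rows, nGenomes) {
  m <- do.call(rbind, rows)
  reps <- vapply(split(m, m$family_id), function(sub) {
    lmax <- max(sub$seq_length)
    sort(sub$seq_id[sub$seq_length == lmax], method = "radix")[1L]
  }, character(1L))
  new("FamilySet", members = m, representatives = reps,
      nGenomesTotal = as.integer(nGenomes),
      genomeReps = data.frame(family_id = character(),
                              genome_id = character(),
                              seq_id = character()))
}

#' Greedy incremental protein clustering
#'
#' CD-HIT-style clustering: sequences are sorted by length (descending; ties
#' by sequence id) and each joins the first existing family whose
#' representative it matches at both thresholds, otherwise founding a new
#' family. The representative of every family is its founder, which by the
#' sort order is also the longest member. Fully deterministic.
#'
#' @param ps a \linkS4class{ProteomeSet}.
#' @param minIdentity,minCoverage thresholds against the representative
#'   (defaults 0.5 and 0.5: homologues sharing at least half of their
#'   sequence length and identity).
#' @return A \linkS4class{FamilySet}; the members table caches each member's
#'   identity and coverage against its representative.
#' @export
clusterGreedy <- function(ps, minIdentity = 0.5, minCoverage = 0.5) {
  seqs <- aaSequences(ps)
  stopifnot(length(seqs) >= 1L)
  strs <- as.character(seqs)
  ids <- names(seqs)
  o <- order(-nchar(strs), ids, method = "radix")
  ids <- ids[o]; strs <- strs[o]
  sg <- genomeOf(ps)

  famOf <- character(length(ids)); names(famOf) <- ids
  repSeq <- character(); repId <- character()
  idv <- numeric(length(ids)); covv <- numeric(length(ids))
  nextFam <- 0L
  for (i in seq_along(ids)) {
    placed <- FALSE
    if (nextFam > 0L) {
      for (f in seq_len(nextFam)) {
        ic <- pairwiseIdentity(strs[i], repSeq[f])
        if (ic[["identity"]] >= minIdentity &&
            ic[["coverage"]] >= minCoverage) {
          famOf[i] <- repId[f]
          idv[i] <- ic[["identity"]]; covv[i] <- ic[["coverage"]]
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      nextFam <- nextFam + 1L
      repSeq[nextFam] <- strs[i]
      repId[nextFam] <- ids[i]
      famOf[i] <- ids[i]
      idv[i] <- 1; covv[i] <- 1
    }
  }
  # family ids named after founding order
  famIdx <- match(famOf, repId)
  famLab <- sprintf("FAM%04d", famIdx)
  rows <- data.frame(family_id = famLab, seq_id = ids,
                     genome_id = unname(sg[ids]),
                     seq_length = nchar(strs),
                     rep_identity = idv, rep_coverage = covv)
  .newFamilySet(list(rows), length(genomeIds(ps)))
}

#' Select core families and per-genome representatives
#'
#' Keeps families present in at least \code{prevalence} of the genomes (the
#' core criterion) and, within each kept family, selects one sequence per
#' genome: the member with the highest identity to the family representative
#' (ties broken by length, then by sequence id).
#'
#' @param fs a \linkS4class{FamilySet} from \code{\link{clusterGreedy}} or
#'   \code{\link{familiesFromBlast}}.
#' @param prevalence minimum fraction of genomes with at least one member.
#' @return A \linkS4class{FamilySet} restricted to the core families, with
#'   the \code{genomeReps} table filled in.
#' @export
selectCore <- function(fs, prevalence = 0.8) {
  prev <- prevalence(fs)
  keep <- names(prev)[prev >= prevalence]
  m <- fs@members[fs@members$family_id %in% keep, , drop = FALSE]
  reps <- fs@representatives[keep]
  gr <- do.call(rbind, lapply(split(m, m$family_id), function(sub) {
    picked <- do.call(rbind, lapply(split(sub, sub$genome_id), function(g) {
      o <- order(-g$rep_identity, -g$seq_length, g$seq_id, method = "radix")
      g[o[1L], c("family_id", "genome_id", "seq_id")]
    }))
    picked
  }))
  if (is.null(gr)) gr <- data.frame(family_id = character(),
                                    genome_id = character(),
                                    seq_id = character())
  rownames(gr) <- NULL
  new("FamilySet", members = m, representatives = reps,
      nGenomesTotal = fs@nGenomesTotal, genomeReps = gr)
}

#' Protein families from BLAST tabular hits
#'
#' Builds families as single-linkage connected components over hits passing
#' the e-value threshold; each surviving edge must additionally satisfy the
#' identity and coverage thresholds recomputed by global alignment of the two
#' sequences. Representatives and per-member statistics follow the same rules
#' as \code{\link{clusterGreedy}}; sequences without any qualifying hit form
#' singleton families.
#'
#' @param hits data.frame as returned by \code{\link{readBlastTab}}.
#' @param ps the \linkS4class{ProteomeSet} the hit ids refer to.
#' @param maxEvalue discard hits above this e-value (high-scoring homologue
#'   threshold, default 1e-20).
#' @param minIdentity,minCoverage edge thresholds.
#' @return A \linkS4class{FamilySet}.
#' @export
familiesFromBlast <- function(hits, ps, maxEvalue = 1e-20,
                              minIdentity = 0.5, minCoverage = 0.5) {
  seqs <- as.character(aaSequences(ps))
  ids <- names(seqs)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
  if (length(unknown))
    stop("hit id(s) not present in the ProteomeSet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keep <- hits$evalue <= maxEvalue & hits$query_id != hits$subject_id
  edges <- unique(hits[keep, c("query_id", "subject_id")])
  if (nrow(edges)) {
    ok <- vapply(seq_len(nrow(edges)), function(i) {
      ic <- pairwiseIdentity(seqs[[edges$query_id[i]]],
                             seqs[[edges$subject_id[i]]])
      ic[["identity"]] >= minIdentity && ic[["coverage"]] >= minCoverage
    }, logical(1L))
    edges <- edges[ok, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  sg <- genomeOf(ps)
  rows <- data.frame(family_id = sprintf("FAM%04d", unname(comp)),
                     seq_id = ids, genome_id = unname(sg[ids]),
                     seq_length = nchar(seqs),
                     rep_identity = NA_real_, rep_coverage = NA_real_)
  fs <- .newFamilySet(list(rows), length(genomeIds(ps)))
  # fill identity/coverage of every member against its representative
  m <- fs@members
  for (i in seq_len(nrow(m))) {
    rep <- fs@representatives[[m$family_id[i]]]
    if (m$seq_id[i] == rep) {
      m$rep_identity[i] <- 1; m$rep_coverage[i] <- 1
    } else {
      ic <- pairwiseIdentity(seqs[[m$seq_id[i]]], seqs[[rep]])
      m$rep_identity[i] <- ic[["identity"]]
      m$rep_coverage[i] <- ic[["coverage"]]
    }
  }
  new("FamilySet", members = m, representatives = fs@representatives,
      nGenomesTotal = fs@nGenomesTotal, genomeReps = fs@genomeReps)
}

#' Export a family table
#'
#' Writes the membership as TSV with columns family_id, genome_id, seq_id,
#' is_representative.
#'
#' @param fs a \linkS4class{FamilySet}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
exportFamilies <- function(fs, path) {
  m <- fs@members
  out <- data.frame(family_id = m$family_id, genome_id = m$genome_id,
                    seq_id = m$seq_id,
                    is_representative =
                      m$seq_id == fs@representatives[m$family_id])
  out <- out[order(out$family_id, out$genome_id, out$seq_id,
                   method = "radix"), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
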