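#' @import methods
#' @importFrom Biostrings AAStringSet readBStringSet writeXStringSet width
#' @importFrom stats hclust as.dist cutree setNames
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
GAP <- "-"

#' Scan parameters for conserved signature indel detection
#'
#' Holds the tunable thresholds of the CSI scanner: the width of the flanking
#' window inspected on each side of a candidate indel block, the minimum number
#' of conserved columns required in each window, the residue frequency a column
#' must reach to count as conserved, the admissible indel lengths, the number
#' of isolated out-of-clade exceptions tolerated, and whether clade members
#' lacking a homologue are tolerated.
#'
#' Defaults encode the classical CSI criterion: an indel of fixed length
#' flanked on both sides by at least four conserved residues within the
#' neighbouring 40 alignment columns, with strict (100%) column conservation
#' and no exceptions.
#'
#' @slot flankWindow integer, columns inspected each side of the block (40-50).
#' @slot minConservedFlank integer, conserved columns required per side.
#' @slot conservedFraction numeric in (0,1], residue frequency for conservation.
#' @slot maxIndelLen,minIndelLen integer, admissible block lengths in columns.
#' @slot maxExceptions integer, tolerated out-of-clade genomes sharing the
#'   clade state.
#' @slot allowMissing logical, tolerate clade genomes with no homologue.
#' @exportClass ScanParams
setClass("ScanParams", representation(
  flankWindow       = "integer",
  minConservedFlank = "integer",
  conservedFraction = "numeric",
  maxIndelLen       = "integer",
  minIndelLen       = "integer",
  maxExceptions     = "integer",
  allowMissing      = "logical"
))

setValidity("ScanParams", function(object) {
  msg <- character()
  if (object@minIndelLen < 1L)
    msg <- c(msg, "minIndelLen must be >= 1")
  if (object@maxIndelLen < object@minIndelLen)
    msg <- c(msg, "maxIndelLen must be >= minIndelLen")
  if (object@flankWindow < object@minConservedFlank)
    msg <- c(msg, "flankWindow must be >= minConservedFlank")
  if (object@flankWindow < 40L || object@flankWindow > 50L)
    msg <- c(msg, "flankWindow must be in [40, 50]")
  if (object@conservedFraction <= 0 || object@conservedFraction > 1)
    msg <- c(msg, "conservedFraction must be in (0, 1]")
  if (object@maxExceptions < 0L)
    msg <- c(msg, "maxExceptions must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct ScanParams
#'
#' @param flankWindow columns inspected on each side of a candidate block.
#' @param minConservedFlank conserved columns required on each side.
#' @param conservedFraction frequency a single residue must reach for a column
#'   to count as conserved ('X' never counts).
#' @param maxIndelLen,minIndelLen admissible indel lengths (alignment columns).
#' @param maxExceptions out-of-clade genomes allowed to share the clade state.
#' @param allowMissing tolerate clade members without a homologue (at least
#'   two clade rows must remain).
#' @return A \linkS4class{ScanParams} object.
#' @examples
#' scanParams()
#' scanParams(flankWindow = 50, maxExceptions = 1)
#' @export
scanParams <- function(flankWindow = 40, minConservedFlank = 4,
                       conservedFraction = 1.0, maxIndelLen = 10,
                       minIndelLen = 1, maxExceptions = 0,
                       allowMissing = TRUE) {
  new("ScanParams",
      flankWindow       = as.integer(flankWindow),
      minConservedFlank = as.integer(minConservedFlank),
      conservedFraction = as.numeric(conservedFraction),
      maxIndelLen       = as.integer(maxIndelLen),
      minIndelLen       = as.integer(minIndelLen),
      maxExceptions     = as.integer(maxExceptions),
      allowMissing      = isTRUE(allowMissing))
}

#' A set of proteomes with clade labels
#'
#' The input universe for the pipeline: one protein complement per genome,
#' a display name per genome, and a genome-to-clade assignment. Sequences are
#' stored as an \code{AAStringSet} named by sequence id; each sequence belongs
#' to exactly one genome and contains only the 20 amino-acid letters plus 'X'.
#'
#' @slot sequences AAStringSet named by seq_id (no gaps).
#' @slot seqGenome named character, seq_id -> genome_id.
#' @slot genomeTable data.frame with columns genome_id, display_name, clade.
#' @exportClass ProteomeSet
setClass("ProteomeSet", representation(
  sequences   = "AAStringSet",
  seqGenome   = "character",
  genomeTable = "data.frame"
))

setValidity("ProteomeSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be present and unique")
  if (!identical(sort(names(object@seqGenome)), sort(ids)))
    msg <- c(msg, "seqGenome must be named by exactly the sequence ids")
  gt <- object@genomeTable
  need <- c("genome_id", "display_name", "clade")
  if (!all(need %in% names(gt))) {
    msg <- c(msg, "genomeTable must have genome_id, display_name, clade")
  } else {
    if (anyDuplicated(gt$genome_id))
      msg <- c(msg, "duplicate genome_id in genomeTable")
    bad <- setdiff(unique(object@seqGenome), gt$genome_id)
    if (length(bad))
      msg <- c(msg, paste0("sequences assigned to unlisted genomes: ",
                           paste(bad, collapse = ", ")))
    if (any(is.na(gt$clade)) || any(gt$clade == ""))
      msg <- c(msg, "every genome needs a clade label")
  }
  if (length(object@sequences) &&
      any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "empty sequences are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteomeSet
#'
#' @param sequences AAStringSet (or named character vector) of ungapped
#'   protein sequences, named by unique sequence id.
#' @param seqGenome named character mapping each seq_id to its genome_id.
#' @param genomeTable data.frame with columns \code{genome_id},
#'   \code{display_name} (defaults to genome_id) and \code{clade}.
#' @return A \linkS4class{ProteomeSet}.
#' @export
proteomeSet <- function(sequences, seqGenome, genomeTable) {
  if (is.character(sequences)) sequences <- AAStringSet(sequences)
  if (!"display_name" %in% names(genomeTable))
    genomeTable$display_name <- genomeTable$genome_id
  genomeTable <- as.data.frame(
    genomeTable[c("genome_id", "display_name", "clade")])
  genomeTable[] <- lapply(genomeTable, as.character)
  .checkResidues(as.character(sequences), names(sequences))
  new("ProteomeSet", sequences = sequences,
      seqGenome = seqGenome[names(sequences)],
      genomeTable = genomeTable)
}

.checkResidues <- function(strs, ids) {
  ok <- paste0(c(AA20, "X"), collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), strs)
  if (any(bad)) {
    stop("invalid residue characters in sequence(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' A multiple sequence alignment of one protein family
#'
#' Rows are gapped protein sequences of equal width, named by sequence id;
#' the gap character is '-'. Removing gaps from a row reproduces the source
#' protein exactly.
#'
#' @slot familyId character, the family the alignment belongs to.
#' @slot aln AAStringSet of equal-width gapped rows, named by seq_id.
#' @exportClass Msa
setClass("Msa", representation(familyId = "character", aln = "AAStringSet"))

setValidity("Msa", function(object) {
  msg <- character()
  if (length(object@aln)) {
    w <- Biostrings::width(object@aln)
    if (length(unique(w)) != 1L)
      msg <- c(msg, "all alignment rows must have equal width")
    if (is.null(names(object@aln)) || anyDuplicated(names(object@aln)))
      msg <- c(msg, "alignment rows must be uniquely named")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Msa
#' @param rows named character vector (or AAStringSet) of equal-length gapped
#'   rows; '.' is normalised to '-'.
#' @param familyId family identifier.
#' @return An \linkS4class{Msa}.
#' @export
msa <- function(rows, familyId = "family") {
  if (is(rows, "AAStringSet")) rows <- as.character(rows)
  rows <- chartr(".", "-", toupper(rows))
  new("Msa", familyId = as.character(familyId), aln = AAStringSet(rows))
}

#' Protein families over a proteome set
#'
#' The outcome of clustering: a membership table (one row per sequence), the
#' representative (longest member) of every family, and, after core selection,
#' a per-genome best-representative table used for alignment and
#' concatenation.
#'
#' @slot members data.frame: family_id, seq_id, genome_id, seq_length,
#'   rep_identity, rep_coverage.
#' @slot representatives named character, family_id -> representative seq_id.
#' @slot nGenomesTotal integer, genomes in the universe (prevalence
#'   denominator).
#' @slot genomeReps data.frame: family_id, genome_id, seq_id (may be empty
#'   before \code{selectCore}).
#' @exportClass FamilySet
setClass("FamilySet", representation(
  members        = "data.frame",
  representatives = "character",
  nGenomesTotal  = "integer",
  genomeReps     = "data.frame"
))

setValidity("FamilySet", function(object) {
  msg <- character()
  m <- object@members
  need <- c("family_id", "seq_id", "genome_id", "seq_length",
            "rep_identity", "rep_coverage")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("members must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(m$seq_id))
      msg <- c(msg, "a sequence may belong to only one family")
    fam <- split(m, m$family_id)
    for (f in names(fam)) {
      rep <- object@representatives[[f]]
      sub <- fam[[f]]
      if (!rep %in% sub$seq_id) {
        msg <- c(msg, paste0("representative of ", f, " not a member"))
        next
      }
      lmax <- max(sub$seq_length)
      cand <- sort(sub$seq_id[sub$seq_length == lmax], method = "radix")[1L]
      if (!identical(rep, cand))
        msg <- c(msg, paste0("representative of ", f,
                             " is not the longest (tie: smallest id) member"))
    }
  }
  if (nrow(object@genomeReps) &&
      anyDuplicated(object@genomeReps[c("family_id", "genome_id")]))
    msg <- c(msg, "at most one representative per genome per family")
  if (length(msg)) msg else TRUE
})

#' Concatenated core-protein super-matrix
#'
#' Column-wise concatenation of trimmed per-family alignments, one row per
#' genome, with a partition table recording each family's column interval
#' (1-based inclusive). Genomes lacking a family carry '-' across that
#' partition.
#'
#' @slot aln AAStringSet of equal-width rows named by genome_id.
#' @slot partitions data.frame: family_id, start, end.
#' @exportClass SuperMatrix
setClass("SuperMatrix", representation(
  aln        = "AAStringSet",
  partitions = "data.frame"
))

setValidity("SuperMatrix", function(object) {
  msg <- character()
  if (!length(object@aln)) return("super-matrix must contain at least one row")
  w <- unique(Biostrings::width(object@aln))
  if (length(w) != 1L)
    msg <- c(msg, "all rows must have equal width")
  p <- object@partitions
  if (!all(c("family_id", "start", "end") %in% names(p)))
    msg <- c(msg, "partitions must have family_id, start, end")
  else if (nrow(p)) {
    o <- order(p$start)
    p <- p[o, ]
    if (p$start[1L] != 1L || (length(w) == 1L && p$end[nrow(p)] != w) ||
        (nrow(p) > 1L && any(p$start[-1L] != p$end[-nrow(p)] + 1L)))
      msg <- c(msg, "partitions must tile [1, ncols] without overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Average amino-acid identity matrix
#'
#' Symmetric percentage matrix over genomes, computed from the core-protein
#' super-matrix, along with the count of columns where both genomes carry an
#' informative residue (the AAI denominator). An entry with zero overlap is
#' reported as NA.
#'
#' @slot values symmetric numeric matrix of percentages, diagonal 100.
#' @slot overlap symmetric integer matrix of both-present column counts.
#' @exportClass AaiMatrix
setClass("AaiMatrix", representation(
  values  = "matrix",
  overlap = "matrix"
))

setValidity("AaiMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE)) ||
      !identical(object@overlap, t(object@overlap)))
    msg <- c(msg, "values and overlap must be symmetric")
  if (any(abs(diag(v) - 100) > 1e-9))
    msg <- c(msg, "diagonal must be 100")
  off <- v[upper.tri(v)]
  if (any(!is.na(off) & (off < 0 | off > 100)))
    msg <- c(msg, "values must lie in [0, 100]")
  if (any(is.na(off) != (object@overlap[upper.tri(v)] == 0L)))
    msg <- c(msg, "NA values must correspond exactly to zero overlap")
  if (length(msg)) msg else TRUE
})

#' A conserved signature indel record
#'
#' A detected (or planted) clade-specific indel: the family and alignment
#' block where it lies, its type and length, the reference sequence and the
#' 1-based residue interval of the flanked region in reference coordinates,
#' the target clade, any isolated out-of-clade exceptions, clade genomes with
#' no detected homologue, and the conserved-column counts of the two flanks.
#'
#' @slot familyId,referenceSeqId,clade character scalars.
#' @slot indelType "insertion" or "deletion" (clade state vs outgroup).
#' @slot indelLength integer, block length in alignment columns.
#' @slot blockStart,blockEnd integer, 1-based inclusive alignment columns.
#' @slot refStart,refEnd integer, 1-based inclusive residue interval in the
#'   reference sequence spanning block plus flank windows.
#' @slot exceptions,missing character vectors of genome ids.
#' @slot flankConserved integer length 2: conserved columns (left, right).
#' @exportClass CsiRecord
setClass("CsiRecord", representation(
  familyId       = "character",
  referenceSeqId = "character",
  indelType      = "character",
  indelLength    = "integer",
  blockStart     = "integer",
  blockEnd       = "integer",
  refStart       = "integer",
  refEnd         = "integer",
  clade          = "character",
  exceptions     = "character",
  missing        = "character",
  flankConserved = "integer"
))

setValidity("CsiRecord", function(object) {
  msg <- character()
  if (!object@indelType %in% c("insertion", "deletion"))
    msg <- c(msg, "indelType must be 'insertion' or 'deletion'")
  if (object@indelLength != object@blockEnd - object@blockStart + 1L)
    msg <- c(msg, "indelLength must equal blockEnd - blockStart + 1")
  if (object@blockStart < 1L)
    msg <- c(msg, "blockStart must be >= 1")
  if (object@refStart < 1L || object@refEnd < object@refStart)
    msg <- c(msg, "reference interval must be 1-based and non-empty")
  if (length(object@flankConserved) != 2L)
    msg <- c(msg, "flankConserved must have length 2 (left, right)")
  if (length(msg)) msg else TRUE
})

#' Construct a CsiRecord
#' @param familyId,referenceSeqId,clade character scalars.
#' @param indelType "insertion" or "deletion".
#' @param blockStart,blockEnd 1-based inclusive alignment column interval.
#' @param refStart,refEnd 1-based inclusive reference residue interval of the
#'   flanked region.
#' @param exceptions,missing character vectors of genome ids.
#' @param flankConserved integer length 2, conserved columns (left, right).
#' @return A \linkS4class{CsiRecord}.
#' @export
csiRecord <- function(familyId, referenceSeqId, indelType,
                      blockStart, blockEnd, refStart, refEnd, clade,
                      exceptions = character(), missing = character(),
                      flankConserved = c(NA_integer_, NA_integer_)) {
  new("CsiRecord",
      familyId = as.character(familyId),
      referenceSeqId = as.character(referenceSeqId),
      indelType = as.character(indelType),
      indelLength = as.integer(blockEnd) - as.integer(blockStart) + 1L,
      blockStart = as.integer(blockStart), blockEnd = as.integer(blockEnd),
      refStart = as.integer(refStart), refEnd = as.integer(refEnd),
      clade = as.character(clade),
      exceptions = as.character(exceptions),
      missing = as.character(missing),
      flankConserved = as.integer(flankConserved))
}

#' Ground-truth manifest of a planted simulation
#'
#' Records what the generator planted: the seed, one \linkS4class{CsiRecord}
#' per planted indel (as the scanner should report it), the removed
#' (family, genome) homologues, and the (family, genome) isolated exceptions.
#'
#' @slot seed integer.
#' @slot records list of CsiRecord.
#' @slot missing data.frame: family_id, genome_id.
#' @slot exceptions data.frame: family_id, genome_id.
#' @exportClass TruthManifest
setClass("TruthManifest", representation(
  seed       = "integer",
  records    = "list",
  missing    = "data.frame",
  exceptions = "data.frame"
))

#' Clade-structured simulation design
#'
#' Describes the tree the generator uses: a star of clade ancestors hanging
#' off the root, each ancestor separated from the root by the between-clade
#' substitution fraction and each genome from its ancestor by the
#' within-clade fraction.
#'
#' @slot sizes named integer, clade label -> number of genomes.
#' @slot withinRate,betweenRate numeric per-branch substitution fractions.
#' @exportClass CladeSpec
setClass("CladeSpec", representation(
  sizes       = "integer",
  withinRate  = "numeric",
  betweenRate = "numeric"
))

setValidity("CladeSpec", function(object) {
  msg <- character()
  if (sum(object@sizes) < 4L)
    msg <- c(msg, "total genomes must be >= 4")
  if (is.null(names(object@sizes)) || anyDuplicated(names(object@sizes)))
    msg <- c(msg, "clade labels must be present and unique")
  if (any(c(object@withinRate, object@betweenRate) < 0) ||
      any(c(object@withinRate, object@betweenRate) > 0.95))
    msg <- c(msg, "rates must lie in [0, 0.95]")
  if (length(msg)) msg else TRUE
})

#' Construct a CladeSpec
#'
#' The default is the study design used throughout the package's validation:
#' 30 genomes in five clades (8 + 6 + 5 + 4 + 7) with a within-clade
#' substitution fraction of 0.03 and a between-clade fraction of 0.12 per
#' branch, which yields intra-clade AAI in the low-to-mid 90s and inter-clade
#' AAI in the 60-75% band, matching the spread seen across real
#' congeneric/confamilial proteomes.
#'
#' @param sizes named integer vector, clade label -> genome count.
#' @param withinRate per-branch substitution fraction ancestor -> genome.
#' @param betweenRate per-branch substitution fraction root -> clade ancestor.
#' @return A \linkS4class{CladeSpec}.
#' @examples
#' cladeSpec()
#' cladeSpec(c(A = 3, B = 3), withinRate = 0.01, betweenRate = 0.2)
#' @export
cladeSpec <- function(sizes = c(sensu_stricto = 8L, clade_A = 6L,
                                clade_B = 5L, clade_C = 4L, outgroup = 7L),
                      withinRate = 0.03, betweenRate = 0.12) {
  new("CladeSpec", sizes = setNames(as.integer(sizes), names(sizes)),
      withinRate = as.numeric(withinRate),
      betweenRate = as.numeric(betweenRate))
}
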