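#' @include AllClasses.R
NULL

#' Read a protein FASTA file
#'
#' Reads one FASTA file of ungapped protein sequences. The header token before
#' the first whitespace becomes the sequence id; lowercase residues are
#' uppercased; a terminal '*' (stop) is stripped silently. Duplicate ids and
#' characters outside the 20 amino-acid letters plus 'X' are errors.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return A named \code{AAStringSet}, one element per record, in file order.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">s1 desc", "MKV"), tf)
#' readProteinFasta(tf)
#' @export
readProteinFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  strs <- toupper(as.character(raw))
  strs <- sub("\\*$", "", strs)
  if (any(grepl("\\*", strs)))
    stop("internal '*' in sequence(s): ",
         paste(ids[grepl("\\*", strs)], collapse = ", "), call. = FALSE)
  .checkResidues(strs, ids)
  if (any(nchar(strs) == 0L))
    stop("empty sequence(s): ", paste(ids[nchar(strs) == 0L], collapse = ", "),
         call. = FALSE)
  AAStringSet(stats::setNames(strs, ids))
}

#' Write protein sequences as FASTA
#'
#' @param seqs named AAStringSet or character vector.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a proteome directory into a ProteomeSet
#'
#' Expects one \code{<genome_id>.faa} FASTA file per genome plus a
#' \code{clade_map.tsv} with columns \code{genome_id}, \code{clade} and
#' optionally \code{display_name}.
#'
#' @param dir directory written by \code{\link{writeProteomeSet}} (or
#'   assembled by hand in the same layout).
#' @return A \linkS4class{ProteomeSet}.
#' @export
readProteomeSet <- function(dir) {
  cmPath <- file.path(dir, "clade_map.tsv")
  if (!file.exists(cmPath)) stop("missing ", cmPath, call. = FALSE)
  gt <- utils::read.delim(cmPath, colClasses = "character")
  seqs <- character(); sg <- character()
  for (g in gt$genome_id) {
    fa <- readProteinFasta(file.path(dir, paste0(g, ".faa")))
    seqs <- c(seqs, stats::setNames(as.character(fa), names(fa)))
    sg <- c(sg, stats::setNames(rep(g, length(fa)), names(fa)))
  }
  proteomeSet(AAStringSet(seqs), sg, gt)
}

#' Write a ProteomeSet as a proteome directory
#'
#' One FASTA per genome plus \code{clade_map.tsv}; the inverse of
#' \code{\link{readProteomeSet}}.
#'
#' @param ps a \linkS4class{ProteomeSet}.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeProteomeSet <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sg <- genomeOf(ps)
  for (g in genomeIds(ps)) {
    ids <- names(sg)[sg == g]
    writeProteinFasta(aaSequences(ps)[ids], file.path(dir, paste0(g, ".faa")))
  }
  utils::write.table(ps@genomeTable, file.path(dir, "clade_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the 12-column tab-separated BLAST tabular dialect (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Rows with e-value above \code{maxEvalue} are dropped; extra trailing
#' columns are ignored with a warning; fewer than 12 columns is a parse error
#' naming the line.
#'
#' @param path path to the tabular file.
#' @param maxEvalue keep only hits with evalue <= this threshold.
#' @return data.frame with columns query_id, subject_id, percent_identity,
#'   align_len, evalue, bitscore.
#' @export
readBlastTab <- function(path, maxEvalue = Inf) {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "",
                            quote = "")
  if (is.null(nf) || length(nf) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), align_len = integer(),
                      evalue = numeric(), bitscore = numeric()))
  short <- which(nf < 12L)
  if (length(short))
    stop("line ", short[1L], " of ", path, " has ", nf[short[1L]],
         " columns; 12 expected (outfmt 6)", call. = FALSE)
  if (any(nf > 12L))
    warning("ignoring extra columns beyond 12 in ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", comment.char = "", quote = "",
                           colClasses = "character", fill = TRUE)
  hits <- data.frame(query_id = tab[[1L]], subject_id = tab[[2L]],
                     percent_identity = as.numeric(tab[[3L]]),
                     align_len = as.integer(tab[[4L]]),
                     evalue = as.numeric(tab[[11L]]),
                     bitscore = as.numeric(tab[[12L]]))
  if (any(hits$evalue < 0) || any(is.na(hits$evalue)))
    stop("invalid e-value in ", path, call. = FALSE)
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100))
    stop("percent identity outside [0, 100] in ", path, call. = FALSE)
  hits[hits$evalue <= maxEvalue, , drop = FALSE]
}

#' Read an aligned FASTA file as an Msa
#'
#' Adapter for externally produced alignments: any aligned FASTA of the same
#' members behaves identically downstream. '.' gaps are normalised to '-'.
#'
#' @param path aligned FASTA path.
#' @param familyId family identifier to attach.
#' @return An \linkS4class{Msa}.
#' @export
readMsaFasta <- function(path, familyId = "family") {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate row id(s) in ", path, call. = FALSE)
  msa(stats::setNames(as.character(raw), ids), familyId = familyId)
}

#' Write an Msa as aligned FASTA
#' @param x an \linkS4class{Msa}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMsaFasta <- function(x, path) {
  Biostrings::writeXStringSet(x@aln, path)
  invisible(path)
}

#' Write a super-matrix for external tree inference
#'
#' Writes the concatenated alignment as aligned FASTA or relaxed PHYLIP
#' (header line "n_taxa n_cols", then "name<space>sequence" rows) and the
#' partition table alongside as TSV (family_id, start, end). Output is
#' byte-deterministic for fixed input.
#'
#' @param sm a \linkS4class{SuperMatrix}.
#' @param path output alignment path.
#' @param format "fasta" or "phylip".
#' @param partitionsPath output path for the partition TSV.
#' @return Invisibly, \code{path}.
#' @export
writeSuperMatrix <- function(sm, path, format = c("fasta", "phylip"),
                             partitionsPath = paste0(path, ".partitions.tsv")) {
  format <- match.arg(format)
  if (!length(sm@aln)) stop("empty super-matrix", call. = FALSE)
  if (format == "fasta") {
    Biostrings::writeXStringSet(sm@aln, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(length(sm@aln), Biostrings::width(sm@aln)[1L]), con)
    writeLines(paste(names(sm@aln), as.character(sm@aln)), con)
  }
  utils::write.table(sm@partitions, partitionsPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA super-matrix back
#'
#' @param path aligned FASTA written by \code{\link{writeSuperMatrix}}.
#' @param partitionsPath the partition TSV written alongside.
#' @return A \linkS4class{SuperMatrix}.
#' @export
readSuperMatrix <- function(path, partitionsPath = paste0(path, ".partitions.tsv")) {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  p <- utils::read.delim(partitionsPath,
                         colClasses = c("character", "integer", "integer"))
  new("SuperMatrix",
      aln = AAStringSet(stats::setNames(chartr(".", "-",
                                               toupper(as.character(raw))),
                                        ids)),
      partitions = p)
}

#' Read/write ScanParams as JSON
#' @param path JSON file path.
#' @return \code{readScanParams}: a \linkS4class{ScanParams}.
#' @export
readScanParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scanParams, x)
}

#' @rdname readScanParams
#' @param params a \linkS4class{ScanParams}.
#' @export
writeScanParams <- function(params, path) {
  jsonlite::write_json(list(
    flankWindow = params@flankWindow,
    minConservedFlank = params@minConservedFlank,
    conservedFraction = params@conservedFraction,
    maxIndelLen = params@maxIndelLen, minIndelLen = params@minIndelLen,
    maxExceptions = params@maxExceptions,
    allowMissing = params@allowMissing), path, auto_unbox = TRUE)
  invisible(path)
}

.recordToList <- function(r) list(
  family_id = r@familyId, reference_seq_id = r@referenceSeqId,
  indel_type = r@indelType, indel_length = r@indelLength,
  block_start = r@blockStart, block_end = r@blockEnd,
  ref_start = r@refStart, ref_end = r@refEnd, clade = r@clade,
  exceptions = I(r@exceptions), missing = I(r@missing),
  flank_conserved = I(r@flankConserved))

.recordFromList <- function(x) csiRecord(
  familyId = x$family_id, referenceSeqId = x$reference_seq_id,
  indelType = x$indel_type, blockStart = x$block_start,
  blockEnd = x$block_end, refStart = x$ref_start, refEnd = x$ref_end,
  clade = x$clade, exceptions = unlist(x$exceptions),
  missing = unlist(x$missing),
  flankConserved = unlist(x$flank_conserved))

#' Read/write a TruthManifest as JSON
#' @param path JSON file path.
#' @return \code{readTruthManifest}: a \linkS4class{TruthManifest}.
#' @export
readTruthManifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mk <- function(tab) {
    if (!length(tab)) return(data.frame(family_id = character(),
                                        genome_id = character()))
    do.call(rbind, lapply(tab, function(r)
      data.frame(family_id = r$family_id, genome_id = r$genome_id)))
  }
  new("TruthManifest", seed = as.integer(x$seed),
      records = lapply(x$records, .recordFromList),
      missing = mk(x$missing), exceptions = mk(x$exceptions))
}

#' @rdname readTruthManifest
#' @param manifest a \linkS4class{TruthManifest}.
#' @export
writeTruthManifest <- function(manifest, path) {
  df2l <- function(d) lapply(seq_len(nrow(d)), function(i)
    list(family_id = d$family_id[i], genome_id = d$genome_id[i]))
  jsonlite::write_json(list(
    seed = manifest@seed,
    records = lapply(manifest@records, .recordToList),
    missing = df2l(manifest@missing),
    exceptions = df2l(manifest@exceptions)), path, auto_unbox = TRUE)
  invisible(path)
}
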