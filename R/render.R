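#' @include AllClasses.R csiscan.R
NULL

#' Render a CSI alignment excerpt as text
#'
#' Produces a publication-style excerpt of the flanked region around a CSI:
#' the reference sequence on the top line, every other row showing '-' where
#' it matches the top line, the differing residue where it does not, and a
#' blank where it is gapped (so the indel block appears as a blank stretch in
#' the rows lacking it). A marker row of '*' flags the indel columns, the
#' header reports the reference-coordinate span, and long excerpts wrap into
#' fixed-width blocks. Output is deterministic.
#'
#' @param x the family \linkS4class{Msa}.
#' @param record a \linkS4class{CsiRecord} that validates against \code{x}.
#' @param labels optional named character, row id -> display label (e.g.
#'   "species name  accession"); labels must not contain \code{" | "}.
#' @param params \linkS4class{ScanParams} (supplies the flank window).
#' @param width residue columns per wrapped block.
#' @return character scalar, the rendered text block.
#' @export
renderCsiText <- function(x, record, labels = NULL,
                          params = scanParams(), width = 60) {
  rows <- msaRows(x)
  if (!record@referenceSeqId %in% names(rows))
    stop("record does not refer to a row of this alignment", call. = FALSE)
  if (record@blockEnd > ncol(x))
    stop("record block exceeds the alignment", call. = FALSE)
  if (is.null(labels))
    labels <- stats::setNames(names(rows), names(rows))
  if (any(grepl(" | ", labels, fixed = TRUE)))
    stop("labels must not contain ' | '", call. = FALSE)
  w <- params@flankWindow
  spanStart <- max(1L, record@blockStart - w)
  spanEnd <- min(ncol(x), record@blockEnd + w)
  span <- seq.int(spanStart, spanEnd)
  m <- .msaMatrix(x)[, span, drop = FALSE]
  refId <- record@referenceSeqId
  order <- c(refId, setdiff(names(rows), refId))
  top <- m[refId, ]
  disp <- matrix(" ", length(order), ncol(m),
                 dimnames = list(order, NULL))
  disp[1L, ] <- ifelse(top == GAP, " ", top)
  for (r in order[-1L]) {
    ch <- m[r, ]
    disp[r, ] <- ifelse(ch == GAP, " ",
                        ifelse(ch == top & top != GAP, "-", ch))
  }
  marker <- ifelse(span >= record@blockStart & span <= record@blockEnd,
                   "*", " ")
  lw <- max(nchar(labels[order]))
  pad <- function(s) formatC(s, width = lw, flag = "-")
  header <- sprintf("%s; %d aa %s; clade %s; ref %s:%d-%d",
                    record@familyId, record@indelLength,
                    if (record@indelType == "insertion") "Ins" else "Del",
                    record@clade, refId, record@refStart, record@refEnd)
  out <- header
  for (chunkStart in seq.int(1L, ncol(m), by = width)) {
    cols <- seq.int(chunkStart, min(ncol(m), chunkStart + width - 1L))
    out <- c(out, "",
             paste0(pad(""), " | ", paste0(marker[cols], collapse = "")))
    for (r in order)
      out <- c(out, paste0(pad(labels[[r]]), " | ",
                           paste0(disp[r, cols], collapse = "")))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# inverse of renderCsiText over the displayed span: reconstructs each row's
# characters ('-' for gaps) from a rendered block
.parseCsiText <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  seqLines <- grep(" | ", lines, fixed = TRUE, value = TRUE)
  labs <- sub(" \\|.*$", "", seqLines)
  labs <- sub("\\s+$", "", labs)
  seqs <- sub("^.*? \\| ", "", seqLines)
  isMarker <- labs == "" & grepl("^[* ]*$", seqs)
  seqLines <- seqLines[!isMarker]
  labs <- labs[!isMarker]; seqs <- seqs[!isMarker]
  order <- unique(labs)
  chunks <- stats::setNames(vector("list", length(order)), order)
  for (i in seq_along(labs))
    chunks[[labs[i]]] <- c(chunks[[labs[i]]], seqs[i])
  full <- vapply(chunks, paste0, character(1L), collapse = "")
  topCh <- strsplit(full[[1L]], "", fixed = TRUE)[[1L]]
  top <- ifelse(topCh == " ", GAP, topCh)
  out <- stats::setNames(character(length(order)), order)
  out[[1L]] <- paste0(top, collapse = "")
  for (k in seq_along(order)[-1L]) {
    ch <- strsplit(full[[k]], "", fixed = TRUE)[[1L]]
    dec <- ifelse(ch == " ", GAP, ifelse(ch == "-", top, ch))
    out[[k]] <- paste0(dec, collapse = "")
  }
  out
}

#' Export a CSI summary table
#'
#' One row per CSI in the style of a signature-indel summary table: protein
#' (or family) name, reference accession, indel size rendered as
#' "<n> aa Ins|Del", indel position as the reference-residue span
#' "<a>–<b>", the specificity (clade) label, and footnote flags: '*'
#' when an isolated exception is present in a distantly related genome,
#' '†' when the homologue was not detected in some clade genomes.
#' Records are sorted by (clade, family, start column), so the table is
#' stable under input reordering.
#'
#' @param records list of \linkS4class{CsiRecord}.
#' @param proteinNames optional named character, family_id -> protein name.
#' @param path optional output TSV path (written UTF-8).
#' @return data.frame (invisibly when \code{path} is given).
#' @export
exportCsiTable <- function(records, proteinNames = NULL, path = NULL) {
  if (length(records)) {
    o <- order(vapply(records, function(r) r@clade, character(1L)),
               vapply(records, function(r) r@familyId, character(1L)),
               vapply(records, function(r) r@blockStart, integer(1L)),
               method = "radix")
    records <- records[o]
  }
  rowFor <- function(r) {
    name <- if (!is.null(proteinNames) && r@familyId %in% names(proteinNames))
      proteinNames[[r@familyId]] else r@familyId
    data.frame(
      protein_name = name,
      accession = r@referenceSeqId,
      indel_size = sprintf("%d aa %s", r@indelLength,
                           if (r@indelType == "insertion") "Ins" else "Del"),
      indel_position = sprintf("%d–%d", r@refStart, r@refEnd),
      specificity = r@clade,
      footnote = paste0(if (length(r@exceptions)) "*" else "",
                        if (length(r@missing)) "†" else ""),
      exceptions = paste(r@exceptions, collapse = ","),
      missing = paste(r@missing, collapse = ","))
  }
  tab <- if (length(records)) do.call(rbind, lapply(records, rowFor)) else
    data.frame(protein_name = character(), accession = character(),
               indel_size = character(), indel_position = character(),
               specificity = character(), footnote = character(),
               exceptions = character(), missing = character())
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(tab))
  }
  tab
}

#' Export CSI flanked regions as FASTA
#'
#' Writes, for each record, the reference sequence's flanked region (the
#' residue span the record reports) as an ungapped FASTA record, for manual
#' confirmation searches against external databases.
#'
#' @param records list of \linkS4class{CsiRecord}.
#' @param msas named list of \linkS4class{Msa} (by family id).
#' @param path output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
exportCsiRegions <- function(records, msas, path) {
  seqs <- vapply(records, function(r) {
    rows <- msaRows(msas[[r@familyId]])
    ungapped <- gsub(GAP, "", rows[[r@referenceSeqId]], fixed = TRUE)
    substr(ungapped, r@refStart, r@refEnd)
  }, character(1L))
  ids <- vapply(records, function(r)
    sprintf("%s_%s_%d-%d", r@familyId, r@referenceSeqId, r@refStart,
            r@refEnd), character(1L))
  writeProteinFasta(stats::setNames(seqs, make.unique(ids)), path)
  invisible(path)
}
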