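#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics used across the package: genome ids, the
#' genome-to-clade map, sequence retrieval, prevalence, alignment dimensions,
#' AAI values and partitions.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname accessors
#' @export
setGeneric("cladeMap", function(x) standardGeneric("cladeMap"))
#' @rdname accessors
#' @export
setGeneric("aaSequences", function(x) standardGeneric("aaSequences"))
#' @rdname accessors
#' @export
setGeneric("genomeOf", function(x) standardGeneric("genomeOf"))
#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))
#' @rdname accessors
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))
#' @rdname accessors
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setGeneric("genomeReps", function(x) standardGeneric("genomeReps"))
#' @rdname accessors
#' @export
setGeneric("aaiValues", function(x) standardGeneric("aaiValues"))
#' @rdname accessors
#' @export
setGeneric("aaiOverlap", function(x) standardGeneric("aaiOverlap"))
#' @rdname accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))
#' @rdname accessors
#' @export
setGeneric("truthRecords", function(x) standardGeneric("truthRecords"))

#' @rdname accessors
setMethod("genomeIds", "ProteomeSet", function(x) x@genomeTable$genome_id)
#' @rdname accessors
setMethod("cladeMap", "ProteomeSet", function(x)
  stats::setNames(x@genomeTable$clade, x@genomeTable$genome_id))
#' @rdname accessors
setMethod("aaSequences", "ProteomeSet", function(x) x@sequences)
#' @rdname accessors
setMethod("genomeOf", "ProteomeSet", function(x) x@seqGenome)

#' @rdname accessors
setMethod("familyId", "Msa", function(x) x@familyId)
#' @rdname accessors
setMethod("msaRows", "Msa", function(x)
  stats::setNames(as.character(x@aln), names(x@aln)))
#' @rdname accessors
#' @export
setMethod("nrow", "Msa", function(x) length(x@aln))
#' @rdname accessors
#' @export
setMethod("ncol", "Msa", function(x)
  if (length(x@aln)) Biostrings::width(x@aln)[1L] else 0L)

#' @rdname accessors
setMethod("members", "FamilySet", function(x) x@members)
#' @rdname accessors
setMethod("representatives", "FamilySet", function(x) x@representatives)
#' @rdname accessors
setMethod("genomeReps", "FamilySet", function(x) x@genomeReps)
#' @rdname accessors
setMethod("familyIds", "FamilySet", function(x) names(x@representatives))
#' @rdname accessors
setMethod("prevalence", "FamilySet", function(x) {
  ng <- tapply(x@members$genome_id, x@members$family_id,
               function(g) length(unique(g)))
  stats::setNames(as.numeric(ng) / x@nGenomesTotal, names(ng))
})

#' @rdname accessors
setMethod("genomeIds", "SuperMatrix", function(x) names(x@aln))
#' @rdname accessors
setMethod("msaRows", "SuperMatrix", function(x)
  stats::setNames(as.character(x@aln), names(x@aln)))
#' @rdname accessors
setMethod("partitions", "SuperMatrix", function(x) x@partitions)
#' @rdname accessors
#' @export
setMethod("ncol", "SuperMatrix", function(x) Biostrings::width(x@aln)[1L])
#' @rdname accessors
#' @export
setMethod("nrow", "SuperMatrix", function(x) length(x@aln))

#' @rdname accessors
setMethod("genomeIds", "AaiMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("aaiValues", "AaiMatrix", function(x) x@values)
#' @rdname accessors
setMethod("aaiOverlap", "AaiMatrix", function(x) x@overlap)

#' @rdname accessors
setMethod("truthRecords", "TruthManifest", function(x) x@records)

#' @exportMethod show
setMethod("show", "ScanParams", function(object) {
  cat("ScanParams: flank window", object@flankWindow,
      "| min conserved flank", object@minConservedFlank,
      "| conserved fraction", object@conservedFraction, "\n",
      "  indel length", object@minIndelLen, "-", object@maxIndelLen,
      "aa | max exceptions", object@maxExceptions,
      "| allow missing:", object@allowMissing, "\n")
})

setMethod("show", "ProteomeSet", function(object) {
  cat("ProteomeSet:", length(genomeIds(object)), "genomes,",
      length(object@sequences), "protein sequences,",
      length(unique(object@genomeTable$clade)), "clades\n")
  cl <- table(object@genomeTable$clade)
  cat("  clades:", paste0(names(cl), " (", cl, ")", collapse = ", "), "\n")
})

setMethod("show", "Msa", function(object) {
  cat("Msa", object@familyId, ":", nrow(object), "rows x",
      ncol(object), "columns\n")
})

setMethod("show", "FamilySet", function(object) {
  cat("FamilySet:", length(object@representatives), "families over",
      nrow(object@members), "sequences (",
      object@nGenomesTotal, "genomes )\n")
})

setMethod("show", "SuperMatrix", function(object) {
  cat("SuperMatrix:", nrow(object), "genomes x", ncol(object),
      "aligned positions in", nrow(object@partitions), "partitions\n")
})

setMethod("show", "AaiMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat("AaiMatrix:", nrow(object@values), "genomes; AAI range",
      if (length(v)) sprintf("%.1f-%.1f%%", min(v, na.rm = TRUE),
                             max(v, na.rm = TRUE)) else "n/a", "\n")
})

setMethod("show", "CsiRecord", function(object) {
  cat(sprintf("CsiRecord %s: %d aa %s for clade '%s' at columns %d-%d (ref %s:%d-%d)\n",
              object@familyId, object@indelLength,
              if (object@indelType == "insertion") "Ins" else "Del",
              object@clade, object@blockStart, object@blockEnd,
              object@referenceSeqId, object@refStart, object@refEnd))
  if (length(object@exceptions))
    cat("  exceptions:", paste(object@exceptions, collapse = ", "), "\n")
  if (length(object@missing))
    cat("  missing homologue:", paste(object@missing, collapse = ", "), "\n")
})

setMethod("show", "TruthManifest", function(object) {
  cat("TruthManifest: seed", object@seed, "|",
      length(object@records), "planted CSIs |",
      nrow(object@missing), "missing homologues |",
      nrow(object@exceptions), "exceptions\n")
})

setMethod("show", "CladeSpec", function(object) {
  cat("CladeSpec:", paste0(names(object@sizes), ":", object@sizes,
                           collapse = ", "),
      "| within", object@withinRate, "| between", object@betweenRate, "\n")
})
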