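#' @include AllClasses.R families.R
NULL

.AAX <- c(AA20, "X")

# per-column residue frequency profile (21 x ncols); gaps carry zero mass
.profileFreq <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  nc <- ncol(m)
  f <- matrix(0, length(.AAX), nc, dimnames = list(.AAX, NULL))
  for (j in seq_len(nc)) {
    tab <- table(factor(m[, j], levels = .AAX))
    f[, j] <- as.numeric(tab) / nrow(m)
  }
  f
}

# affine-gap global profile-profile alignment; returns per-profile column
# index vectors with NA marking gap columns. Gap of length L costs
# open + ext * L. Deterministic tie-break: diagonal, then gap-in-B, then
# gap-in-A.
.alignProfiles <- function(fa, fb, open = 10, ext = 1) {
  S <- .blosum62()[.AAX, .AAX]
  n <- ncol(fa); m <- ncol(fb)
  s <- t(fa) %*% S %*% fb
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in B (consumes profile A)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in A (consumes profile B)
  M[1L, 1L] <- 0
  if (n) X[2L:(n + 1L), 1L] <- -open - ext * seq_len(n)
  if (m) Y[1L, 2L:(m + 1L)] <- -open - ext * seq_len(m)
  for (i in seq_len(n)) {
    prevBest <- pmax(M[i, ], X[i, ], Y[i, ])
    M[i + 1L, 2L:(m + 1L)] <- s[i, ] + prevBest[1L:m]
    X[i + 1L, ] <- pmax(M[i, ] - open - ext, X[i, ] - ext,
                        Y[i, ] - open - ext)
    # gap run along row i+1: Y[i+1, j] = max_{k<j} (best(M,X)[i+1,k]
    #   - open - ext*(j-k))
    base <- pmax(M[i + 1L, ], X[i + 1L, ]) - open + ext * (0L:m)
    cm <- cummax(base)
    Y[i + 1L, 2L:(m + 1L)] <- cm[1L:m] - ext * (1L:m)
  }
  eps <- 1e-9
  ai <- integer(0); bi <- integer(0)
  i <- n; j <- m
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                       Y[n + 1L, m + 1L]))
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      ai <- c(i, ai); bi <- c(j, bi)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which(prev >= max(prev) - eps)[1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ai <- c(i, ai); bi <- c(NA_integer_, bi)
      val <- X[i + 1L, j + 1L]
      cand <- c(M[i, j + 1L] - open - ext, X[i, j + 1L] - ext,
                Y[i, j + 1L] - open - ext)
      state <- which(cand >= val - eps)[1L]
      i <- i - 1L
    } else {
      ai <- c(NA_integer_, ai); bi <- c(j, bi)
      val <- Y[i + 1L, j + 1L]
      cand <- c(M[i + 1L, j] - open - ext, X[i + 1L, j] - open - ext,
                Y[i + 1L, j] - ext)
      state <- which(cand >= val - eps)[1L]
      j <- j - 1L
    }
    if (i == 0L && state == 1L && j > 0L) state <- 3L
    if (j == 0L && state == 1L && i > 0L) state <- 2L
  }
  list(a = ai, b = bi)
}

.expandRows <- function(rows, idx) {
  vapply(strsplit(rows, "", fixed = TRUE), function(ch) {
    out <- rep(GAP, length(idx))
    out[!is.na(idx)] <- ch[idx[!is.na(idx)]]
    paste0(out, collapse = "")
  }, character(1L))
}

# 3-mer cosine distance matrix used for the guide tree
.kmerDist <- function(strs, k = 3L) {
  n <- length(strs)
  counts <- lapply(strs, function(s) {
    if (nchar(s) < k) return(table(character()))
    kms <- substring(s, seq_len(nchar(s) - k + 1L),
                     seq.int(k, nchar(s)))
    table(kms)
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ci <- counts[[i]]; cj <- counts[[j]]
    common <- intersect(names(ci), names(cj))
    dot <- sum(as.numeric(ci[common]) * as.numeric(cj[common]))
    ni <- sqrt(sum(as.numeric(ci)^2)); nj <- sqrt(sum(as.numeric(cj)^2))
    cs <- if (ni > 0 && nj > 0) dot / (ni * nj) else 0
    d[i, j] <- d[j, i] <- 1 - cs
  }
  d
}

#' Progressive multiple sequence alignment of one family
#'
#' Aligns the members of a protein family progressively: a UPGMA guide tree
#' is built from cosine distances between 3-mer count vectors, then profiles
#' are merged bottom-up with global profile-profile alignment under BLOSUM62
#' scores and affine gap penalties (open 10, extend 1; a gap of length L
#' costs open + L * extend). Column scores are the frequency-weighted average
#' substitution score; gap characters carry zero mass. De-gapping any output
#' row reproduces its input sequence exactly, and the procedure is
#' deterministic.
#'
#' @param seqs named AAStringSet or character vector of at least two
#'   ungapped protein sequences.
#' @param familyId family identifier for the resulting alignment.
#' @param gapOpening,gapExtension affine gap penalties.
#' @return An \linkS4class{Msa} with rows in the input order.
#' @examples
#' alignFamily(c(a = "MKVLT", b = "MKLT"))
#' @export
alignFamily <- function(seqs, familyId = "family",
                        gapOpening = 10, gapExtension = 1) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (length(seqs) < 2L)
    stop("alignment needs at least two sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must be uniquely named", call. = FALSE)
  .checkResidues(seqs, ids)
  n <- length(seqs)
  if (n == 2L) {
    idx <- .alignProfiles(.profileFreq(seqs[1L]), .profileFreq(seqs[2L]),
                          open = gapOpening, ext = gapExtension)
    rows <- c(.expandRows(seqs[1L], idx$a), .expandRows(seqs[2L], idx$b))
    return(msa(stats::setNames(rows, ids), familyId = familyId))
  }
  d <- .kmerDist(unname(seqs))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profiles <- vector("list", n - 1L)
  leafProfile <- function(i) list(order = i, rows = unname(seqs[i]))
  getNode <- function(v) if (v < 0L) leafProfile(-v) else profiles[[v]]
  for (step in seq_len(n - 1L)) {
    a <- getNode(hc$merge[step, 1L])
    b <- getNode(hc$merge[step, 2L])
    idx <- .alignProfiles(.profileFreq(a$rows), .profileFreq(b$rows),
                          open = gapOpening, ext = gapExtension)
    profiles[[step]] <- list(order = c(a$order, b$order),
                             rows = c(.expandRows(a$rows, idx$a),
                                      .expandRows(b$rows, idx$b)))
  }
  final <- profiles[[n - 1L]]
  rows <- final$rows[order(final$order)]
  msa(stats::setNames(rows, ids), familyId = familyId)
}

#' Trim alignment columns by gap fraction
#'
#' Removes every column whose gap fraction exceeds \code{maxGapFraction};
#' columns without gaps are never removed. The column map records, for each
#' original column, its new index (NA when removed). Trimming at the same
#' threshold is idempotent.
#'
#' @param x an \linkS4class{Msa}.
#' @param maxGapFraction columns with a larger gap fraction are dropped.
#' @return list with elements \code{msa} (trimmed \linkS4class{Msa}) and
#'   \code{columnMap} (integer vector over the original columns).
#' @export
trimAlignment <- function(x, maxGapFraction = 0.2) {
  m <- .msaMatrix(x)
  gapFrac <- colMeans(m == GAP)
  keep <- gapFrac <= maxGapFraction
  if (!any(keep))
    stop("trimming removed every column; raise maxGapFraction",
         call. = FALSE)
  columnMap <- rep(NA_integer_, ncol(m))
  columnMap[keep] <- seq_len(sum(keep))
  list(msa = .matrixMsa(m[, keep, drop = FALSE], familyId = x@familyId),
       columnMap = columnMap)
}

#' Concatenate family alignments into a super-matrix
#'
#' Concatenates per-family alignments in lexicographic family-id order, one
#' row per genome; a genome absent from a family receives '-' across that
#' partition. Each alignment may contribute at most one row per genome.
#'
#' @param msas list of \linkS4class{Msa} (typically trimmed).
#' @param genomes genome order for the rows.
#' @param seqGenome named character mapping row (sequence) ids to genome ids;
#'   may be omitted when a \linkS4class{ProteomeSet} is given instead.
#' @param ps optional \linkS4class{ProteomeSet} supplying \code{genomes} and
#'   \code{seqGenome}.
#' @return A \linkS4class{SuperMatrix}.
#' @export
concatenateMsas <- function(msas, genomes = NULL, seqGenome = NULL,
                            ps = NULL) {
  if (!is.null(ps)) {
    if (is.null(genomes)) genomes <- genomeIds(ps)
    if (is.null(seqGenome)) seqGenome <- genomeOf(ps)
  }
  if (is.null(genomes) || is.null(seqGenome))
    stop("supply either ps or both genomes and seqGenome", call. = FALSE)
  if (!length(msas)) stop("no alignments to concatenate", call. = FALSE)
  fids <- vapply(msas, familyId, character(1L))
  o <- order(fids, method = "radix")
  msas <- msas[o]; fids <- fids[o]
  widths <- vapply(msas, ncol, integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  pieces <- matrix("", length(genomes), length(msas),
                   dimnames = list(genomes, NULL))
  for (k in seq_along(msas)) {
    rows <- msaRows(msas[[k]])
    gs <- unname(seqGenome[names(rows)])
    if (anyNA(gs))
      stop("unmapped row id(s) in family ", fids[k], ": ",
           paste(names(rows)[is.na(gs)], collapse = ", "), call. = FALSE)
    if (anyDuplicated(gs))
      stop("family ", fids[k], " has two rows for genome ",
           gs[duplicated(gs)][1L], call. = FALSE)
    filler <- strrep(GAP, widths[k])
    col <- stats::setNames(rep(filler, length(genomes)), genomes)
    col[gs[gs %in% genomes]] <- rows[gs %in% genomes]
    pieces[, k] <- col
  }
  rows <- apply(pieces, 1L, paste0, collapse = "")
  new("SuperMatrix",
      aln = AAStringSet(stats::setNames(rows, genomes)),
      partitions = data.frame(family_id = fids, start = starts,
                              end = ends))
}
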