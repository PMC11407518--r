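#' @include AllClasses.R
NULL

.rowChars <- function(sm) {
  rows <- msaRows(sm)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Average amino-acid identity of one genome pair
#'
#' Over the super-matrix columns where both genomes carry a residue other
#' than '-' and 'X', reports 100 times the fraction of exact matches. This is
#' identical to the length-weighted mean of per-family identities, the
#' weights being each family's count of qualifying columns. A pair with no
#' qualifying column is reported as NA with a message.
#'
#' @param sm a \linkS4class{SuperMatrix}.
#' @param g1,g2 genome ids present in the matrix.
#' @return Numeric percentage in [0, 100], or NA.
#' @export
aaiPair <- function(sm, g1, g2) {
  rows <- msaRows(sm)
  if (!all(c(g1, g2) %in% names(rows)))
    stop("genome(s) not in super-matrix: ",
         paste(setdiff(c(g1, g2), names(rows)), collapse = ", "),
         call. = FALSE)
  a <- strsplit(rows[[g1]], "", fixed = TRUE)[[1L]]
  b <- strsplit(rows[[g2]], "", fixed = TRUE)[[1L]]
  ok <- a != GAP & b != GAP & a != "X" & b != "X"
  if (!any(ok)) {
    message("no qualifying columns for pair ", g1, " / ", g2)
    return(NA_real_)
  }
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Full AAI matrix
#'
#' Computes \code{\link{aaiPair}} for every genome pair of a super-matrix.
#'
#' @param sm a \linkS4class{SuperMatrix} with at least two genomes.
#' @return An \linkS4class{AaiMatrix}.
#' @export
computeAaiMatrix <- function(sm) {
  m <- .rowChars(sm)
  if (nrow(m) < 2L) stop("need at least two genomes", call. = FALSE)
  g <- rownames(m)
  informative <- m != GAP & m != "X"
  storage.mode(informative) <- "numeric"
  ov <- tcrossprod(informative)
  matches <- matrix(0, nrow(m), nrow(m))
  for (l in AA20) {
    il <- informative * (m == l)
    matches <- matches + tcrossprod(il)
  }
  vals <- ifelse(ov > 0, 100 * matches / ov, NA_real_)
  if (any(ov[upper.tri(ov)] == 0))
    message("pair(s) with no qualifying columns reported as NA")
  diag(vals) <- 100
  dimnames(vals) <- list(g, g)
  ov <- matrix(as.integer(round(ov)), nrow(m), dimnames = list(g, g))
  new("AaiMatrix", values = vals, overlap = ov)
}

#' Export an AAI matrix as TSV
#' @param x an \linkS4class{AaiMatrix}.
#' @param path output path; genomes form the header row and first column.
#' @return Invisibly, \code{path}.
#' @export
exportAai <- function(x, path) {
  utils::write.table(cbind(genome_id = rownames(x@values),
                           as.data.frame(x@values)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-clade AAI range summary
#'
#' Summarises the AAI matrix per clade pair: intra-clade rows (clade_i ==
#' clade_j) use the unordered member pairs excluding self-comparisons and are
#' omitted (with a message) for singleton clades; inter-clade rows use all
#' cross pairs.
#'
#' @param x an \linkS4class{AaiMatrix}.
#' @param cladeMap named character, genome_id -> clade label.
#' @return data.frame with columns clade_i, clade_j, n_pairs, min, mean, max.
#' @export
cladeAaiSummary <- function(x, cladeMap) {
  g <- rownames(x@values)
  cl <- unname(cladeMap[g])
  if (anyNA(cl)) stop("genome(s) missing from cladeMap", call. = FALSE)
  labs <- unique(cl)
  out <- list()
  for (a in seq_along(labs)) {
    for (b in seq.int(a, length(labs))) {
      gi <- g[cl == labs[a]]; gj <- g[cl == labs[b]]
      if (a == b) {
        if (length(gi) < 2L) {
          message("singleton clade '", labs[a], "': intra row omitted")
          next
        }
        sub <- x@values[gi, gi, drop = FALSE]
        v <- sub[upper.tri(sub)]
      } else {
        v <- as.vector(x@values[gi, gj, drop = FALSE])
      }
      out[[length(out) + 1L]] <- data.frame(
        clade_i = labs[a], clade_j = labs[b], n_pairs = length(v),
        min = min(v), mean = mean(v), max = max(v))
    }
  }
  do.call(rbind, out)
}

#' Diagnostic neighbor-joining tree from AAI
#'
#' Builds a classic neighbor-joining tree on the distance d = 1 - AAI/100
#' and returns it in Newick format. Negative branch lengths produced by NJ
#' are clamped to zero. Any missing AAI value is an error: raise family
#' prevalence so that every genome pair shares columns.
#'
#' @param x an \linkS4class{AaiMatrix} without missing values.
#' @return Newick string (also readable with \code{ape::read.tree}).
#' @export
njTree <- function(x) {
  v <- x@values
  if (any(is.na(v)))
    stop("missing AAI value(s); raise core-family prevalence so all pairs ",
         "share columns", call. = FALSE)
  d <- 1 - v / 100
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::write.tree(tr)
}
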