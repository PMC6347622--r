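# Shared low-level helpers: pairwise sequence identity, classical scaling,
# and small internal utilities used across modules.

#' Percent identity between two nucleotide sequences
#'
#' Globally aligns two sequences and returns the percent identity computed
#' over aligned columns, excluding terminal (overhanging) gaps; internal gaps
#' count as mismatches. When both sequences have equal length and the
#' ungapped comparison scores at least as well as any gapped alignment would
#' (the common case for the mutation-only sequences this package simulates),
#' the column-wise comparison is used directly; otherwise
#' \code{Biostrings::pairwiseAlignment} performs the alignment.
#'
#' @param a,b Character scalars (nucleotide sequences, case-insensitive).
#' @return Percent identity in \code{[0, 100]}.
#' @export
seq_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence in seq_identity")
  if (nchar(a) == nchar(b)) {
    av <- charToRaw(a); bv <- charToRaw(b)
    return(100 * sum(av == bv) / length(av))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- !(pa == "-" & pb == "-")
  pa <- pa[keep]; pb <- pb[keep]
  if (!length(pa)) return(0)
  100 * sum(pa == pb) / length(pa)
}

#' Classical principal-coordinates analysis
#'
#' Thin wrapper around \code{stats::cmdscale} that keeps only axes with
#' positive eigenvalues and returns both coordinates and eigenvalues.
#'
#' @param d A distance matrix (symmetric numeric matrix or \code{dist}).
#' @param k Maximum number of axes (default: all positive-eigenvalue axes).
#' @return List with \code{points} (samples x axes) and \code{eig}.
#' @export
pcoa_coords <- function(d, k = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 samples for PCoA")
  # negative eigenvalues are routine for non-Euclidean (Jaccard)
  # distances; cmdscale's warning about them is noise here
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1,
                                         eig = TRUE))
  pos <- which(sc$eig > sqrt(.Machine$double.eps) * max(abs(sc$eig), 1))
  pos <- pos[pos <= ncol(sc$points)]
  if (!is.null(k)) pos <- pos[seq_len(min(k, length(pos)))]
  pts <- sc$points[, pos, drop = FALSE]
  rownames(pts) <- rownames(dm)
  list(points = pts, eig = sc$eig)
}

# Connected components of an undirected graph given as an adjacency matrix.
# Tiny union-find; adequate for the handfuls of genomes per phylotype.
.components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Deterministic sub-seed derivation: one user seed fans out to per-taxon /
# per-use streams without correlated draws. Kept below 2^31.
.subseed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  (as.integer(seed) * 10007L + as.integer(h %% 100003L)) %% 2147483629L
}

.msg <- function(...) message("[beediv] ", ...)
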