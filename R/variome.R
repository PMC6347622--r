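# Gene-content variability: normalization of gene-family coverage to the
# phylotype's terminus coverage, variome assignment, SDP correlation,
# genomic-island construction / occurrence, and variome-sharing distances.

#' Aggregate gene coverage to family coverage
#'
#' Raw family coverage is the sum of the member genes' coverages.
#'
#' @param cov Coverage matrix (genes x samples).
#' @param db A \code{ReferenceDB}.
#' @param families Family ids to aggregate (default: all).
#' @return Matrix family x sample.
#' @export
family_coverage <- function(cov, db, families = names(db$family_members)) {
  out <- matrix(0, length(families), ncol(cov),
                dimnames = list(families, colnames(cov)))
  for (f in families) {
    members <- intersect(db$family_members[[f]], rownames(cov))
    if (length(members))
      out[f, ] <- colSums(cov[members, , drop = FALSE])
  }
  out
}

#' Normalize family coverage to a 10x phylotype scale
#'
#' Linearly rescales each sample's family coverages so that the
#' phylotype's terminus coverage corresponds to 10x:
#' \code{normalized = raw * 10 / terminus}. Samples whose phylotype
#' terminus coverage is below \code{min_terminus} are excluded (logged).
#'
#' @param raw Matrix family x sample of raw (summed) family coverages.
#' @param terminus Named numeric vector sample -> phylotype terminus
#'   coverage.
#' @param min_terminus Inclusion threshold (default 10).
#' @return A \code{GeneFamilyMatrix} list: \code{normalized} (family x
#'   included samples), \code{raw} (same subset), \code{terminus},
#'   \code{excluded_samples}.
#' @export
normalize_families <- function(raw, terminus, min_terminus = 10) {
  samples <- colnames(raw)
  terminus <- terminus[samples]
  keep <- !is.na(terminus) & terminus >= min_terminus
  if (any(!keep))
    .msg("excluded ", sum(!keep), " sample(s) with phylotype terminus ",
         "coverage < ", min_terminus)
  stopifnot(all(terminus[keep] > 0))
  norm <- sweep(raw[, keep, drop = FALSE], 2, 10 / terminus[keep], "*")
  structure(list(normalized = norm, raw = raw[, keep, drop = FALSE],
                 terminus = terminus[keep],
                 excluded_samples = samples[!keep]),
            class = "GeneFamilyMatrix")
}

#' Assign the variome
#'
#' A family is variably associated with its phylotype (variome member)
#' when its normalized coverage falls below 1x — i.e. below 10% of the
#' phylotype abundance — in at least one included sample.
#'
#' @param m A \code{GeneFamilyMatrix}.
#' @return A \code{VariomeSet} list: \code{variable} (family ids),
#'   \code{min_normalized} (per family), \code{sdp_label} (NULL until
#'   \code{correlate_with_sdps}), \code{n_samples}.
#' @export
assign_variome <- function(m) {
  stopifnot(inherits(m, "GeneFamilyMatrix"), ncol(m$normalized) >= 1)
  mn <- apply(m$normalized, 1, min)
  structure(list(variable = rownames(m$normalized)[mn < 1],
                 min_normalized = mn, sdp_label = NULL,
                 n_samples = ncol(m$normalized)),
            class = "VariomeSet")
}

#' Correlate variome families with SDP abundances
#'
#' Pearson correlation between log10 raw family coverage and log10 SDP
#' terminus coverage across samples; a family is labelled with an SDP when
#' exactly one SDP exceeds \code{r_min}. Zeros are replaced by half the
#' smallest positive value of the respective matrix before the log.
#'
#' @param variome A \code{VariomeSet}.
#' @param m A \code{GeneFamilyMatrix} (raw coverages used).
#' @param sdp_terminus Matrix sample x sdp of SDP terminus coverages.
#' @param r_min Correlation threshold (default 0.8).
#' @return The \code{VariomeSet} with \code{sdp_label} filled (named
#'   character, NA where no unique SDP qualifies) and \code{sdp_r} (family
#'   x sdp correlation matrix).
#' @export
correlate_with_sdps <- function(variome, m, sdp_terminus, r_min = 0.8) {
  samples <- intersect(colnames(m$raw), rownames(sdp_terminus))
  if (length(samples) < 4)
    stop("need >= 4 samples for SDP correlation")
  logx <- function(x) {
    posmin <- suppressWarnings(min(x[x > 0]))
    if (!is.finite(posmin)) posmin <- 1
    log10(ifelse(x > 0, x, posmin / 2))
  }
  fams <- variome$variable
  fam_l <- logx(m$raw[fams, samples, drop = FALSE])
  sdp_l <- logx(sdp_terminus[samples, , drop = FALSE])
  rmat <- matrix(NA_real_, length(fams), ncol(sdp_l),
                 dimnames = list(fams, colnames(sdp_l)))
  for (f in fams) for (s in colnames(sdp_l)) {
    if (stats::sd(fam_l[f, ]) == 0 || stats::sd(sdp_l[, s]) == 0) next
    rmat[f, s] <- stats::cor(fam_l[f, ], sdp_l[, s])
  }
  label <- apply(rmat, 1, function(r) {
    hit <- which(!is.na(r) & r > r_min)
    if (length(hit) == 1) colnames(rmat)[hit] else NA_character_
  })
  variome$sdp_label <- label
  variome$sdp_r <- rmat
  variome
}

#' Build genomic islands from variome genes
#'
#' Within each genome, genes whose family belongs to the variome are
#' sorted by start; consecutive genes on the same contig with intergenic
#' gaps below \code{max_gap} bp are chained into an island. Island span
#' runs from the first gene start to the last gene end. Big islands have
#' length >= \code{big_min_length} and >= \code{big_min_genes} genes.
#' Among big islands, any island whose family set is a subset of another
#' big island's family set is removed (redundant copies of the same
#' island in several genomes); ties keep the longer island, then the
#' lexicographically smaller id.
#'
#' @param db A \code{ReferenceDB}.
#' @param variome A \code{VariomeSet} (or character vector of family
#'   ids).
#' @param max_gap Maximum intergenic distance joined (default 5000).
#' @param big_min_length,big_min_genes Big-island thresholds (defaults
#'   10000 bp and 5 genes).
#' @return Data frame of islands: island_id, genome_id, contig_id, start,
#'   end, length, n_genes, is_big, gene_ids, family_ids
#'   (comma-separated), redundant (TRUE for big islands removed by the
#'   subset rule).
#' @export
build_islands <- function(db, variome, max_gap = 5000,
                          big_min_length = 10000, big_min_genes = 5) {
  fams <- if (inherits(variome, "VariomeSet")) variome$variable
  else as.character(variome)
  g <- db$genes[!is.na(db$genes$family_id) &
                  db$genes$family_id %in% fams, , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(island_id = character(0), genome_id = character(0),
                      contig_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_genes = integer(0), is_big = logical(0),
                      gene_ids = character(0), family_ids = character(0),
                      redundant = logical(0)))
  g <- g[order(g$genome_id, g$contig_id, g$start), , drop = FALSE]
  rows <- list()
  for (key in unique(paste(g$genome_id, g$contig_id))) {
    sub <- g[paste(g$genome_id, g$contig_id) == key, , drop = FALSE]
    run_start <- 1L
    for (i in seq_len(nrow(sub))) {
      last <- i == nrow(sub)
      gap_next <- if (!last) sub$start[i + 1L] - sub$end[i] else Inf
      if (gap_next >= max_gap) {
        idx <- run_start:i
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = sub$genome_id[1], contig_id = sub$contig_id[1],
          start = min(sub$start[idx]), end = max(sub$end[idx]),
          n_genes = length(idx),
          gene_ids = paste(sub$gene_id[idx], collapse = ","),
          family_ids = paste(sub$family_id[idx], collapse = ","),
          stringsAsFactors = FALSE)
        run_start <- i + 1L
      }
    }
  }
  isl <- do.call(rbind, rows)
  isl$length <- isl$end - isl$start
  isl$is_big <- isl$length >= big_min_length & isl$n_genes >= big_min_genes
  isl$island_id <- sprintf("%s:%s:%d-%d", isl$genome_id, isl$contig_id,
                           isl$start, isl$end)
  isl$redundant <- FALSE
  big <- which(isl$is_big)
  if (length(big) > 1) {
    famsets <- lapply(strsplit(isl$family_ids[big], ","), unique)
    ord <- big[order(-isl$length[big], isl$island_id[big])]
    for (a in seq_along(big)) {
      ia <- big[a]
      if (isl$redundant[ia]) next
      for (ib in ord) {
        if (ib == ia || isl$redundant[ib]) next
        sa <- famsets[[a]]; sb <- famsets[[match(ib, big)]]
        if (all(sa %in% sb) &&
            (length(sa) < length(sb) ||
               isl$length[ia] < isl$length[ib] ||
               (isl$length[ia] == isl$length[ib] &&
                  isl$island_id[ia] > isl$island_id[ib]))) {
          isl$redundant[ia] <- TRUE
          break
        }
      }
    }
  }
  isl <- isl[, c("island_id", "genome_id", "contig_id", "start", "end",
                 "length", "n_genes", "is_big", "gene_ids", "family_ids",
                 "redundant")]
  rownames(isl) <- NULL
  isl
}

#' Island occurrence across samples
#'
#' An island is present in a sample when at least
#' \code{min_family_fraction} of its families have normalized coverage >=
#' \code{presence_threshold} (both boundaries inclusive).
#'
#' @param islands Island data.frame from \code{build_islands} (redundant
#'   big islands are skipped).
#' @param m A \code{GeneFamilyMatrix}.
#' @param presence_threshold Normalized-coverage presence cut (default 1).
#' @param min_family_fraction Fraction of island families required
#'   (default 0.8).
#' @return List: \code{present} (island x sample logical matrix),
#'   \code{frequency} (mean presence per island over included samples).
#' @export
island_occurrence <- function(islands, m, presence_threshold = 1.0,
                              min_family_fraction = 0.8) {
  isl <- islands[!islands$redundant, , drop = FALSE]
  samples <- colnames(m$normalized)
  pres <- matrix(NA, nrow(isl), length(samples),
                 dimnames = list(isl$island_id, samples))
  for (i in seq_len(nrow(isl))) {
    fams <- unique(strsplit(isl$family_ids[i], ",")[[1]])
    fams <- intersect(fams, rownames(m$normalized))
    if (!length(fams)) next
    sub <- m$normalized[fams, , drop = FALSE] >= presence_threshold
    pres[i, ] <- colMeans(sub) >= min_family_fraction
  }
  list(present = pres, frequency = rowMeans(pres))
}

#' Variome-sharing Jaccard distances
#'
#' Presence/absence of variome families (normalized coverage >=
#' \code{presence_threshold}) per sample, Jaccard distance on the
#' presence sets, and a PCoA embedding.
#'
#' @param m A \code{GeneFamilyMatrix}.
#' @param variome A \code{VariomeSet} (or family id vector).
#' @param presence_threshold Presence cut (default 1).
#' @return List: \code{dist} (sample x sample), \code{pcoa}
#'   (coordinates), \code{empty_samples} (samples with no variome family
#'   present; their distances are 1 and flagged).
#' @export
variome_distance <- function(m, variome, presence_threshold = 1.0) {
  fams <- if (inherits(variome, "VariomeSet")) variome$variable
  else as.character(variome)
  fams <- intersect(fams, rownames(m$normalized))
  samples <- colnames(m$normalized)
  if (length(samples) < 2) stop("need >= 2 included samples")
  pres <- t(m$normalized[fams, , drop = FALSE] >= presence_threshold)
  empty <- rownames(pres)[rowSums(pres) == 0]
  if (length(empty))
    .msg("sample(s) with empty variome presence: ",
         paste(empty, collapse = ", "))
  # vegdist warns about empty rows and yields NaN for empty pairs; empty
  # samples are flagged above and scored maximally dissimilar
  D <- as.matrix(suppressWarnings(
    vegan::vegdist(pres, method = "jaccard", binary = TRUE)))
  D[is.nan(D)] <- 1
  diag(D) <- 0
  pc <- if (nrow(D) >= 3) pcoa_coords(D)$points else NULL
  list(dist = D, pcoa = pc, empty_samples = empty)
}
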