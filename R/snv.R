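# Strain-level analysis: read-recruitment fractions, the SNV filter
# cascade, polymorphic-site fractions, cumulative diversity curves, the
# sampling-design comparison and shared-SNV Jaccard distances.

#' Read a candidate SNV table
#'
#' VCF-like TSV: columns taxon, gene_id, pos (1-based within gene), ref,
#' alt, then one numeric column per sample holding the intra-sample
#' alt-allele relative abundance. Multi-allelic sites arrive decomposed
#' into biallelic rows sharing a position.
#'
#' @param path TSV path.
#' @return Data frame in the candidate-SNV layout.
#' @export
read_snv_candidates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon", "gene_id", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("candidate SNV table must start with columns: ",
         paste(need, collapse = ", "))
  df
}

#' SNV filter cascade
#'
#' Applies, in order: (i) samples where the taxon's terminus coverage is
#' below \code{min_terminus_cov} are set wholly missing; (ii) within
#' eligible samples, sites in genes with mean coverage below
#' \code{min_gene_cov} are missing; (iii) intra-sample relative abundances
#' below \code{min_freq} are set to 0. Sites in genes outside the supplied
#' core families are dropped up front. A site is then retained only if it
#' stays polymorphic: scored in at least one sample, abundance >=
#' \code{min_freq} in at least one sample, and not fixed (not 1 in every
#' scored sample and not 0 in every scored sample).
#'
#' @param candidates Candidate SNV data.frame (see
#'   \code{read_snv_candidates}).
#' @param cov Coverage matrix (genes x samples), for rule (ii).
#' @param terminus_cov Named numeric vector sample -> taxon terminus
#'   coverage (or a matrix sample x taxon for multi-taxon tables).
#' @param core_families Character vector of core family ids; candidate
#'   rows whose gene belongs to none of them are dropped.
#' @param db A \code{ReferenceDB} (maps genes to families and checks
#'   positions against gene bounds).
#' @param min_terminus_cov Rule (i) threshold (default 10).
#' @param min_gene_cov Rule (ii) threshold (default 10).
#' @param min_freq Rule (iii) threshold (default 0.1).
#' @return An \code{SNVTable} list: \code{sites} (data.frame taxon,
#'   gene_id, pos, ref, alt), \code{abundance} (sites x samples matrix, NA
#'   = missing), \code{eligible} (logical per sample), \code{scored_bp}
#'   (per sample: total bp of core genes scored), \code{core_length}
#'   (total core bp), \code{ledger} (counts dropped per rule).
#' @export
filter_snvs <- function(candidates, cov, terminus_cov, core_families, db,
                        min_terminus_cov = 10, min_gene_cov = 10,
                        min_freq = 0.1) {
  samples <- setdiff(colnames(candidates),
                     c("taxon", "gene_id", "pos", "ref", "alt"))
  ab <- as.matrix(candidates[, samples, drop = FALSE])
  storage.mode(ab) <- "double"
  ledger <- c(non_core = 0, low_terminus_samples = 0, low_cov_gene = 0,
              low_freq_zeroed = 0, fixed_or_absent = 0)

  gene_fam <- db$genes$family_id[match(candidates$gene_id,
                                       db$genes$gene_id)]
  glen <- db$genes$length[match(candidates$gene_id, db$genes$gene_id)]
  if (any(is.na(glen)))
    stop("candidate SNV references unknown gene: ",
         candidates$gene_id[which(is.na(glen))[1]])
  if (any(candidates$pos < 1 | candidates$pos > glen))
    stop("candidate SNV position outside gene bounds (coordinate ",
         "mismatch): ",
         candidates$gene_id[which(candidates$pos > glen)[1]])
  in_core <- !is.na(gene_fam) & gene_fam %in% core_families
  ledger["non_core"] <- sum(!in_core)
  candidates <- candidates[in_core, , drop = FALSE]
  ab <- ab[in_core, , drop = FALSE]

  if (is.matrix(terminus_cov)) {
    # one taxon per row group; take per-sample terminus of each row's taxon
    ter <- terminus_cov[samples, , drop = FALSE]
    eligible_mat <- ter >= min_terminus_cov
    elig_of <- function(taxon) eligible_mat[, taxon]
  } else {
    ter <- terminus_cov[samples]
    elig <- ter >= min_terminus_cov
    elig_of <- function(taxon) elig
  }
  # rule (i)
  for (tx in unique(candidates$taxon)) {
    rows <- candidates$taxon == tx
    bad <- !elig_of(tx)
    ab[rows, bad] <- NA_real_
  }
  eligible <- vapply(samples, function(s)
    any(!is.na(ab[, s])), logical(1))
  ledger["low_terminus_samples"] <- sum(!eligible)

  # rule (ii): gene coverage in eligible samples. Scoring denominators
  # use the reduced database actually carrying the candidates (one
  # representative genome per taxon), not every genome in db
  ref_genomes <- unique(db$genes$genome_id[match(candidates$gene_id,
                                                 db$genes$gene_id)])
  core_genes <- db$genes$gene_id[!is.na(db$genes$family_id) &
                                   db$genes$family_id %in% core_families &
                                   db$genes$genome_id %in% ref_genomes]
  core_genes <- intersect(core_genes, rownames(cov))
  scored_bp <- stats::setNames(numeric(length(samples)), samples)
  for (s in samples) {
    if (!eligible[s]) { scored_bp[s] <- 0; next }
    gcov <- cov[core_genes, s]
    low_genes <- core_genes[gcov < min_gene_cov]
    rows <- candidates$gene_id %in% low_genes
    ledger["low_cov_gene"] <- ledger["low_cov_gene"] +
      sum(rows & !is.na(ab[, s]))
    ab[rows, s] <- NA_real_
    ok_genes <- core_genes[gcov >= min_gene_cov]
    scored_bp[s] <- sum(db$genes$length[match(ok_genes,
                                              db$genes$gene_id)])
  }

  # rule (iii)
  low <- !is.na(ab) & ab < min_freq & ab > 0
  ledger["low_freq_zeroed"] <- sum(low)
  ab[!is.na(ab) & ab < min_freq] <- 0

  # polymorphic retention
  keep <- apply(ab, 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(FALSE)
    if (max(r) < min_freq) return(FALSE)
    !(all(r >= 1) || all(r <= 0))
  })
  ledger["fixed_or_absent"] <- sum(!keep)

  sites <- candidates[keep, c("taxon", "gene_id", "pos", "ref", "alt"),
                      drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 abundance = ab[keep, , drop = FALSE],
                 eligible = eligible, scored_bp = scored_bp,
                 core_length = sum(db$genes$length[
                   match(core_genes, db$genes$gene_id)]),
                 min_freq = min_freq, ledger = ledger),
            class = "SNVTable")
}

#' @export
print.SNVTable <- function(x, ...) {
  cat("SNVTable:", nrow(x$sites), "polymorphic sites x",
      ncol(x$abundance), "samples (", sum(x$eligible), "eligible )\n")
  cat("  filter ledger:",
      paste(names(x$ledger), x$ledger, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# is a site "variable" within the sample subset `cols`?  yes when any
# scored abundance is intermediate, or both fixed states are observed
.site_variable <- function(row, cols) {
  r <- row[cols]
  r <- r[!is.na(r)]
  if (!length(r)) return(FALSE)
  any(r > 0 & r < 1) || (any(r >= 1) && any(r <= 0))
}

#' Fraction of polymorphic sites
#'
#' Per sample: sites with intermediate abundance (strictly between 0 and
#' 1, missing excluded) divided by the bp scored in that sample. Overall:
#' retained polymorphic sites divided by the total scored core length.
#'
#' @param table An \code{SNVTable}.
#' @param scope "per_sample" or "overall".
#' @return Named numeric vector (per sample) or a single fraction.
#' @export
polymorphic_fraction <- function(table,
                                 scope = c("overall", "per_sample")) {
  scope <- match.arg(scope)
  ab <- table$abundance
  if (scope == "overall") {
    if (table$core_length == 0) { warning("zero core length"); return(NA) }
    return(nrow(ab) / table$core_length)
  }
  out <- stats::setNames(rep(NA_real_, ncol(ab)), colnames(ab))
  for (s in colnames(ab)) {
    den <- table$scored_bp[s]
    if (is.na(den) || den == 0) {
      warning("sample ", s, ": no scored positions"); next
    }
    out[s] <- sum(!is.na(ab[, s]) & ab[, s] > 0 & ab[, s] < 1) / den
  }
  out
}

#' Cumulative diversity curves
#'
#' For each of \code{n_orders} random permutations of the eligible
#' samples, the cumulative fraction of variable sites (sites polymorphic
#' within the growing sample subset) after adding each sample. All orders
#' share the final value, the overall fraction.
#'
#' @param table An \code{SNVTable}.
#' @param n_orders Number of random sampling orders (default 10).
#' @param seed Integer seed.
#' @return Matrix n_orders x n_samples of cumulative fractions
#'   (denominator: total scored core length), with sample orders as
#'   attribute \code{orders}.
#' @export
cumulative_curves <- function(table, n_orders = 10, seed = 1) {
  ab <- table$abundance
  cols <- colnames(ab)[table$eligible[colnames(ab)]]
  if (length(cols) < 1) stop("no eligible samples")
  set.seed(as.integer(seed))
  orders <- lapply(seq_len(n_orders), function(i) sample(cols))
  den <- table$core_length
  curves <- matrix(NA_real_, n_orders, length(cols))
  for (o in seq_len(n_orders)) {
    ord <- orders[[o]]
    # incremental state per site: any intermediate seen; any 0 seen; any 1
    has_mid <- rep(FALSE, nrow(ab)); has0 <- has_mid; has1 <- has_mid
    for (j in seq_along(ord)) {
      v <- ab[, ord[j]]
      has_mid <- has_mid | (!is.na(v) & v > 0 & v < 1)
      has0 <- has0 | (!is.na(v) & v <= 0)
      has1 <- has1 | (!is.na(v) & v >= 1)
      curves[o, j] <- sum(has_mid | (has0 & has1)) / den
    }
  }
  attr(curves, "orders") <- orders
  curves
}

#' Compare real samplings with random subsets
#'
#' The fraction of variable sites is computed for each real sampling (the
#' bees collected together) and for \code{n_random} random subsets of
#' \code{subset_size} bees drawn from all eligible samples, then compared
#' with a two-sided Welch t test. Samplings with fewer than
#' \code{min_bees} eligible bees are skipped; the taxon is skipped when
#' fewer than \code{min_samplings} samplings survive.
#'
#' @param table An \code{SNVTable}.
#' @param metadata Data frame with sample_id and sampling_label columns.
#' @param n_random Number of random subsets (default 27).
#' @param subset_size Bees per random subset (default 6).
#' @param min_bees Minimum eligible bees per real sampling (default 5).
#' @param min_samplings Minimum usable samplings (default 6).
#' @param seed Integer seed.
#' @return List: \code{real} (named fractions per sampling),
#'   \code{random} (fractions), \code{t}, \code{p}, \code{skipped}
#'   (reason or NULL).
#' @export
sampling_subset_test <- function(table, metadata, n_random = 27,
                                 subset_size = 6, min_bees = 5,
                                 min_samplings = 6, seed = 1) {
  ab <- table$abundance
  elig <- colnames(ab)[table$eligible[colnames(ab)]]
  den <- table$core_length
  frac_of <- function(cols)
    sum(apply(ab, 1, .site_variable, cols = cols)) / den

  meta <- metadata[metadata$sample_id %in% elig, , drop = FALSE]
  groups <- split(meta$sample_id, meta$sampling_label)
  groups <- groups[lengths(groups) >= min_bees]
  if (length(groups) < min_samplings)
    return(list(real = NULL, random = NULL, t = NA, p = NA,
                skipped = sprintf(
                  "only %d samplings with >= %d eligible bees",
                  length(groups), min_bees)))
  real <- vapply(groups, frac_of, numeric(1))
  set.seed(as.integer(seed))
  rnd <- vapply(seq_len(n_random), function(i)
    frac_of(sample(elig, min(subset_size, length(elig)))), numeric(1))
  if (stats::sd(real) == 0 && stats::sd(rnd) == 0) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(real, rnd, var.equal = FALSE)
  }
  list(real = real, random = rnd, t = unname(tt$statistic),
       p = tt$p.value, skipped = NULL)
}

#' Shared-SNV Jaccard distance matrix
#'
#' A SNV is shared between two samples when its abundance is at least
#' \code{min_freq} in both; the distance is the number of sites present
#' (>= min_freq) in exactly one of the two samples divided by the number
#' of sites scored (non-missing) in both. A pair with no co-scored sites
#' gets a missing distance.
#'
#' @param table An \code{SNVTable}.
#' @param min_freq Presence threshold (default: the table's filter
#'   threshold).
#' @return List: \code{dist} (sample x sample matrix, NA where
#'   undefined), \code{pcoa} (coordinates from classical scaling on the
#'   complete-case submatrix, or NULL).
#' @export
shared_snv_distance <- function(table, min_freq = table$min_freq) {
  ab <- table$abundance
  cols <- colnames(ab)[table$eligible[colnames(ab)]]
  if (length(cols) < 2) stop("need >= 2 eligible samples")
  n <- length(cols)
  D <- matrix(NA_real_, n, n, dimnames = list(cols, cols))
  diag(D) <- 0
  pres <- !is.na(ab[, cols, drop = FALSE]) &
    ab[, cols, drop = FALSE] >= min_freq
  scored <- !is.na(ab[, cols, drop = FALSE])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    both <- scored[, i] & scored[, j]
    nb <- sum(both)
    if (nb == 0) next
    disc <- sum(both & (pres[, i] != pres[, j]))
    D[i, j] <- D[j, i] <- disc / nb
  }
  cc <- cols[apply(D, 1, function(r) !anyNA(r))]
  pc <- if (length(cc) >= 3)
    tryCatch(pcoa_coords(D[cc, cc])$points, error = function(e) NULL)
  else NULL
  list(dist = D, pcoa = pc)
}

#' Within-SDP read-recruitment fractions
#'
#' Normalizes per-genome mapped-read counts on core genes by each genome's
#' total core-gene length and converts them to relative fractions within
#' each SDP (columns sum to 1 per SDP wherever any reads mapped).
#'
#' @param counts Matrix genome x sample of mapped read counts on core
#'   genes.
#' @param core_gene_length Named vector genome_id -> total core-gene bp.
#' @param partition Named vector genome_id -> sdp_id.
#' @return Matrix genome x sample of within-SDP fractions.
#' @export
recruitment_fractions <- function(counts, core_gene_length, partition) {
  norm <- counts / core_gene_length[rownames(counts)]
  out <- norm
  for (sdp in unique(partition[rownames(counts)])) {
    rows <- rownames(counts)[partition[rownames(counts)] == sdp]
    tot <- colSums(norm[rows, , drop = FALSE])
    sc <- ifelse(tot > 0, tot, NA_real_)
    out[rows, ] <- sweep(norm[rows, , drop = FALSE], 2, sc, "/")
    out[rows, ][is.na(out[rows, ])] <- 0
  }
  out
}
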