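# Community-level statistics: greedy identity clustering of universal
# single-copy ortholog sequences, presence-absence beta-diversity with
# distance-to-centroid dispersion, PERMANOVA on distance matrices, and
# ANOVA / Welch t utilities.

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in decreasing length (ties broken by
#' lexicographic id) and assigned to the first existing centroid with
#' global-alignment identity >= \code{threshold}; otherwise they found a
#' new cluster. Deterministic given the input set.
#'
#' @param seqs Named character vector or \code{DNAStringSet}.
#' @param threshold Percent identity (default 95).
#' @return Data frame: seq_id, cluster_id, centroid_id, identity (to the
#'   centroid; 100 for the centroid itself).
#' @export
cluster_sequences <- function(seqs, threshold = 95.0) {
  nms <- names(seqs)
  v <- as.character(seqs)
  names(v) <- nms
  if (length(v) == 0)
    return(data.frame(seq_id = character(0), cluster_id = character(0),
                      centroid_id = character(0), identity = numeric(0)))
  if (is.null(names(v))) names(v) <- sprintf("seq%04d", seq_along(v))
  ord <- order(-nchar(v), names(v))
  v <- v[ord]
  centroid_ids <- character(0)
  assign <- character(length(v)); ident <- numeric(length(v))
  names(assign) <- names(v)
  for (i in seq_along(v)) {
    hit <- NA_character_; hit_id <- NA_real_
    for (c_id in centroid_ids) {
      pid <- seq_identity(v[[i]], v[[c_id]])
      if (pid >= threshold) { hit <- c_id; hit_id <- pid; break }
    }
    if (is.na(hit)) {
      centroid_ids <- c(centroid_ids, names(v)[i])
      assign[i] <- names(v)[i]; ident[i] <- 100
    } else {
      assign[i] <- hit; ident[i] <- hit_id
    }
  }
  data.frame(seq_id = names(v),
             cluster_id = paste0("clu_", assign),
             centroid_id = unname(assign),
             identity = ident, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Beta-dispersion of presence-absence tables
#'
#' Per gene-family table: Jaccard distances between samples, PCoA on the
#' positive-eigenvalue axes, Euclidean distance of each sample to its
#' group mean centroid in that space. Distances are pooled across tables
#' and compared across groups with one-way ANOVA.
#'
#' @param tables List of binary matrices (sample x cluster), one per
#'   universal gene family.
#' @param groups Named factor / character vector sample -> group.
#' @return List: \code{distances} (data.frame sample, family, group,
#'   distance), \code{anova} (list F, p, df), \code{flagged} (tables
#'   where all distances were 0).
#' @export
beta_dispersion <- function(tables, groups) {
  if (is.null(names(tables))) names(tables) <- seq_along(tables)
  res <- list(); flagged <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    samples <- rownames(tb)
    g <- groups[samples]
    if (length(unique(g)) < 2) stop("need >= 2 groups")
    D <- as.matrix(vegan::vegdist(tb, method = "jaccard", binary = TRUE))
    D[is.nan(D)] <- 0
    pts <- if (max(D) > 0) pcoa_coords(D)$points else
      matrix(0, length(samples), 1, dimnames = list(samples, NULL))
    dist_c <- numeric(length(samples))
    for (gr in unique(g)) {
      idx <- which(g == gr)
      ctr <- colMeans(pts[idx, , drop = FALSE])
      dist_c[idx] <- sqrt(rowSums(
        sweep(pts[idx, , drop = FALSE], 2, ctr)^2))
    }
    if (all(dist_c == 0)) flagged <- c(flagged, nm)
    res[[nm]] <- data.frame(sample = samples, family = nm, group = g,
                            distance = dist_c, stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, res)
  rownames(pooled) <- NULL
  if (stats::var(pooled$distance) == 0) {
    an <- list(F = NA_real_, p = NA_real_, df = NA,
               note = "all distances identical; F undefined")
  } else {
    fit <- stats::aov(distance ~ group, data = pooled)
    s <- summary(fit)[[1]]
    an <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
               df = s[["Df"]])
  }
  list(distances = pooled, anova = an, flagged = flagged)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the total sum of
#' squared distances is partitioned into between- and within-group parts
#' (\code{SS_total = sum(d^2)/n}, \code{SS_within = sum over groups of
#' within-group d^2 / n_g}), giving a pseudo-F; the p-value is the
#' permutation tail probability \code{(1 + #(F* >= F)) / (1 + n_perm)}
#' with rows/columns permuted jointly.
#'
#' @param d Distance matrix (square symmetric) or \code{dist}.
#' @param factor Grouping vector aligned with the samples (>= 2 levels).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List: \code{pseudo_F}, \code{R2}, \code{p}, \code{n_perm}.
#' @export
permanova <- function(d, factor, n_perm = 999, seed = 1) {
  D <- as.matrix(d)
  n <- nrow(D)
  g <- as.character(factor)
  stopifnot(length(g) == n)
  if (length(unique(g)) < 2) stop("factor needs >= 2 levels")
  if (any(table(g) < 2))
    warning("grouping has level(s) with a single sample")
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  k <- length(unique(g))
  ss_within <- function(gv) {
    s <- 0
    for (lev in unique(gv)) {
      idx <- which(gv == lev)
      if (length(idx) > 1)
        s <- s + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    s
  }
  f_stat <- function(gv) {
    sw <- ss_within(gv)
    sb <- ss_total - sw
    (sb / (k - 1)) / (sw / (n - k))
  }
  F_obs <- f_stat(g)
  set.seed(as.integer(seed))
  ge <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(g[sample.int(n)]) >= F_obs) ge <- ge + 1L
  }
  sw <- ss_within(g)
  list(pseudo_F = F_obs, R2 = (ss_total - sw) / ss_total,
       p = (1 + ge) / (1 + n_perm), n_perm = n_perm)
}

#' One-way ANOVA and Welch t utilities
#'
#' Standard one-way ANOVA (optionally after log10 transform) and, for two
#' groups, Welch's t test with Welch-Satterthwaite degrees of freedom.
#' Groups with fewer than 2 values are skipped.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector.
#' @param log10_transform Log-transform values first (default FALSE).
#' @return List: \code{anova} (F, p) and, when exactly two groups remain,
#'   \code{welch} (t, df, p).
#' @export
basic_tests <- function(values, groups, log10_transform = FALSE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  keep_levels <- names(which(table(groups) >= 2))
  skipped <- setdiff(unique(groups), keep_levels)
  sel <- groups %in% keep_levels
  values <- values[sel]; groups <- groups[sel]
  if (log10_transform) values <- log10(values)
  if (length(keep_levels) < 2) stop("need >= 2 groups with >= 2 values")
  if (stats::var(values) == 0) {
    an <- list(F = 0, p = 1)
  } else {
    fit <- summary(stats::aov(values ~ factor(groups)))[[1]]
    an <- list(F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1])
  }
  out <- list(anova = an, skipped_groups = skipped)
  if (length(keep_levels) == 2) {
    a <- values[groups == keep_levels[1]]
    b <- values[groups == keep_levels[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      out$welch <- list(t = 0, df = NA_real_, p = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      out$welch <- list(t = unname(tt$statistic),
                        df = unname(tt$parameter), p = tt$p.value)
    }
  }
  out
}
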