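# Abundance and replication estimation from positional core-gene coverage:
# summed family depths along a reference genome, a two-segment linear fit
# locating the replication terminus, terminus coverage as raw abundance and
# the origin/terminus coverage ratio (PTR) as a replication proxy.

#' Read a gene coverage table
#'
#' TSV with gene ids in the first column (named \code{gene_id}) and one
#' numeric column per sample (mean per-bp read depth). The table must come
#' from mapping with a minimum alignment length of 50 bp (and, for
#' SNV-grade tables, edit distance < 5); that filtering is the provenance
#' contract of the input, not re-done here.
#'
#' @param path TSV path.
#' @return Numeric matrix genes x samples.
#' @export
read_coverage <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative depths in coverage table")
  m
}

# summed depth per family for one sample; families: character vector;
# returns named numeric
.family_depth <- function(cov, sample, db, families, genomes = NULL) {
  out <- stats::setNames(numeric(length(families)), families)
  for (f in families) {
    members <- db$family_members[[f]]
    if (!is.null(genomes)) {
      gm <- db$genes$genome_id[match(members, db$genes$gene_id)]
      members <- members[gm %in% genomes]
    }
    present <- members %in% rownames(cov)
    if (!all(present)) {
      warning("genes missing from coverage table treated as depth 0: ",
              paste(utils::head(members[!present], 2), collapse = ", "))
    }
    members <- members[present]
    out[f] <- if (length(members)) sum(cov[members, sample]) else 0
  }
  out
}

#' Build a positional coverage profile for a taxon
#'
#' Sums the depths of all member genes of each retained core family and
#' places the sum at the family's gene midpoint on the designated reference
#' genome. Families with no gene on the reference are dropped with a
#' warning.
#'
#' @param cov Coverage matrix (genes x samples).
#' @param sample Sample id (column of \code{cov}).
#' @param db A \code{ReferenceDB}.
#' @param reference_genome Genome id whose coordinates order the profile.
#' @param families Core family ids to use (for SDP-level profiles, the
#'   cross-SDP-filtered set).
#' @param genomes Genomes whose member genes are summed (the taxon's own
#'   genomes; default NULL sums over all members, appropriate for
#'   single-SDP phylotypes).
#' @return A \code{CoverageProfile} data.frame (position, family_id, depth)
#'   ordered by position, with attributes \code{taxon},
#'   \code{genome_length}.
#' @export
build_profile <- function(cov, sample, db, reference_genome, families,
                          genomes = NULL) {
  if (!reference_genome %in% db$genome_ids)
    stop("no such reference genome: ", reference_genome)
  depths <- .family_depth(cov, sample, db, families, genomes)
  gmask <- db$genes$genome_id == reference_genome
  rows <- lapply(families, function(f) {
    members <- db$family_members[[f]]
    on_ref <- members[members %in% db$genes$gene_id[gmask]]
    if (!length(on_ref)) return(NULL)
    i <- match(on_ref[[1]], db$genes$gene_id)
    data.frame(position = (db$genes$start[i] + db$genes$end[i]) / 2,
               family_id = f, depth = unname(depths[f]),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " family(ies) absent from reference genome dropped")
  prof <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(prof) || nrow(prof) == 0)
    stop("no core families mapped onto reference genome")
  prof <- prof[order(prof$position), , drop = FALSE]
  rownames(prof) <- NULL
  L <- sum(Biostrings::width(db$genomes[[reference_genome]]))
  attr(prof, "taxon") <- reference_genome
  attr(prof, "genome_length") <- L
  class(prof) <- c("CoverageProfile", class(prof))
  prof
}

#' Two-segment linear fit of a coverage profile
#'
#' Grid search over candidate breakpoints (each observed position, the
#' outermost 5% of points excluded): ordinary least squares is fitted
#' separately to the points left and right of the candidate, and the
#' breakpoint minimising the total residual sum of squares is chosen.
#' \code{cov_ter} is the mean of the two fitted segment values at the
#' breakpoint; \code{cov_ori} the larger fitted value at the two profile
#' ends. The fit is valid when \code{cov_ori >= cov_ter}, \code{cov_ter >
#' 0} and the breakpoint lies within the central 80% of positions; an
#' invalid fit reports PTR = 1 and falls back to the median family depth as
#' abundance.
#'
#' @param profile A \code{CoverageProfile}.
#' @param min_points Minimum points with positive depth (default 20).
#' @param edge_exclude Fraction of points excluded from each end of the
#'   breakpoint grid (default 0.05).
#' @param central_window Fraction of the position range the breakpoint must
#'   fall in for validity (default 0.8).
#' @param log2_depth Fit on log2(depth) instead of depth (default FALSE;
#'   the default matches fitting mean coverage directly).
#' @return A \code{SegmentedFit} list: \code{breakpoint_position},
#'   \code{cov_ter}, \code{cov_ori}, \code{ptr}, \code{valid},
#'   \code{reason}, \code{fallback_abundance}, \code{rss}.
#' @export
fit_segmented <- function(profile, min_points = 20, edge_exclude = 0.05,
                          central_window = 0.8, log2_depth = FALSE) {
  x <- profile$position
  y <- profile$depth
  fallback <- stats::median(y)
  bad <- function(reason) {
    structure(list(breakpoint_position = NA_real_, cov_ter = NA_real_,
                   cov_ori = NA_real_, ptr = 1, valid = FALSE,
                   reason = reason, fallback_abundance = fallback,
                   rss = NA_real_),
              class = "SegmentedFit")
  }
  if (sum(y > 0) < min_points) return(bad("too_few_points"))
  if (log2_depth) y <- log2(pmax(y, .Machine$double.eps))
  n <- length(x)
  lo <- max(2L, ceiling(edge_exclude * n))
  hi <- min(n - 1L, floor((1 - edge_exclude) * n))
  if (hi - lo < 1L) return(bad("too_few_points"))

  # prefix sums make each candidate's two OLS fits O(1)
  cs <- function(v) cumsum(v)
  Sx <- cs(x); Sy <- cs(y); Sxx <- cs(x * x); Sxy <- cs(x * y)
  Syy <- cs(y * y)
  tot <- function(S, i, j) if (i > j) 0 else S[j] - if (i > 1) S[i - 1] else 0
  seg_fit <- function(i, j) {
    m <- j - i + 1
    sx <- tot(Sx, i, j); sy <- tot(Sy, i, j)
    sxx <- tot(Sxx, i, j); sxy <- tot(Sxy, i, j); syy <- tot(Syy, i, j)
    den <- m * sxx - sx^2
    if (abs(den) < 1e-12) {
      b <- 0; a <- sy / m
    } else {
      b <- (m * sxy - sx * sy) / den
      a <- (sy - b * sx) / m
    }
    rss <- syy - 2 * (a * sy + b * sxy) + m * a^2 + 2 * a * b * sx +
      b^2 * sxx
    list(a = a, b = b, rss = max(rss, 0))
  }

  best_rss <- Inf; best_k <- NA_integer_
  for (k in lo:hi) {
    rss <- seg_fit(1L, k)$rss + seg_fit(k + 1L, n)$rss
    if (rss < best_rss) { best_rss <- rss; best_k <- k }
  }
  # exact refinement near the coarse optimum: the prefix-sum RSS loses
  # precision on large position scales, which matters when several
  # candidates tie (flat or exactly piecewise-linear data); recompute
  # residuals directly and resolve ties toward the profile centre
  ols_exact <- function(idx) {
    xx <- x[idx]; yy <- y[idx]
    xc <- xx - mean(xx)
    b <- if (sum(xc^2) < 1e-12) 0 else sum(xc * yy) / sum(xc^2)
    a <- mean(yy) - b * mean(xx)
    list(a = a, b = b, rss = sum((yy - a - b * xx)^2))
  }
  cand <- intersect((best_k - 5L):(best_k + 5L), lo:hi)
  # also consider the most central candidate, so exact ties (e.g. a
  # constant profile) settle on a central breakpoint
  center_k <- lo:hi
  center_k <- center_k[which.min(abs(x[center_k] - mean(range(x))))]
  cand <- union(cand, center_k)
  cand <- cand[order(abs(x[cand] - mean(range(x))))]
  best <- NULL; best_rss <- Inf; best_k <- NA_integer_
  for (k in cand) {
    fl <- ols_exact(1:k); fr <- ols_exact((k + 1L):n)
    rss <- fl$rss + fr$rss
    if (rss < best_rss * (1 - 1e-9) - 1e-12) {
      best_rss <- rss; best <- list(left = fl, right = fr); best_k <- k
    }
  }
  bp <- x[best_k]
  pred <- function(f, xx) f$a + f$b * xx
  cov_ter <- (pred(best$left, bp) + pred(best$right, bp)) / 2
  cov_ori <- max(pred(best$left, x[1]), pred(best$right, x[n]))
  if (log2_depth) { cov_ter <- 2^cov_ter; cov_ori <- 2^cov_ori }

  rng <- range(x)
  margin <- (1 - central_window) / 2
  in_window <- bp >= rng[1] + margin * diff(rng) &
    bp <= rng[2] - margin * diff(rng)
  reason <- NULL
  if (!in_window) reason <- "breakpoint_outside_central_window"
  if (cov_ter <= 0) reason <- c(reason, "nonpositive_terminus_coverage")
  if (cov_ori < cov_ter) reason <- c(reason, "origin_below_terminus")
  if (!is.null(reason)) {
    out <- bad(paste(reason, collapse = ";"))
    out$breakpoint_position <- bp
    out$cov_ter <- cov_ter; out$cov_ori <- cov_ori; out$rss <- best_rss
    return(out)
  }
  structure(list(breakpoint_position = bp, cov_ter = cov_ter,
                 cov_ori = cov_ori, ptr = cov_ori / cov_ter, valid = TRUE,
                 reason = "ok",
                 fallback_abundance = stats::median(profile$depth),
                 rss = best_rss),
            class = "SegmentedFit")
}

#' @export
print.SegmentedFit <- function(x, ...) {
  cat("SegmentedFit:", if (x$valid) "valid" else paste0("invalid (",
                                                        x$reason, ")"),
      "\n  breakpoint:", round(x$breakpoint_position, 1),
      " cov_ter:", round(x$cov_ter, 3), " cov_ori:", round(x$cov_ori, 3),
      " PTR:", round(x$ptr, 3), "\n")
  invisible(x)
}

#' Presence call and abundance for one taxon in one sample
#'
#' A taxon is present when at least \code{min_presence} of its core
#' families have mean depth > 1 (equivalently: it is set absent when more
#' than 20% of the quantification families fall below 1x). When present,
#' abundance is the terminus coverage of a valid segmented fit, or the
#' median family depth otherwise; when absent, abundance is 0 and PTR is
#' reported missing.
#'
#' @param cov Coverage matrix.
#' @param sample Sample id.
#' @param db A \code{ReferenceDB}.
#' @param reference_genome Reference genome id for the taxon (NULL for
#'   draft-genome taxa without positional order: abundance is then the
#'   median family depth and PTR is missing).
#' @param families Core family ids used for quantification.
#' @param genomes Genomes whose member genes are summed (see
#'   \code{build_profile}).
#' @param min_presence Fraction of families that must exceed 1x depth
#'   (default 0.8).
#' @param ... Passed to \code{fit_segmented}.
#' @return List: \code{abundance}, \code{present}, \code{ptr} (NA when
#'   absent or unfit), \code{fit} (the SegmentedFit or NULL).
#' @export
detect_presence <- function(cov, sample, db, reference_genome, families,
                            genomes = NULL, min_presence = 0.8, ...) {
  depths <- .family_depth(cov, sample, db, families, genomes)
  frac_cov <- mean(depths > 1)
  if (frac_cov < min_presence)
    return(list(abundance = 0, present = FALSE, ptr = NA_real_,
                fit = NULL))
  if (is.null(reference_genome))
    return(list(abundance = stats::median(depths), present = TRUE,
                ptr = NA_real_, fit = NULL))
  prof <- build_profile(cov, sample, db, reference_genome, families,
                        genomes)
  fit <- fit_segmented(prof, ...)
  if (fit$valid)
    list(abundance = fit$cov_ter, present = TRUE, ptr = fit$ptr,
         fit = fit)
  else
    list(abundance = fit$fallback_abundance, present = TRUE, ptr = 1,
         fit = fit)
}

#' Quantify all taxa across all samples
#'
#' Applies \code{detect_presence} per sample x taxon and assembles raw
#' abundance, PTR and within-sample relative abundance matrices.
#'
#' @param cov Coverage matrix.
#' @param db A \code{ReferenceDB}.
#' @param taxa Named list: taxon -> list(reference_genome, families,
#'   genomes). \code{reference_genome} may be NULL (draft taxa);
#'   \code{genomes} (optional) restricts the family summation to the
#'   taxon's own genomes.
#' @param samples Sample ids (default: all columns of \code{cov}).
#' @param min_presence Passed through.
#' @return An \code{AbundanceMatrix} list: \code{abundance} (sample x
#'   taxon), \code{ptr}, \code{relative} (rows sum to 1 over detected taxa;
#'   all-NA for samples with nothing detected), \code{present} (logical).
#' @export
quantify_all <- function(cov, db, taxa, samples = colnames(cov),
                         min_presence = 0.8) {
  tn <- names(taxa)
  ab <- matrix(NA_real_, length(samples), length(tn),
               dimnames = list(samples, tn))
  ptr <- ab; pres <- matrix(NA, length(samples), length(tn),
                            dimnames = list(samples, tn))
  for (s in samples) for (t in tn) {
    res <- tryCatch(
      detect_presence(cov, s, db, taxa[[t]]$reference_genome,
                      taxa[[t]]$families, genomes = taxa[[t]]$genomes,
                      min_presence = min_presence),
      error = function(e) {
        .msg("quantification failed for ", t, " in ", s, ": ",
             conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    ab[s, t] <- res$abundance
    ptr[s, t] <- res$ptr
    pres[s, t] <- res$present
  }
  rel <- ab
  for (s in samples) {
    tot <- sum(ab[s, ], na.rm = TRUE)
    if (is.finite(tot) && tot > 0) rel[s, ] <- ab[s, ] / tot
    else {
      rel[s, ] <- NA_real_
      .msg("sample ", s, ": no taxa detected; relative abundances ",
           "undefined")
    }
  }
  structure(list(abundance = ab, ptr = ptr, relative = rel,
                 present = pres),
            class = "AbundanceMatrix")
}
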