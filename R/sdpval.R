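# Metagenomic validation of candidate SDPs: recruit assembled ORFs to
# core gene families, score best vs second-best SDP identity per ORF, and
# quantify the identity gap ("gap-zone") between the two distributions.

# Karlin-Altschul style e-value for an ungapped nucleotide match score,
# on a fixed effective database size; parameters are the standard
# ungapped +1/-2 nucleotide values. Only used for internally computed
# hits; precomputed hit files carry their own e-values.
.evalue <- function(score, query_len, db_len = 1e7,
                    lambda = 1.33, K = 0.621) {
  K * query_len * db_len * exp(-lambda * score)
}

#' Recruit metagenome-assembled ORFs to core gene families
#'
#' With a precomputed 12-column tabular hit file (query, subject, pid,
#' length, mismatches, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore), hits are parsed and filtered. Otherwise each ORF is aligned
#' against every core gene in the database and scored internally. Retained
#' hits satisfy e-value < \code{max_evalue}, percent identity >=
#' \code{min_pid} and query coverage > \code{min_qcov}; each ORF keeps at
#' most one family (best e-value, ties by higher identity then
#' lexicographic family id). ORFs shorter than 300 bp are dropped.
#'
#' @param orfs \code{DNAStringSet} (or named character vector) of ORFs.
#' @param db A \code{ReferenceDB}.
#' @param phylotype Restrict the search to this phylotype's single-copy
#'   core families (NULL: all).
#' @param hits Optional path to a precomputed tabular hit file whose
#'   subject ids are gene ids in the database.
#' @param max_evalue,min_pid,min_qcov Retention thresholds (defaults
#'   1e-5, 80, 0.5).
#' @param min_orf_length ORFs below this are dropped (default 300).
#' @return Data frame of \code{OrthologHit}s: orf_id, family_id, evalue,
#'   percent_id, query_coverage.
#' @export
recruit_orfs <- function(orfs, db, phylotype = NULL, hits = NULL,
                         max_evalue = 1e-5, min_pid = 80,
                         min_qcov = 0.5, min_orf_length = 300L) {
  nms <- names(orfs)
  v <- as.character(orfs)
  names(v) <- nms
  if (is.null(names(v))) stop("ORFs must be named")
  v <- v[nchar(v) >= min_orf_length]
  fams <- if (is.null(phylotype)) {
    db$families$family_id[db$families$single_copy]
  } else .core_families(db, phylotype)

  if (!is.null(hits)) {
    ht <- utils::read.table(hits, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, fill = TRUE)
    ok_line <- !is.na(suppressWarnings(as.numeric(ht[[3]]))) &
      !is.na(suppressWarnings(as.numeric(ht[[11]]))) & ncol(ht) >= 12
    if (any(!ok_line)) {
      warning(sum(!ok_line), " malformed hit line(s) skipped")
      ht <- ht[ok_line, , drop = FALSE]
    }
    fam_of_subject <- db$genes$family_id[match(ht[[2]],
                                               db$genes$gene_id)]
    rows <- data.frame(orf_id = ht[[1]],
                       family_id = fam_of_subject,
                       percent_id = as.numeric(ht[[3]]),
                       aln_len = as.numeric(ht[[4]]),
                       evalue = as.numeric(ht[[11]]),
                       stringsAsFactors = FALSE)
    rows <- rows[!is.na(rows$family_id) & rows$family_id %in% fams &
                   rows$orf_id %in% names(v), , drop = FALSE]
    rows$query_coverage <- rows$aln_len / nchar(v[rows$orf_id])
  } else {
    out <- list()
    for (o in names(v)) {
      for (f in fams) {
        for (gene in db$family_members[[f]]) {
          if (!gene %in% names(db$gene_seq)) next
          gseq <- db$gene_seq[[gene]]
          pid <- seq_identity(v[[o]], gseq)
          qcov <- min(nchar(gseq), nchar(v[[o]])) / nchar(v[[o]])
          score <- qcov * nchar(v[[o]]) *
            (pid / 100 - 2 * (1 - pid / 100))
          ev <- .evalue(max(score, 0), nchar(v[[o]]))
          out[[length(out) + 1L]] <- data.frame(
            orf_id = o, family_id = f, percent_id = pid,
            query_coverage = qcov, evalue = ev,
            stringsAsFactors = FALSE)
        }
      }
    }
    rows <- do.call(rbind, out)
    if (is.null(rows)) rows <- data.frame(orf_id = character(0),
                                          family_id = character(0),
                                          percent_id = numeric(0),
                                          query_coverage = numeric(0),
                                          evalue = numeric(0))
  }
  rows <- rows[rows$evalue < max_evalue & rows$percent_id >= min_pid &
                 rows$query_coverage > min_qcov, , drop = FALSE]
  if (nrow(rows) == 0)
    return(data.frame(orf_id = character(0), family_id = character(0),
                      evalue = numeric(0), percent_id = numeric(0),
                      query_coverage = numeric(0)))
  # best family per ORF: min e-value, then max identity, then family id
  rows <- rows[order(rows$orf_id, rows$evalue, -rows$percent_id,
                     rows$family_id), , drop = FALSE]
  rows <- rows[!duplicated(rows$orf_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows[, c("orf_id", "family_id", "evalue", "percent_id",
           "query_coverage")]
}

#' Score an ORF against the SDPs of its core family
#'
#' The ORF is compared with every member gene of the family; per SDP the
#' maximum percent identity to any member is taken, and the two largest
#' SDP maxima become best/second-best. Ties are broken by lexicographic
#' SDP id. Single-SDP phylotypes yield a null second hit.
#'
#' @param orf_seq Character scalar (nucleotide sequence).
#' @param orf_id Identifier for reporting.
#' @param family_id Core family id.
#' @param db A \code{ReferenceDB}.
#' @param partition An \code{SDPPartition}.
#' @return One-row data.frame: orf_id, family_id, best_sdp, best_pid,
#'   second_sdp, second_pid (NA when absent).
#' @export
score_orf <- function(orf_seq, orf_id, family_id, db, partition) {
  members <- db$family_members[[family_id]]
  if (is.null(members)) stop("unknown family: ", family_id)
  gmap <- db$genes$genome_id[match(members, db$genes$gene_id)]
  smap <- partition$mapping[gmap]
  per_sdp <- stats::setNames(rep(-Inf, length(unique(smap[!is.na(smap)]))),
                             sort(unique(smap[!is.na(smap)])))
  for (i in seq_along(members)) {
    if (is.na(smap[i])) next
    pid <- seq_identity(orf_seq, db$gene_seq[[members[i]]])
    if (pid > per_sdp[smap[i]]) per_sdp[smap[i]] <- pid
  }
  if (!length(per_sdp) || all(!is.finite(per_sdp)))
    stop("family ", family_id, " has no members in any SDP")
  # sort by identity desc, ties by sdp id asc (names are presorted)
  ord <- order(-per_sdp, names(per_sdp))
  best <- ord[1]
  data.frame(orf_id = orf_id, family_id = family_id,
             best_sdp = names(per_sdp)[best],
             best_pid = unname(per_sdp[best]),
             second_sdp = if (length(ord) > 1) names(per_sdp)[ord[2]]
             else NA_character_,
             second_pid = if (length(ord) > 1) unname(per_sdp[ord[2]])
             else NA_real_,
             stringsAsFactors = FALSE)
}

#' Score a set of recruited ORFs
#'
#' Convenience wrapper: applies \code{score_orf} to each retained hit.
#'
#' @param orfs \code{DNAStringSet} or named character vector.
#' @param hits Data frame from \code{recruit_orfs}.
#' @param db A \code{ReferenceDB}.
#' @param partition An \code{SDPPartition}.
#' @return Data frame of validation records.
#' @export
score_orfs <- function(orfs, hits, db, partition) {
  nms <- names(orfs)
  v <- as.character(orfs)
  names(v) <- nms
  recs <- lapply(seq_len(nrow(hits)), function(i)
    tryCatch(score_orf(v[[hits$orf_id[i]]], hits$orf_id[i],
                       hits$family_id[i], db, partition),
             error = function(e) {
               warning("scoring failed for ", hits$orf_id[i], ": ",
                       conditionMessage(e))
               NULL
             }))
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Gap-zone report for SDP validation
#'
#' Quantifies the separation between the best- and second-best-SDP
#' identity distributions as the overlap coefficient of 1-percentage-point
#' histogram estimates. SDPs are judged discrete when the overlap is
#' below \code{max_overlap} and the medians differ by at least
#' \code{min_median_gap} percentage points. Below \code{min_orfs} records
#' no verdict is issued (\code{discrete = NA}).
#'
#' @param records Data frame from \code{score_orfs}.
#' @param phylotype Label for the report.
#' @param min_orfs Minimum records for a verdict (default 50).
#' @param max_overlap Overlap threshold (default 0.05).
#' @param min_median_gap Median separation threshold in percentage points
#'   (default 5).
#' @return A \code{GapReport} list: phylotype, n_orfs, best_summary,
#'   second_summary, overlap_coefficient, discrete.
#' @export
gap_report <- function(records, phylotype = NA_character_, min_orfs = 50,
                       max_overlap = 0.05, min_median_gap = 5) {
  best <- records$best_pid
  second <- records$second_pid[!is.na(records$second_pid)]
  n <- nrow(records)
  if (!length(second)) {
    return(structure(list(phylotype = phylotype, n_orfs = n,
                          best_summary = summary(best),
                          second_summary = NULL,
                          overlap_coefficient = NA_real_,
                          discrete = NA),
                     class = "GapReport"))
  }
  breaks <- seq(floor(min(c(best, second))) - 1,
                ceiling(max(c(best, second))) + 1, by = 1)
  hb <- hist(best, breaks = breaks, plot = FALSE)$counts / length(best)
  hs <- hist(second, breaks = breaks, plot = FALSE)$counts /
    length(second)
  ovl <- sum(pmin(hb, hs))
  discrete <- if (n < min_orfs) NA else {
    ovl < max_overlap &&
      (stats::median(best) - stats::median(second)) >= min_median_gap
  }
  structure(list(phylotype = phylotype, n_orfs = n,
                 best_summary = summary(best),
                 second_summary = summary(second),
                 overlap_coefficient = ovl, discrete = discrete),
            class = "GapReport")
}

#' @export
print.GapReport <- function(x, ...) {
  cat("GapReport", if (!is.na(x$phylotype)) paste0("(", x$phylotype, ")"),
      ": n =", x$n_orfs, " overlap =",
      round(x$overlap_coefficient, 4), " discrete =", x$discrete, "\n")
  invisible(x)
}
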