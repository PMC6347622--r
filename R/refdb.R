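# Reference database: data model, I/O, core-gene ANI, SDP delineation and
# cross-SDP core-family filtering.
#
# Coordinates are 0-based half-open internally and on disk (BED convention).

#' Load a reference database
#'
#' Reads reference genomes (FASTA), gene coordinates (BED6, name = gene_id)
#' and core gene family membership (TSV: family_id, gene_id, phylotype,
#' single_copy) into a \code{ReferenceDB}. Genes shorter than 300 bp are
#' dropped at load (short genes add mapping noise and annotation-pipeline
#' variation); families left without members are dropped.
#'
#' @param genomes Named character vector of FASTA paths (names = genome_id),
#'   or a single directory containing \code{<genome_id>.fasta} files.
#' @param genes Path to a BED6 file of gene coordinates. Contig names must
#'   be of the form used in the FASTA headers.
#' @param families Path to a TSV with columns family_id, gene_id, phylotype,
#'   single_copy (logical).
#' @param phylotypes Optional named character vector genome_id -> phylotype;
#'   if omitted, phylotypes are taken from the family table via gene
#'   membership.
#' @param min_gene_length Minimum gene length in bp (default 300).
#' @return An object of class \code{ReferenceDB}: list with \code{genomes}
#'   (named list of contig DNAStringSets), \code{genome_ids},
#'   \code{phylotype} (named vector), \code{genes} (data.frame gene_id,
#'   genome_id, contig_id, start, end, strand, length, family_id),
#'   \code{gene_seq} (named character vector of gene sequences, strand
#'   applied), \code{families} (data.frame family_id, phylotype,
#'   single_copy), \code{family_members} (named list family_id -> gene_ids).
#' @export
load_reference <- function(genomes, genes, families, phylotypes = NULL,
                           min_gene_length = 300L) {
  if (length(genomes) == 1L && dir.exists(genomes)) {
    paths <- list.files(genomes, pattern = "\\.(fa|fna|fasta)$",
                        full.names = TRUE)
    names(paths) <- sub("\\.(fa|fna|fasta)$", "", basename(paths))
    genomes <- paths
  }
  if (is.null(names(genomes)) || any(names(genomes) == ""))
    stop("genome FASTA paths must be named by genome_id")
  contig_sets <- lapply(genomes, Biostrings::readDNAStringSet)
  # FASTA headers may carry descriptions; contig_id is the first word
  contig_sets <- lapply(contig_sets, function(s) {
    names(s) <- sub("\\s.*$", "", names(s)); s
  })
  contig2genome <- unlist(lapply(names(contig_sets), function(g)
    stats::setNames(rep(g, length(contig_sets[[g]])),
                    names(contig_sets[[g]]))))
  if (anyDuplicated(names(contig2genome)))
    stop("duplicate contig_id across genomes")

  bed <- if (file.size(genes) > 0)
    utils::read.table(genes, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  else data.frame()
  if (nrow(bed) == 0L) {
    warning("empty BED: reference database has no genes")
    gene_df <- data.frame(gene_id = character(), genome_id = character(),
                          contig_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          length = integer(), stringsAsFactors = FALSE)
  } else {
    if (ncol(bed) < 6L) stop("BED must have 6 columns")
    gene_df <- data.frame(gene_id = as.character(bed[[4]]),
                          contig_id = as.character(bed[[1]]),
                          start = as.integer(bed[[2]]),
                          end = as.integer(bed[[3]]),
                          strand = as.character(bed[[6]]),
                          stringsAsFactors = FALSE)
    if (anyDuplicated(gene_df$gene_id))
      stop("duplicate gene_id in BED: ",
           gene_df$gene_id[duplicated(gene_df$gene_id)][1])
    miss <- setdiff(gene_df$contig_id, names(contig2genome))
    if (length(miss))
      stop("BED references unknown contig(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
    gene_df$genome_id <- unname(contig2genome[gene_df$contig_id])
    clen <- vapply(seq_len(nrow(gene_df)), function(i)
      length(contig_sets[[gene_df$genome_id[i]]][[gene_df$contig_id[i]]]),
      integer(1))
    bad <- gene_df$start < 0L | gene_df$start >= gene_df$end |
      gene_df$end > clen
    if (any(bad))
      stop("gene coordinates out of contig bounds: ",
           paste(utils::head(gene_df$gene_id[bad], 3), collapse = ", "))
    gene_df$length <- gene_df$end - gene_df$start
    n_short <- sum(gene_df$length < min_gene_length)
    if (n_short > 0) {
      .msg("dropped ", n_short, " gene(s) shorter than ",
           min_gene_length, " bp")
      gene_df <- gene_df[gene_df$length >= min_gene_length, , drop = FALSE]
    }
    gene_df <- gene_df[, c("gene_id", "genome_id", "contig_id", "start",
                           "end", "strand", "length")]
    rownames(gene_df) <- NULL
  }

  # gene sequences, strand-applied (BED is 0-based half-open)
  gene_seq <- character(nrow(gene_df))
  for (i in seq_len(nrow(gene_df))) {
    s <- Biostrings::subseq(
      contig_sets[[gene_df$genome_id[i]]][[gene_df$contig_id[i]]],
      start = gene_df$start[i] + 1L, end = gene_df$end[i])
    if (gene_df$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    gene_seq[i] <- as.character(s)
  }
  names(gene_seq) <- gene_df$gene_id

  fam <- utils::read.table(families, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("family_id", "gene_id", "phylotype", "single_copy")
  if (!all(need %in% names(fam)))
    stop("family TSV must have columns: ", paste(need, collapse = ", "))
  fam$single_copy <- as.logical(fam$single_copy)
  unknown <- setdiff(fam$gene_id, gene_df$gene_id)
  if (length(unknown)) {
    # members referring to dropped (short) genes vanish quietly; anything
    # else is a broken reference
    truly_bad <- if (ncol(bed) >= 4)
      setdiff(unknown, as.character(bed[[4]])) else character()
    if (length(truly_bad))
      stop("family TSV references unknown gene_id: ", truly_bad[1])
    fam <- fam[fam$gene_id %in% gene_df$gene_id, , drop = FALSE]
  }
  family_members <- split(fam$gene_id, fam$family_id)
  empty <- names(family_members)[lengths(family_members) == 0L]
  family_members <- family_members[lengths(family_members) > 0L]
  fam_info <- unique(fam[, c("family_id", "phylotype", "single_copy")])
  fam_info <- fam_info[fam_info$family_id %in% names(family_members), ,
                       drop = FALSE]
  rownames(fam_info) <- NULL

  gene2fam <- stats::setNames(fam$family_id, fam$gene_id)
  gene_df$family_id <- unname(gene2fam[gene_df$gene_id])

  if (is.null(phylotypes)) {
    g2p <- tapply(
      fam$phylotype[match(gene_df$gene_id, fam$gene_id)],
      gene_df$genome_id, function(p) {
        p <- p[!is.na(p)]
        if (!length(p)) NA_character_ else names(sort(table(p),
                                                      decreasing = TRUE))[1]
      })
    phylotypes <- stats::setNames(as.character(g2p), names(g2p))
    phylotypes <- phylotypes[!is.na(phylotypes)]
  }

  db <- list(genomes = contig_sets,
             genome_ids = names(contig_sets),
             phylotype = phylotypes,
             genes = gene_df,
             gene_seq = gene_seq,
             families = fam_info,
             family_members = family_members)
  class(db) <- "ReferenceDB"
  db
}

#' @export
print.ReferenceDB <- function(x, ...) {
  cat("ReferenceDB:", length(x$genome_ids), "genomes,",
      nrow(x$genes), "genes,", nrow(x$families), "families,",
      length(unique(x$phylotype)), "phylotype(s)\n")
  invisible(x)
}

# single-copy core families of a phylotype, as family_id vector
.core_families <- function(db, phylotype) {
  f <- db$families
  f$family_id[f$phylotype == phylotype & f$single_copy]
}

# member gene of family in genome (single-copy); NA if absent
.family_gene_in_genome <- function(db, family_id, genome_id) {
  members <- db$family_members[[family_id]]
  g <- members[db$genes$genome_id[match(members, db$genes$gene_id)] ==
                 genome_id]
  if (length(g) == 0L) NA_character_ else g[[1]]
}

#' Core-gene average nucleotide identity matrix
#'
#' Computes a surrogate ANI for all genome pairs of a phylotype as the mean
#' pairwise percent identity over all shared single-copy core gene families.
#' Pairwise whole-genome estimators (FastANI-style) are interchangeable at
#' this granularity; a precomputed square matrix TSV can be supplied instead
#' and is returned verbatim.
#'
#' @param db A \code{ReferenceDB}.
#' @param phylotype Phylotype to analyse (>= 2 genomes required).
#' @param precomputed Optional path to a TSV square ANI matrix with genome
#'   ids as header row and first column; if given, computation is skipped.
#' @return An \code{ANIMatrix}: symmetric numeric matrix (percent, diagonal
#'   100) with genome ids as dimnames.
#' @export
core_gene_ani <- function(db, phylotype, precomputed = NULL) {
  if (!is.null(precomputed)) {
    m <- as.matrix(utils::read.table(precomputed, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    return(validate_ani(m))
  }
  gids <- names(db$phylotype)[db$phylotype == phylotype]
  if (length(gids) < 2L)
    stop("phylotype ", phylotype, " has fewer than 2 genomes")
  fams <- .core_families(db, phylotype)
  m <- matrix(100, length(gids), length(gids),
              dimnames = list(gids, gids))
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    ids <- numeric(0)
    for (f in fams) {
      ga <- .family_gene_in_genome(db, f, gids[i])
      gb <- .family_gene_in_genome(db, f, gids[j])
      if (is.na(ga) || is.na(gb)) next
      ids <- c(ids, seq_identity(db$gene_seq[[ga]], db$gene_seq[[gb]]))
    }
    if (!length(ids))
      stop("no shared single-copy core families between ",
           gids[i], " and ", gids[j])
    m[i, j] <- m[j, i] <- mean(ids)
  }
  validate_ani(m)
}

#' Validate an ANI matrix
#'
#' Checks symmetry, range and unit diagonal, and attaches the
#' \code{ANIMatrix} class.
#' @param m Square numeric matrix of percent identities.
#' @return The validated matrix, class \code{ANIMatrix}.
#' @export
validate_ani <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("ANI matrix needs genome ids as dimnames")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("ANI matrix not symmetric")
  if (any(m < 0 | m > 100)) stop("ANI values outside [0, 100]")
  if (any(abs(diag(m) - 100) > 1e-8)) stop("ANI diagonal must be 100")
  class(m) <- c("ANIMatrix", class(m))
  m
}

#' Delineate candidate sequence-discrete populations
#'
#' Partitions genomes into candidate SDPs: connected components of the graph
#' with an edge wherever pairwise ANI >= \code{ani_within}, then each
#' component is checked for complete linkage (minimum internal pairwise ANI
#' >= threshold). Components failing complete linkage are flagged, not
#' split: chained clusters were resolved by inspection in practice, so the
#' caller must look at them. Singleton SDPs are allowed. If a phylogeny is
#' supplied, each candidate SDP is additionally checked for monophyly.
#'
#' @param ani An \code{ANIMatrix}.
#' @param ani_within Minimum within-SDP pairwise ANI in percent (default 89).
#' @param tree Optional \code{ape::phylo} tree with the same genome ids as
#'   tip labels; candidate SDPs not monophyletic in it are flagged.
#' @param prefix Prefix for SDP ids (default "SDP").
#' @return An \code{SDPPartition}: list with \code{mapping} (named vector
#'   genome_id -> sdp_id), \code{sdp_ids}, \code{min_within_ani} (per SDP),
#'   \code{max_cross_ani} (matrix sdp x sdp), \code{complete_linkage}
#'   (named logical per SDP), \code{monophyletic} (named logical or NULL),
#'   \code{ani_within} (threshold used).
#' @export
candidate_sdps <- function(ani, ani_within = 89.0, tree = NULL,
                           prefix = "SDP") {
  ani <- validate_ani(unclass(ani))
  gids <- rownames(ani)
  adj <- ani >= ani_within
  diag(adj) <- TRUE
  comp <- .components(adj)
  # stable ids: number components by first genome appearance
  sdp_id <- paste0(prefix, "-", comp)
  names(sdp_id) <- gids
  sdp_ids <- unique(sdp_id)

  min_within <- stats::setNames(rep(100, length(sdp_ids)), sdp_ids)
  complete <- stats::setNames(rep(TRUE, length(sdp_ids)), sdp_ids)
  for (s in sdp_ids) {
    members <- gids[sdp_id == s]
    if (length(members) > 1L) {
      sub <- ani[members, members]
      mn <- min(sub[upper.tri(sub)])
      min_within[s] <- mn
      complete[s] <- mn >= ani_within
      if (!complete[s])
        warning("SDP ", s, " fails complete linkage (min internal ANI ",
                round(mn, 2), " < ", ani_within, "); flagged, not split")
    }
  }
  cross <- matrix(NA_real_, length(sdp_ids), length(sdp_ids),
                  dimnames = list(sdp_ids, sdp_ids))
  for (a in sdp_ids) for (b in sdp_ids) {
    if (a == b) next
    cross[a, b] <- max(ani[gids[sdp_id == a], gids[sdp_id == b]])
  }
  mono <- NULL
  if (!is.null(tree)) {
    mono <- stats::setNames(rep(NA, length(sdp_ids)), sdp_ids)
    for (s in sdp_ids) {
      members <- gids[sdp_id == s]
      mono[s] <- .is_monophyletic(tree, members)
    }
  }
  out <- list(mapping = sdp_id, sdp_ids = sdp_ids,
              min_within_ani = min_within, max_cross_ani = cross,
              complete_linkage = complete, monophyletic = mono,
              ani_within = ani_within)
  class(out) <- "SDPPartition"
  out
}

# monophyly without importing ape: the clade spanned by `tips` contains no
# other tips
.is_monophyletic <- function(tree, tips) {
  if (length(tips) <= 1L) return(TRUE)
  all_tips <- tree$tip.label
  if (!all(tips %in% all_tips)) stop("tree lacks tips: ",
                                     paste(setdiff(tips, all_tips),
                                           collapse = ", "))
  # find MRCA by intersecting root paths
  n_tip <- length(all_tips)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path_to_root <- function(node) {
    p <- node
    while (parent[node] != 0L) { node <- parent[node]; p <- c(p, node) }
    p
  }
  paths <- lapply(match(tips, all_tips), path_to_root)
  common <- Reduce(intersect, paths)
  mrca <- common[1]
  # tips under mrca
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) return(node)
    unlist(lapply(kids, desc))
  }
  under <- desc(mrca)
  setequal(all_tips[under[under <= n_tip]], tips)
}

#' @export
print.SDPPartition <- function(x, ...) {
  cat("SDPPartition:", length(x$sdp_ids), "SDP(s) over",
      length(x$mapping), "genomes (ani_within =", x$ani_within, ")\n")
  for (s in x$sdp_ids)
    cat("  ", s, ": ", paste(names(x$mapping)[x$mapping == s],
                             collapse = ", "),
        if (!x$complete_linkage[s]) "  [FLAG: incomplete linkage]" else "",
        "\n", sep = "")
  invisible(x)
}

#' Filter core gene families for cross-SDP similarity
#'
#' Excludes core gene families in which any cross-SDP member pair exceeds
#' \code{max_cross_sdp_identity} percent aligned nucleotide identity
#' (conserved or recently recombined families blur SDP-level signals).
#' For single-SDP phylotypes all core families are returned unchanged.
#'
#' @param db A \code{ReferenceDB}.
#' @param partition An \code{SDPPartition} for one phylotype.
#' @param phylotype Phylotype whose core families are filtered.
#' @param max_cross_sdp_identity Exclusion threshold in percent (default 95):
#'   families are retained only if every cross-SDP pair is at or below it.
#' @return Character vector of retained family ids (subset of the
#'   phylotype's single-copy core families).
#' @export
filter_core_families <- function(db, partition, phylotype,
                                 max_cross_sdp_identity = 95.0) {
  fams <- .core_families(db, phylotype)
  if (length(partition$sdp_ids) < 2L) return(fams)
  keep <- logical(length(fams))
  for (k in seq_along(fams)) {
    members <- db$family_members[[fams[k]]]
    gmap <- db$genes$genome_id[match(members, db$genes$gene_id)]
    smap <- partition$mapping[gmap]
    ok <- TRUE
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (i >= j || is.na(smap[i]) || is.na(smap[j])) next
      if (smap[i] == smap[j]) next
      pid <- seq_identity(db$gene_seq[[members[i]]],
                          db$gene_seq[[members[j]]])
      if (pid > max_cross_sdp_identity) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  fams[keep]
}
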