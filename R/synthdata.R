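# Synthetic-data generator: reference databases, per-sample coverage /
# SNV / ORF inputs and metadata with planted ground truth, emulating a
# simple social-insect gut community (few phylotypes, each split into
# sequence-discrete populations, strains segregating into individual hosts).

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic community generator.
#' Defaults emulate the honey-bee gut study design: 5 phylotypes carrying
#' 1-4 SDPs each, 2 colonies sampled over 9 samplings (3 age groups, one
#' colony in two consecutive years) with 6 bees each, a per-colony strain
#' pool from which each bee draws a small strain subset (priority-effect
#' segregation), and bidirectional-replication coverage gradients.
#'
#' @param n_phylotypes Number of phylotypes.
#' @param n_sdps Integer vector (recycled) of SDPs per phylotype.
#' @param n_genomes_per_sdp Database genomes per SDP.
#' @param within_sdp_divergence Planted pairwise nucleotide divergence
#'   within SDPs (fraction; default 0.04, i.e. ~96% ANI).
#' @param between_sdp_divergence Planted divergence between SDPs of one
#'   phylotype (default 0.14, i.e. ~86% ANI; must exceed the within value).
#' @param n_core_families Single-copy core gene families per phylotype.
#' @param mean_gene_length Core gene length in bp (constant; substitutions
#'   only, which keeps identity arithmetic exact).
#' @param n_conserved_families Core families deliberately kept conserved
#'   across SDPs (cross-SDP identity above the 95% filter threshold), to
#'   exercise the cross-SDP family filter.
#' @param n_strains Strains per SDP in the colony pool.
#' @param strains_per_bee Strains per SDP carried by each bee.
#' @param islands_per_strain Strain-private accessory islands per strain.
#' @param genes_per_island Genes per accessory island.
#' @param island_gene_length Accessory gene length in bp.
#' @param snv_rate Fraction of core positions segregating among strains.
#' @param samplings Data frame describing the sampling design (columns
#'   sampling_label, colony, age_group, date); default is the 9-sampling
#'   two-colony design.
#' @param bees_per_sampling Bees per sampling.
#' @param ptr_range Range from which per-sample peak-to-trough ratios are
#'   drawn (uniform).
#' @param terminus_range Range of per-sample terminus coverages (uniform).
#' @param noise Counting-noise model for gene depths: "poisson" or "nb".
#' @param nb_size Negative-binomial size (dispersion) when noise = "nb".
#' @param colony_structure "shared" (both colonies draw from the full strain
#'   pool; the study found no colony signal) or "structured" (disjoint
#'   per-colony pools, for power testing).
#' @param n_orfs Metagenome-assembled ORFs to emit per dataset.
#' @param orf_divergence Extra divergence of emitted ORFs from their source
#'   strain gene (fraction).
#' @return A \code{SimConfig} list.
#' @export
sim_config <- function(n_phylotypes = 5,
                       n_sdps = c(4, 2, 2, 3, 1),
                       n_genomes_per_sdp = 3,
                       within_sdp_divergence = 0.04,
                       between_sdp_divergence = 0.14,
                       n_core_families = 60,
                       mean_gene_length = 900,
                       n_conserved_families = 3,
                       n_strains = 8,
                       strains_per_bee = 2,
                       islands_per_strain = 2,
                       genes_per_island = 6,
                       island_gene_length = 2000,
                       snv_rate = 0.03,
                       samplings = NULL,
                       bees_per_sampling = 6,
                       ptr_range = c(1, 3),
                       terminus_range = c(20, 80),
                       noise = c("poisson", "nb"),
                       nb_size = 10,
                       colony_structure = c("shared", "structured"),
                       n_orfs = 200,
                       orf_divergence = 0.01) {
  noise <- match.arg(noise)
  colony_structure <- match.arg(colony_structure)
  if (within_sdp_divergence <= 0 || within_sdp_divergence >= 1 ||
      between_sdp_divergence <= 0 || between_sdp_divergence >= 1)
    stop("divergences must lie in (0, 1)")
  if (within_sdp_divergence >= between_sdp_divergence)
    stop("within-SDP divergence must be smaller than between-SDP ",
         "divergence: the planted identity gap would be inverted")
  if (strains_per_bee > n_strains)
    stop("strains_per_bee cannot exceed n_strains")
  if (is.null(samplings)) {
    # 9 samplings: colony 1 in two consecutive years, colony 2 in one,
    # three age groups each
    samplings <- data.frame(
      sampling_label = paste0("S", 1:9),
      colony = rep(c("colony1", "colony1", "colony2"), each = 3),
      age_group = rep(c("young", "middle", "old"), 3),
      date = c("2015-09-28", "2015-10-12", "2016-02-22",
               "2016-09-25", "2016-10-07", "2016-11-01",
               "2016-09-25", "2016-10-07", "2016-11-01"),
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_phylotypes = n_phylotypes,
              n_sdps = rep_len(n_sdps, n_phylotypes),
              n_genomes_per_sdp = n_genomes_per_sdp,
              within_sdp_divergence = within_sdp_divergence,
              between_sdp_divergence = between_sdp_divergence,
              n_core_families = n_core_families,
              mean_gene_length = mean_gene_length,
              n_conserved_families = min(n_conserved_families,
                                         n_core_families),
              n_strains = n_strains,
              strains_per_bee = strains_per_bee,
              islands_per_strain = islands_per_strain,
              genes_per_island = genes_per_island,
              island_gene_length = island_gene_length,
              snv_rate = snv_rate,
              samplings = samplings,
              bees_per_sampling = bees_per_sampling,
              ptr_range = ptr_range,
              terminus_range = terminus_range,
              noise = noise,
              nb_size = nb_size,
              colony_structure = colony_structure,
              n_orfs = n_orfs,
              orf_divergence = orf_divergence)
  class(cfg) <- "SimConfig"
  cfg
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# substitute a fraction `f` of positions, each to a different base;
# returns list(seq, pos) with 1-based mutated positions
.mutate <- function(seq, f) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  k <- round(f * n)
  if (k == 0) return(list(seq = seq, pos = integer(0)))
  pos <- sort(sample.int(n, k))
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  list(seq = paste(v, collapse = ""), pos = pos)
}

# substitute exactly the given positions, each to a different base
.mutate_at <- function(seq, pos) {
  if (!length(pos)) return(seq)
  v <- strsplit(seq, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

#' Generate a synthetic reference database with planted SDP structure
#'
#' Per phylotype, an ancestral set of core genes is simulated; each SDP
#' derives an ancestor by substitutions at half the (between - within)
#' divergence, and each genome adds private substitutions at half the
#' within divergence, so that realized pairwise divergence is approximately
#' \code{within_sdp_divergence} within SDPs and
#' \code{between_sdp_divergence} across them. A configurable number of
#' families skip the SDP-level mutations and stay conserved (> 95%
#' cross-SDP identity). The first genome of each SDP is its representative
#' and additionally carries all the SDP's strain-private accessory islands.
#' FASTA/BED/TSV files are written and re-loaded through
#' \code{load_reference}, so the returned database took the same path user
#' data would.
#'
#' @param cfg A \code{SimConfig}.
#' @param seed Integer seed; all output is byte-identical under it.
#' @param dir Output directory (default a fresh tempdir subdirectory).
#' @return List with \code{db} (ReferenceDB), \code{truth} (GroundTruth
#'   list: \code{partition}, \code{phylotype}, \code{representative},
#'   \code{conserved_families}, \code{strains}, \code{seg_sites},
#'   \code{islands}, \code{core_length}, \code{genome_length}) and
#'   \code{paths}.
#' @export
gen_reference <- function(cfg, seed, dir = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(as.integer(seed))
  if (is.null(dir)) dir <- file.path(tempfile("beediv_ref_"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  glen <- cfg$mean_gene_length
  gap <- 200L
  fam_rows <- list(); bed_rows <- list()
  partition <- character(0); phylo_of <- character(0)
  representative <- character(0)
  conserved <- list()
  strains <- list(); seg_sites <- list(); islands <- list()
  core_length <- numeric(0); genome_length <- numeric(0)
  fasta_paths <- character(0)

  d_gen <- cfg$within_sdp_divergence / 2

  for (p in seq_len(cfg$n_phylotypes)) {
    ph <- sprintf("P%d", p)
    n_sdp <- cfg$n_sdps[p]
    anc <- replicate(cfg$n_core_families, .rand_dna(glen))
    fam_ids <- sprintf("%s_f%03d", ph, seq_len(cfg$n_core_families))
    cons_idx <- if (n_sdp > 1) seq_len(cfg$n_conserved_families)
    else integer(0)
    conserved[[ph]] <- fam_ids[cons_idx]

    # SDP-ancestor mutations sit at disjoint positions (exact pairwise
    # ancestor divergence); the non-conserved divergence is raised to
    # compensate for the dilution by conserved families, so that the
    # emitted mean cross-SDP ANI over all core families matches
    # 100 * (1 - between_sdp_divergence)
    n_fam <- cfg$n_core_families
    n_cons <- length(cons_idx)
    anc_div <- if (n_sdp > 1) {
      target <- (n_fam * cfg$between_sdp_divergence -
                   n_cons * cfg$within_sdp_divergence) / (n_fam - n_cons)
      max(0, target - cfg$within_sdp_divergence)
    } else 0
    k_anc <- round(anc_div / 2 * glen)
    if (n_sdp * k_anc > glen)
      stop("between-SDP divergence too high to plant disjoint ",
           "mutation sets; reduce divergence or SDP count")
    sdp_anc_sets <- vector("list", n_sdp)
    for (s in seq_len(n_sdp)) sdp_anc_sets[[s]] <- anc
    if (n_sdp > 1 && k_anc > 0) {
      for (k in setdiff(seq_len(n_fam), cons_idx)) {
        pos_all <- sample.int(glen, n_sdp * k_anc)
        for (s in seq_len(n_sdp)) {
          chunk <- pos_all[((s - 1L) * k_anc + 1L):(s * k_anc)]
          sdp_anc_sets[[s]][k] <- .mutate_at(anc[k], chunk)
        }
      }
    }

    for (s in seq_len(n_sdp)) {
      sdp <- sprintf("%sS%d", ph, s)
      sdp_anc <- sdp_anc_sets[[s]]

      # strain-private accessory islands live on the representative genome
      n_isl <- cfg$n_strains * cfg$islands_per_strain
      isl_seqs <- replicate(n_isl * cfg$genes_per_island,
                            .rand_dna(cfg$island_gene_length))

      for (g in seq_len(cfg$n_genomes_per_sdp)) {
        gid <- sprintf("%sG%d", sdp, g)
        partition[gid] <- sdp
        phylo_of[gid] <- ph
        if (g == 1L) representative[sdp] <- gid
        genes <- vapply(sdp_anc, function(x) .mutate(x, d_gen)$seq,
                        character(1), USE.NAMES = FALSE)
        # assemble one contig: core genes evenly spaced with accessory
        # islands interleaved (representative genome only), so the core
        # gene positions span the full replichore
        contig_id <- paste0(gid, "_c1")
        parts <- character(0); pos <- 0L
        isl_after <- if (g == 1L && n_isl > 0)
          vapply(seq_len(n_isl), function(i)
            as.integer(ceiling(i * length(genes) / (n_isl + 1L))),
            integer(1)) else integer(0)
        emit_island <- function(isl) {
          # 6 kb flank, genes_per_island genes with 1 kb intra-island gaps
          parts <<- c(parts, .rand_dna(6000L)); pos <<- pos + 6000L
          strain_of_isl <- ((isl - 1L) %/% cfg$islands_per_strain) + 1L
          isl_start <- pos
          isl_fams <- character(0)
          for (q in seq_len(cfg$genes_per_island)) {
            gene_id <- sprintf("%s_acc%02d_%d", gid, isl, q)
            fam_id <- sprintf("%s_accfam%02d_%d", sdp, isl, q)
            bed_rows[[length(bed_rows) + 1L]] <<- data.frame(
              contig = contig_id, start = pos,
              end = pos + cfg$island_gene_length, name = gene_id,
              score = 0L, strand = "+", stringsAsFactors = FALSE)
            fam_rows[[length(fam_rows) + 1L]] <<- data.frame(
              family_id = fam_id, gene_id = gene_id, phylotype = ph,
              single_copy = FALSE, stringsAsFactors = FALSE)
            isl_fams <- c(isl_fams, fam_id)
            parts <<- c(parts,
                        isl_seqs[(isl - 1L) * cfg$genes_per_island + q])
            pos <<- pos + cfg$island_gene_length
            if (q < cfg$genes_per_island) {
              parts <<- c(parts, .rand_dna(1000L)); pos <<- pos + 1000L
            }
          }
          parts <<- c(parts, .rand_dna(6000L)); pos <<- pos + 6000L
          islands[[length(islands) + 1L]] <<- data.frame(
            island_id = sprintf("%s_isl%02d", sdp, isl), sdp = sdp,
            strain = sprintf("%s_str%02d", sdp, strain_of_isl),
            genome_id = gid, contig_id = contig_id,
            start = isl_start, end = pos - 6000L,
            families = paste(isl_fams, collapse = ","),
            stringsAsFactors = FALSE)
        }
        for (k in seq_along(genes)) {
          gene_id <- sprintf("%s_g%03d", gid, k)
          bed_rows[[length(bed_rows) + 1L]] <- data.frame(
            contig = contig_id, start = pos, end = pos + glen,
            name = gene_id, score = 0L, strand = "+",
            stringsAsFactors = FALSE)
          fam_rows[[length(fam_rows) + 1L]] <- data.frame(
            family_id = fam_ids[k], gene_id = gene_id, phylotype = ph,
            single_copy = TRUE, stringsAsFactors = FALSE)
          parts <- c(parts, genes[k], .rand_dna(gap))
          pos <- pos + glen + gap
          for (isl in which(isl_after == k)) emit_island(isl)
        }
        contig <- paste(parts, collapse = "")
        genome_length[gid] <- nchar(contig)
        fa <- file.path(dir, paste0(gid, ".fasta"))
        writeLines(c(paste0(">", contig_id), contig), fa)
        fasta_paths[gid] <- fa
      }

      # strains: alleles at segregating sites of the representative's
      # core genes, plus islands_per_strain private islands each
      core_length[sdp] <- cfg$n_core_families * glen
      n_sites <- round(cfg$snv_rate * core_length[sdp])
      if (n_sites > 0 && cfg$n_strains > 1) {
        site_fam <- sample.int(cfg$n_core_families, n_sites, replace = TRUE)
        site_pos <- sample.int(glen, n_sites, replace = TRUE)
        dup <- duplicated(paste(site_fam, site_pos))
        site_fam <- site_fam[!dup]; site_pos <- site_pos[!dup]
        n_sites <- length(site_fam)
        rep_gid <- representative[sdp]
        rep_genes <- sprintf("%s_g%03d", rep_gid, site_fam)
        ref_al <- character(n_sites); alt_al <- character(n_sites)
        allele_mat <- matrix(0L, n_sites, cfg$n_strains)
        for (k in seq_len(n_sites)) {
          # look up ref base lazily after assembly below; placeholder
          repeat {
            a <- stats::rbinom(cfg$n_strains, 1L, 0.5)
            if (any(a == 1L) && any(a == 0L)) break
          }
          allele_mat[k, ] <- a
        }
        seg_sites[[sdp]] <- data.frame(
          sdp = sdp, gene_id = rep_genes, family_idx = site_fam,
          pos = site_pos, stringsAsFactors = FALSE)
        attr(seg_sites[[sdp]], "alleles") <- allele_mat
      } else {
        seg_sites[[sdp]] <- data.frame(sdp = character(0),
                                       gene_id = character(0),
                                       family_idx = integer(0),
                                       pos = integer(0))
        attr(seg_sites[[sdp]], "alleles") <-
          matrix(0L, 0, cfg$n_strains)
      }
      strains[[sdp]] <- sprintf("%s_str%02d", sdp, seq_len(cfg$n_strains))
    }
  }

  bed <- do.call(rbind, bed_rows)
  fam <- do.call(rbind, fam_rows)
  bed_path <- file.path(dir, "genes.bed")
  fam_path <- file.path(dir, "families.tsv")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, fam_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  db <- load_reference(fasta_paths, bed_path, fam_path,
                       phylotypes = phylo_of)

  # resolve ref/alt alleles for segregating sites from the representative
  # gene sequences now that they are loaded
  for (sdp in names(seg_sites)) {
    ss <- seg_sites[[sdp]]
    if (nrow(ss) == 0) next
    ref <- character(nrow(ss)); alt <- character(nrow(ss))
    for (k in seq_len(nrow(ss))) {
      base <- substr(db$gene_seq[[ss$gene_id[k]]], ss$pos[k], ss$pos[k])
      ref[k] <- base
      alt[k] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    }
    ss$ref <- ref; ss$alt <- alt
    attr(ss, "alleles") <- attr(seg_sites[[sdp]], "alleles")
    seg_sites[[sdp]] <- ss
  }

  islands_df <- if (length(islands)) do.call(rbind, islands) else
    data.frame(island_id = character(0), sdp = character(0),
               strain = character(0), genome_id = character(0),
               contig_id = character(0), start = integer(0),
               end = integer(0), families = character(0))

  truth <- list(partition = partition, phylotype = phylo_of,
                representative = representative,
                conserved_families = conserved,
                strains = strains, seg_sites = seg_sites,
                islands = islands_df, core_length = core_length,
                genome_length = genome_length, cfg = cfg, seed = seed)
  class(truth) <- "GroundTruth"
  list(db = db, truth = truth,
       paths = list(dir = dir, fasta = fasta_paths, bed = bed_path,
                    families = fam_path))
}

#' Simulate one positional coverage profile
#'
#' Expected depth follows the symmetric bidirectional-replication model:
#' \code{ter * (1 + (ptr - 1) * (1 - 2 d / L))} where \code{d} is the
#' circular distance from the replication origin (position 0) to the gene
#' midpoint and \code{L} the genome length. Realized per-gene depth adds
#' counting noise (Poisson on the per-gene base count by default).
#'
#' @param n_families Number of core families (profile points).
#' @param gene_length Gene length in bp.
#' @param ptr Planted peak-to-trough ratio (>= 1).
#' @param terminus_cov Planted terminus coverage.
#' @param noise "poisson", "nb" or "none".
#' @param nb_size Negative-binomial size when noise = "nb".
#' @param gap Intergenic spacing in bp.
#' @return A \code{CoverageProfile} data.frame (position, family_id, depth)
#'   with attributes \code{taxon}, \code{genome_length}.
#' @export
simulate_coverage_profile <- function(n_families = 300, gene_length = 900,
                                      ptr = 2, terminus_cov = 50,
                                      noise = c("poisson", "nb", "none"),
                                      nb_size = 10, gap = 200) {
  noise <- match.arg(noise)
  stopifnot(ptr >= 1, terminus_cov > 0)
  L <- n_families * (gene_length + gap)
  mid <- (seq_len(n_families) - 1) * (gene_length + gap) + gene_length / 2
  d <- pmin(mid, L - mid)
  mu <- terminus_cov * (1 + (ptr - 1) * (1 - 2 * d / L))
  depth <- switch(noise,
    none = mu,
    poisson = stats::rpois(n_families, mu * gene_length) / gene_length,
    nb = stats::rnbinom(n_families, size = nb_size,
                        mu = mu * gene_length) / gene_length)
  prof <- data.frame(position = mid,
                     family_id = sprintf("f%04d", seq_len(n_families)),
                     depth = depth, stringsAsFactors = FALSE)
  attr(prof, "taxon") <- "sim"
  attr(prof, "genome_length") <- L
  class(prof) <- c("CoverageProfile", class(prof))
  prof
}

#' Generate synthetic per-sample metagenomic inputs
#'
#' For each bee, strains of each SDP are drawn from the colony pool with
#' Dirichlet mixture weights (priority-effect model: independent draws per
#' bee). Core-gene depths on the SDP representative genome follow the
#' replication-gradient model with per-sample planted PTR and terminus
#' coverage plus counting noise; accessory island genes receive depth only
#' from the strains carrying them; candidate SNV rows report alt-allele
#' fractions with binomial sampling noise at the local depth; ORFs are
#' sampled from strain gene sequences.
#'
#' @param cfg A \code{SimConfig} (the one used for the reference).
#' @param truth GroundTruth from \code{gen_reference}.
#' @param db ReferenceDB from \code{gen_reference}.
#' @param seed Integer seed.
#' @param orf_mode "strain" (default): ORFs are sampled from strain gene
#'   sequences and cluster tightly around their SDP of origin, producing a
#'   gap-zone. "chimeric": ORFs mix positions of two SDP representatives
#'   50/50, emulating a lineage continuum without a gap (only possible for
#'   phylotypes with >= 2 SDPs).
#' @param dir Optional output directory; when given, coverage / SNV /
#'   metadata TSVs and the ORF FASTA are written there.
#' @return List with \code{coverage} (gene x sample matrix of mean depths),
#'   \code{snv} (candidate SNV data.frame: taxon, gene_id, pos, ref, alt,
#'   one column per sample), \code{orfs} (DNAStringSet),
#'   \code{orf_truth} (data.frame orf_id, family_id, sdp),
#'   \code{metadata} (sample_id, colony, age_group, sampling_label, date),
#'   \code{sample_truth} (sample x sdp planted ptr/terminus),
#'   \code{bee_strains} (list sample -> sdp -> named weight vector),
#'   \code{recruitment_counts} (genome x sample core-gene read counts).
#' @export
gen_samples <- function(cfg, truth, db, seed,
                        orf_mode = c("strain", "chimeric"), dir = NULL) {
  orf_mode <- match.arg(orf_mode)
  set.seed(as.integer(seed))
  sam <- cfg$samplings
  meta <- do.call(rbind, lapply(seq_len(nrow(sam)), function(i) {
    data.frame(sample_id = sprintf("%s_bee%d", sam$sampling_label[i],
                                   seq_len(cfg$bees_per_sampling)),
               colony = sam$colony[i], age_group = sam$age_group[i],
               sampling_label = sam$sampling_label[i], date = sam$date[i],
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  samples <- meta$sample_id
  sdps <- names(truth$representative)
  glen <- cfg$mean_gene_length

  # per-colony strain pools
  pools <- list()
  for (sdp in sdps) {
    st <- truth$strains[[sdp]]
    if (cfg$colony_structure == "structured") {
      half <- split(st, rep(seq_along(unique(meta$colony)),
                            length.out = length(st)))
      names(half) <- unique(meta$colony)
      pools[[sdp]] <- half
    } else {
      pools[[sdp]] <- stats::setNames(
        rep(list(st), length(unique(meta$colony))), unique(meta$colony))
    }
  }

  bee_strains <- list()
  sample_truth <- expand.grid(sample_id = samples, sdp = sdps,
                              stringsAsFactors = FALSE)
  sample_truth$ptr <- NA_real_; sample_truth$terminus <- NA_real_

  all_genes <- db$genes$gene_id
  coverage <- matrix(0, nrow = length(all_genes), ncol = length(samples),
                     dimnames = list(all_genes, samples))
  recruit <- matrix(0, nrow = length(db$genome_ids),
                    ncol = length(samples),
                    dimnames = list(db$genome_ids, samples))

  snv_ab <- list()

  for (si in seq_along(samples)) {
    smp <- samples[si]
    bee_strains[[smp]] <- list()
    for (sdp in sdps) {
      pool <- pools[[sdp]][[meta$colony[si]]]
      picked <- sample(pool, cfg$strains_per_bee)
      w <- stats::rgamma(length(picked), shape = 1)
      w <- w / sum(w)
      names(w) <- picked
      bee_strains[[smp]][[sdp]] <- w

      ptr <- stats::runif(1, cfg$ptr_range[1], cfg$ptr_range[2])
      ter <- stats::runif(1, cfg$terminus_range[1], cfg$terminus_range[2])
      idx <- sample_truth$sample_id == smp & sample_truth$sdp == sdp
      sample_truth$ptr[idx] <- ptr
      sample_truth$terminus[idx] <- ter

      rep_gid <- truth$representative[sdp]
      L <- truth$genome_length[rep_gid]
      gmask <- db$genes$genome_id == rep_gid
      gdf <- db$genes[gmask, , drop = FALSE]
      mid <- (gdf$start + gdf$end) / 2
      d <- pmin(mid, L - mid)
      mu <- ter * (1 + (ptr - 1) * (1 - 2 * d / L))
      is_core <- !is.na(gdf$family_id) &
        gdf$family_id %in% .core_families(db, truth$phylotype[rep_gid])
      # accessory genes: depth proportional to carrying-strain weight,
      # no gradient applied (their position is bookkeeping, not biology)
      if (nrow(truth$islands)) {
        isl <- truth$islands[truth$islands$sdp == sdp, , drop = FALSE]
        for (r in seq_len(nrow(isl))) {
          fams <- strsplit(isl$families[r], ",")[[1]]
          carrier_w <- if (isl$strain[r] %in% names(w))
            w[[isl$strain[r]]] else 0
          gi <- gdf$family_id %in% fams
          mu[gi] <- ter * carrier_w
        }
      }
      len <- gdf$length
      depth <- switch(cfg$noise,
        poisson = stats::rpois(length(mu), mu * len) / len,
        nb = stats::rnbinom(length(mu), size = cfg$nb_size,
                            mu = mu * len) / len)
      coverage[gdf$gene_id, si] <- depth

      # read recruitment: SDP reads split over member genomes by a
      # Dirichlet draw tilted toward the representative
      members <- names(truth$partition)[truth$partition == sdp]
      alpha <- ifelse(members == rep_gid, 4, 1)
      frac <- stats::rgamma(length(members), shape = alpha)
      frac <- frac / sum(frac)
      total_reads <- ter * truth$core_length[sdp] / 100
      recruit[members, si] <- round(total_reads * frac)

      # SNV candidate abundances
      ss <- truth$seg_sites[[sdp]]
      if (nrow(ss)) {
        alle <- attr(ss, "alleles")
        strain_idx <- match(names(w), truth$strains[[sdp]])
        p_alt <- as.numeric(alle[, strain_idx, drop = FALSE] %*% w)
        p_alt <- pmin(pmax(p_alt, 0), 1)  # guard against fp overshoot
        dep <- coverage[ss$gene_id, si]
        n <- pmax(1L, round(dep))
        obs <- stats::rbinom(length(p_alt), size = n, prob = p_alt) / n
        key <- sdp
        if (is.null(snv_ab[[key]]))
          snv_ab[[key]] <- matrix(NA_real_, nrow(ss), length(samples),
                                  dimnames = list(NULL, samples))
        snv_ab[[key]][, si] <- obs
      }
    }
  }

  snv <- do.call(rbind, lapply(sdps, function(sdp) {
    ss <- truth$seg_sites[[sdp]]
    if (!nrow(ss)) return(NULL)
    out <- data.frame(taxon = sdp, gene_id = ss$gene_id, pos = ss$pos,
                      ref = ss$ref, alt = ss$alt, stringsAsFactors = FALSE)
    cbind(out, as.data.frame(snv_ab[[sdp]]))
  }))

  # ORFs sampled from strain gene sequences (strain alleles applied to the
  # representative's core genes), with a touch of extra divergence
  orf_ids <- sprintf("orf%04d", seq_len(cfg$n_orfs))
  orf_seqs <- character(cfg$n_orfs)
  orf_truth <- data.frame(orf_id = orf_ids,
                          family_id = rep(NA_character_, cfg$n_orfs),
                          sdp = rep(NA_character_, cfg$n_orfs),
                          stringsAsFactors = FALSE)
  for (k in seq_len(cfg$n_orfs)) {
    if (orf_mode == "chimeric") {
      sdp_ph <- truth$phylotype[truth$representative[sdps]]
      ph_multi <- names(which(table(sdp_ph) >= 2))
      if (!length(ph_multi))
        stop("chimeric ORFs need a phylotype with >= 2 SDPs")
      ph <- sample(ph_multi, 1)
      pair <- sample(sdps[sdp_ph == ph], 2)
      fam_k <- sample.int(cfg$n_core_families, 1)
      g1 <- sprintf("%s_g%03d", truth$representative[pair[1]], fam_k)
      g2 <- sprintf("%s_g%03d", truth$representative[pair[2]], fam_k)
      v1 <- strsplit(db$gene_seq[[g1]], "")[[1]]
      v2 <- strsplit(db$gene_seq[[g2]], "")[[1]]
      pick <- stats::rbinom(length(v1), 1L, 0.5) == 1L
      v1[pick] <- v2[pick]
      seq <- paste(v1, collapse = "")
      if (cfg$orf_divergence > 0)
        seq <- .mutate(seq, cfg$orf_divergence)$seq
      orf_seqs[k] <- seq
      orf_truth$family_id[k] <- db$genes$family_id[
        match(g1, db$genes$gene_id)]
      orf_truth$sdp[k] <- NA_character_
      next
    }
    sdp <- sample(sdps, 1)
    rep_gid <- truth$representative[sdp]
    fam_k <- sample.int(cfg$n_core_families, 1)
    gene_id <- sprintf("%s_g%03d", rep_gid, fam_k)
    seq <- db$gene_seq[[gene_id]]
    ss <- truth$seg_sites[[sdp]]
    strain_i <- sample.int(cfg$n_strains, 1)
    if (nrow(ss)) {
      here <- which(ss$gene_id == gene_id &
                      attr(ss, "alleles")[, strain_i] == 1L)
      if (length(here)) {
        v <- strsplit(seq, "")[[1]]
        v[ss$pos[here]] <- ss$alt[here]
        seq <- paste(v, collapse = "")
      }
    }
    if (cfg$orf_divergence > 0)
      seq <- .mutate(seq, cfg$orf_divergence)$seq
    orf_seqs[k] <- seq
    orf_truth$family_id[k] <- db$genes$family_id[
      match(gene_id, db$genes$gene_id)]
    orf_truth$sdp[k] <- sdp
  }
  orfs <- Biostrings::DNAStringSet(orf_seqs)
  names(orfs) <- orf_ids

  out <- list(coverage = coverage, snv = snv, orfs = orfs,
              orf_truth = orf_truth, metadata = meta,
              sample_truth = sample_truth, bee_strains = bee_strains,
              recruitment_counts = recruit)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(data.frame(gene_id = rownames(coverage), coverage,
                                  check.names = FALSE),
                       file.path(dir, "coverage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(snv, file.path(dir, "snv_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(orfs, file.path(dir, "orfs.fasta"))
    out$paths <- dir
  }
  out
}
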