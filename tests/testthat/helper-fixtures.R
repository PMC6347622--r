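# Shared fixtures, built in code. Heavier synthetic bundles are cached per
# test run so several test files can reuse them.

.fix <- new.env(parent = emptyenv())

# Hand-written 2-genome miniature database on disk: two contigs, three
# genes each (one short gene to exercise the length filter), two core
# families.
write_mini_db <- function(dir = tempfile("minidb_"),
                          gene_lengths = c(500, 400, 250)) {
  dir.create(dir)
  set.seed(101)
  base <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  mk_contig <- function(mut) {
    v <- strsplit(base, "")[[1]]
    idx <- seq(1, 1500, by = round(1 / mut))
    for (p in idx) v[p] <- c(A = "C", C = "G", G = "T", T = "A")[v[p]]
    paste(v, collapse = "")
  }
  contigs <- c(gA_c1 = base, gB_c1 = mk_contig(0.05))
  for (g in c("gA", "gB")) {
    writeLines(c(paste0(">", g, "_c1"), contigs[[paste0(g, "_c1")]]),
               file.path(dir, paste0(g, ".fasta")))
  }
  starts <- c(0, 600, 1100)
  bed <- do.call(rbind, lapply(c("gA", "gB"), function(g)
    data.frame(contig = paste0(g, "_c1"), start = starts,
               end = starts + gene_lengths,
               name = paste0(g, "_", c("g1", "g2", "g3")), score = 0,
               strand = "+")))
  write.table(bed, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(
    family_id = rep(c("f1", "f2", "f3"), 2),
    gene_id = c("gA_g1", "gA_g2", "gA_g3", "gB_g1", "gB_g2", "gB_g3"),
    phylotype = "PX", single_copy = TRUE)
  write.table(fam, file.path(dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(dir = dir,
       genomes = c(gA = file.path(dir, "gA.fasta"),
                   gB = file.path(dir, "gB.fasta")),
       bed = file.path(dir, "genes.bed"),
       families = file.path(dir, "families.tsv"))
}

# Small planted-structure bundle: 1 phylotype, 2 SDPs x 3 genomes,
# conserved families for the cross-SDP filter, strains + islands.
small_cfg <- function(...) {
  sim_config(n_phylotypes = 1, n_sdps = 2, n_genomes_per_sdp = 3,
             n_core_families = 30, mean_gene_length = 400,
             n_conserved_families = 3, n_strains = 4, strains_per_bee = 2,
             islands_per_strain = 1, genes_per_island = 5,
             island_gene_length = 2000, snv_rate = 0.02,
             bees_per_sampling = 2, n_orfs = 60, ...)
}

small_bundle <- function() {
  if (is.null(.fix$small)) {
    cfg <- small_cfg()
    ref <- gen_reference(cfg, seed = 11)
    smp <- gen_samples(cfg, ref$truth, ref$db, seed = 12)
    .fix$small <- list(cfg = cfg, ref = ref, smp = smp)
  }
  .fix$small
}

# quantification taxa list for a bundle (planted partition, filtered
# families, genomes restricted per SDP)
bundle_taxa <- function(bundle, phylotype = "P1") {
  ref <- bundle$ref
  ani <- core_gene_ani(ref$db, phylotype)
  part <- candidate_sdps(ani)
  kept <- filter_core_families(ref$db, part, phylotype)
  sdps <- unique(ref$truth$partition)
  taxa <- lapply(sdps, function(sdp) {
    list(reference_genome = ref$truth$representative[[sdp]],
         families = kept,
         genomes = names(ref$truth$partition)[
           ref$truth$partition == sdp])
  })
  names(taxa) <- sdps
  list(taxa = taxa, partition = part, families = kept)
}

# independently coded brute-force SNV filter (the oracle the cascade is
# checked against); works on plain vectors/loops on purpose
brute_force_snv_filter <- function(ab, gene_of, gene_cov, ter,
                                   min_ter = 10, min_gene = 10,
                                   min_freq = 0.1) {
  out <- ab
  for (j in seq_len(ncol(ab))) {
    for (i in seq_len(nrow(ab))) {
      if (ter[j] < min_ter) { out[i, j] <- NA; next }
      if (gene_cov[gene_of[i], j] < min_gene) { out[i, j] <- NA; next }
      if (!is.na(out[i, j]) && out[i, j] < min_freq) out[i, j] <- 0
    }
  }
  keep <- logical(nrow(ab))
  for (i in seq_len(nrow(ab))) {
    r <- out[i, ]
    r <- r[!is.na(r)]
    if (length(r) == 0) next
    if (max(r) < min_freq) next
    if (all(r >= 1) || all(r <= 0)) next
    keep[i] <- TRUE
  }
  list(abundance = out, keep = keep)
}
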