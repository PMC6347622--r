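# Small explicit SNV scenario shared by several blocks: one taxon, genes
# from the small bundle's representative genome, hand-set coverages.
snv_scenario <- function() {
  b <- small_bundle()
  db <- b$ref$db
  rep_gid <- b$ref$truth$representative[[1]]
  sdp <- b$ref$truth$partition[[rep_gid]]
  genes <- db$genes$gene_id[db$genes$genome_id == rep_gid &
                              !is.na(db$genes$family_id) &
                              db$genes$family_id %in%
                              db$families$family_id[db$families$single_copy]]
  fams <- db$genes$family_id[match(genes, db$genes$gene_id)]
  list(b = b, db = db, sdp = sdp, genes = genes, fams = fams)
}

test_that("the filter cascade applies rules in order on a hand-checked
          table", {
  sc <- snv_scenario()
  samples <- c("S1", "S2", "S3")
  cand <- data.frame(taxon = sc$sdp, gene_id = sc$genes[c(1, 1, 2, 3)],
                     pos = c(5, 17, 9, 30),
                     ref = "A", alt = "G",
                     S1 = c(0.05, 1.0, 0.5, 1.0),
                     S2 = c(0.50, 1.0, 0.6, 1.0),
                     S3 = c(0.20, 1.0, 0.2, 1.0))
  cov <- matrix(20, nrow = nrow(sc$db$genes), ncol = 3,
                dimnames = list(sc$db$genes$gene_id, samples))
  cov[sc$genes[2], "S3"] <- 4   # rule (ii): gene below 10x in S3
  ter <- c(S1 = 50, S2 = 50, S3 = 5)  # rule (i): S3 ineligible anyway
  tab <- filter_snvs(cand, cov, ter, unique(sc$fams), sc$db)
  # S3 wholly missing by rule (i)
  expect_false(tab$eligible[["S3"]])
  # site 1: 0.05 zeroed in S1, kept (0.5 in S2, not fixed)
  i1 <- which(tab$sites$pos == 5)
  expect_length(i1, 1)
  expect_equal(unname(tab$abundance[i1, "S1"]), 0)
  expect_equal(unname(tab$abundance[i1, "S2"]), 0.5)
  expect_true(is.na(tab$abundance[i1, "S3"]))
  # sites at 1.0 everywhere scored are dropped as fixed
  expect_false(any(tab$sites$pos %in% c(17, 30)))
  expect_gte(tab$ledger[["fixed_or_absent"]], 2)
})

test_that("candidate positions outside gene bounds are fatal", {
  sc <- snv_scenario()
  cand <- data.frame(taxon = sc$sdp, gene_id = sc$genes[1], pos = 10000,
                     ref = "A", alt = "G", S1 = 0.5)
  cov <- matrix(20, nrow = nrow(sc$db$genes), ncol = 1,
                dimnames = list(sc$db$genes$gene_id, "S1"))
  expect_error(filter_snvs(cand, cov, c(S1 = 50), unique(sc$fams),
                           sc$db),
               "coordinate mismatch")
})

test_that("the cascade equals an independently coded brute-force filter
          on random tables", {
  sc <- snv_scenario()
  set.seed(91)
  glen <- sc$db$genes$length[match(sc$genes, sc$db$genes$gene_id)]
  for (rep in 1:40) {
    n_sites <- sample(5:40, 1)
    n_samp <- sample(2:8, 1)
    gidx <- sample(seq_along(sc$genes), n_sites, replace = TRUE)
    samples <- sprintf("S%02d", seq_len(n_samp))
    ab <- matrix(round(runif(n_sites * n_samp), 2), n_sites, n_samp)
    # sprinkle exact 0s and 1s
    ab[runif(length(ab)) < 0.2] <- 0
    ab[runif(length(ab)) < 0.1] <- 1
    cand <- data.frame(taxon = sc$sdp, gene_id = sc$genes[gidx],
                       pos = pmin(glen[gidx],
                                  sample(1:300, n_sites, TRUE)),
                       ref = "A", alt = "G")
    cand[samples] <- as.data.frame(ab)
    cov <- matrix(sample(c(2, 5, 15, 40), nrow(sc$db$genes) * n_samp,
                         TRUE) * 1.0,
                  nrow = nrow(sc$db$genes),
                  dimnames = list(sc$db$genes$gene_id, samples))
    ter <- stats::setNames(sample(c(3, 12, 60), n_samp, TRUE), samples)
    got <- filter_snvs(cand, cov, ter, unique(sc$fams), sc$db)
    oracle <- brute_force_snv_filter(
      ab, gene_of = cand$gene_id, gene_cov = cov, ter = ter)
    expect_equal(unname(got$abundance),
                 unname(oracle$abundance[oracle$keep, , drop = FALSE]))
    expect_equal(nrow(got$sites), sum(oracle$keep))
  }
})

test_that("polymorphic fractions follow their definitions", {
  sc <- snv_scenario()
  samples <- c("S1", "S2")
  # 10 intermediate sites in sample S1; S2 all fixed at 1 (still
  # polymorphic across samples, but no within-sample polymorphism)
  cand <- data.frame(taxon = sc$sdp,
                     gene_id = sc$genes[rep(1:2, 5)],
                     pos = 1:10, ref = "A", alt = "G",
                     S1 = rep(0.5, 10), S2 = rep(1.0, 10))
  cov <- matrix(20, nrow = nrow(sc$db$genes), ncol = 2,
                dimnames = list(sc$db$genes$gene_id, samples))
  tab <- filter_snvs(cand, cov, c(S1 = 50, S2 = 50), unique(sc$fams),
                     sc$db)
  expect_equal(nrow(tab$sites), 10)
  expect_equal(polymorphic_fraction(tab), 10 / tab$core_length)
  ps <- polymorphic_fraction(tab, "per_sample")
  expect_equal(unname(ps["S1"]), 10 / tab$scored_bp[["S1"]])
  expect_equal(unname(ps["S2"]), 0)
})

test_that("cumulative curves are monotone with an order-invariant
          endpoint equal to the overall fraction", {
  b <- small_bundle()
  sc <- snv_scenario()
  tax <- bundle_taxa(b)
  sdp <- names(tax$taxa)[1]
  tr <- b$smp$sample_truth
  ter <- with(tr[tr$sdp == sdp, ], stats::setNames(terminus, sample_id))
  cand <- b$smp$snv[b$smp$snv$taxon == sdp, ]
  tab <- filter_snvs(cand, b$smp$coverage, ter, tax$families, b$ref$db)
  cc <- cumulative_curves(tab, n_orders = 10, seed = 5)
  expect_true(all(apply(cc, 1, function(r) all(diff(r) >= -1e-12))))
  expect_equal(stats::sd(cc[, ncol(cc)]), 0)
  expect_equal(cc[1, ncol(cc)], polymorphic_fraction(tab),
               tolerance = 1e-12)
  # identical SNV content in all samples gives a flat curve
  ab1 <- tab$abundance
  ab1[] <- rep(ab1[, 1], ncol(ab1))
  tab2 <- tab
  tab2$abundance <- ab1
  cc2 <- cumulative_curves(tab2, n_orders = 3, seed = 1)
  expect_true(all(abs(cc2 - cc2[, 1]) < 1e-15))
})

test_that("per-bee diversity sits below colony-wide diversity when
          strains segregate", {
  # 2 of 8 strains per bee: within-bee fraction must be strictly below
  # the overall fraction, across seeds
  for (seed in 1:6) {
    cfg <- sim_config(n_phylotypes = 1, n_sdps = 1, n_genomes_per_sdp = 1,
                      n_core_families = 20, mean_gene_length = 400,
                      n_strains = 8, strains_per_bee = 2,
                      islands_per_strain = 0, snv_rate = 0.05,
                      bees_per_sampling = 3, n_orfs = 0,
                      terminus_range = c(40, 80))
    ref <- gen_reference(cfg, seed = seed)
    smp <- gen_samples(cfg, ref$truth, ref$db, seed = seed + 100)
    sdp <- names(ref$truth$representative)[1]
    fams <- ref$db$families$family_id[ref$db$families$single_copy]
    tr <- smp$sample_truth
    ter <- with(tr[tr$sdp == sdp, ], stats::setNames(terminus, sample_id))
    tab <- filter_snvs(smp$snv, smp$coverage, ter, fams, ref$db)
    overall <- polymorphic_fraction(tab)
    per_bee <- polymorphic_fraction(tab, "per_sample")
    expect_lt(mean(per_bee), overall)
    expect_true(all(per_bee < overall))
  }
})

test_that("overall polymorphic fraction tracks the planted segregating
          fraction", {
  cfg <- sim_config(n_phylotypes = 1, n_sdps = 1, n_genomes_per_sdp = 1,
                    n_core_families = 25, mean_gene_length = 400,
                    n_strains = 6, strains_per_bee = 3,
                    islands_per_strain = 0, snv_rate = 0.04,
                    bees_per_sampling = 4, n_orfs = 0,
                    terminus_range = c(40, 80))
  ref <- gen_reference(cfg, seed = 77)
  smp <- gen_samples(cfg, ref$truth, ref$db, seed = 78)
  sdp <- names(ref$truth$representative)[1]
  fams <- ref$db$families$family_id[ref$db$families$single_copy]
  ter <- with(smp$sample_truth, stats::setNames(terminus, sample_id))
  tab <- filter_snvs(smp$snv, smp$coverage, ter, fams, ref$db)
  planted <- nrow(ref$truth$seg_sites[[sdp]]) /
    ref$truth$core_length[[sdp]]
  got <- polymorphic_fraction(tab)
  # nearly every planted site should surface across 36 bees
  expect_gt(got, 0.85 * planted)
  expect_lte(got, planted + 1e-12)
})

test_that("shared-SNV distances match hand counts and behave like a
          distance", {
  sc <- snv_scenario()
  # printed-style example: 100 co-scored sites, 30 + 20 discordant
  n <- 100
  ab <- matrix(0, n, 2, dimnames = list(NULL, c("A", "B")))
  ab[1:30, "A"] <- 0.5           # present only in A
  ab[31:50, "B"] <- 0.5          # present only in B
  ab[51:60, ] <- 0.9             # shared
  tab <- structure(list(sites = data.frame(idx = 1:n), abundance = ab,
                        eligible = c(A = TRUE, B = TRUE),
                        scored_bp = c(A = n, B = n), core_length = n,
                        min_freq = 0.1),
                   class = "SNVTable")
  d <- shared_snv_distance(tab)
  expect_equal(unname(d$dist["A", "B"]), (30 + 20) / 100)
  # identical samples at distance zero
  ab2 <- cbind(A = ab[, 1], B = ab[, 1])
  tab2 <- tab; tab2$abundance <- ab2
  expect_equal(unname(shared_snv_distance(tab2)$dist["A", "B"]), 0)
  # metric sanity on random tables
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(sample(c(0, 0.05, 0.3, 1, NA), 60, TRUE), 20, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    tb <- tab
    tb$abundance <- m
    tb$eligible <- c(A = TRUE, B = TRUE, C = TRUE)
    D <- shared_snv_distance(tb)$dist
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 3))
    expect_true(all(D[!is.na(D)] >= 0 & D[!is.na(D)] <= 1))
  }
})

test_that("strain-subset structure shows up in distances rather than
          colony labels", {
  b <- small_bundle()
  tax <- bundle_taxa(b)
  sdp <- names(tax$taxa)[1]
  tr <- b$smp$sample_truth
  ter <- with(tr[tr$sdp == sdp, ], stats::setNames(terminus, sample_id))
  cand <- b$smp$snv[b$smp$snv$taxon == sdp, ]
  tab <- filter_snvs(cand, b$smp$coverage, ter, tax$families, b$ref$db)
  D <- shared_snv_distance(tab)$dist
  # bees carrying the same strain pair should be closer than bees with
  # disjoint strain pairs
  key <- vapply(rownames(D), function(s)
    paste(sort(names(b$smp$bee_strains[[s]][[sdp]])), collapse = "+"),
    character(1))
  same <- outer(key, key, "==") & upper.tri(D)
  diff_pair <- !outer(key, key, "==") & upper.tri(D)
  if (any(same)) expect_lt(mean(D[same]), mean(D[diff_pair]))
  # colony labels should NOT structure the distances (shared pool)
  colony <- b$smp$metadata$colony[match(rownames(D),
                                        b$smp$metadata$sample_id)]
  same_c <- outer(colony, colony, "==") & upper.tri(D)
  expect_lt(abs(mean(D[same_c]) - mean(D[!same_c & upper.tri(D)])), 0.1)
})

test_that("sampling-design comparison behaves at the null and is
          deterministic under seed", {
  b <- small_bundle()
  tax <- bundle_taxa(b)
  sdp <- names(tax$taxa)[1]
  tr <- b$smp$sample_truth
  ter <- with(tr[tr$sdp == sdp, ], stats::setNames(terminus, sample_id))
  cand <- b$smp$snv[b$smp$snv$taxon == sdp, ]
  tab <- filter_snvs(cand, b$smp$coverage, ter, tax$families, b$ref$db)
  r1 <- sampling_subset_test(tab, b$smp$metadata, n_random = 9,
                             subset_size = 2, min_bees = 2,
                             min_samplings = 4, seed = 3)
  r2 <- sampling_subset_test(tab, b$smp$metadata, n_random = 9,
                             subset_size = 2, min_bees = 2,
                             min_samplings = 4, seed = 3)
  expect_identical(r1, r2)
  expect_null(r1$skipped)
  expect_gte(r1$p, 0)
  # degenerate null: every sample shows every site, so all subset
  # fractions coincide and the Welch comparison is t = 0, p = 1
  tab0 <- tab
  tab0$abundance[] <- 0.5
  r0 <- sampling_subset_test(tab0, b$smp$metadata, n_random = 5,
                             subset_size = 2, min_bees = 2,
                             min_samplings = 4, seed = 3)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # insufficient samplings are skipped with a reason
  meta2 <- b$smp$metadata[1:2, ]
  sk <- sampling_subset_test(tab, meta2, min_bees = 5, seed = 1)
  expect_match(sk$skipped, "samplings")
})

test_that("recruitment fractions are length-normalized and sum to one
          within SDPs", {
  counts <- matrix(c(100, 300, 50,
                     0,   0,   0), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  counts[, 2] <- c(10, 20, 0)
  core_len <- c(g1 = 1000, g2 = 3000, g3 = 500)
  part <- c(g1 = "X", g2 = "X", g3 = "Y")
  fr <- recruitment_fractions(counts, core_len, part)
  expect_equal(unname(colSums(fr[c("g1", "g2"), ])), c(1, 1))
  # length normalization: equal density gives equal fractions
  expect_equal(unname(fr["g1", "s1"]), 0.5)
  # empty SDP column stays zero
  expect_equal(unname(fr["g3", "s2"]), 0)
})
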