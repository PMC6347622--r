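test_that("normalization reproduces the worked example and is exactly
          linear", {
  raw <- matrix(c(25, 0, 7), 3, 1,
                dimnames = list(c("fa", "fb", "fc"), "s1"))
  m <- normalize_families(raw, c(s1 = 50))
  expect_equal(unname(m$normalized["fa", "s1"]), 5.0)
  expect_equal(unname(m$normalized["fb", "s1"]), 0.0)
  # terminus exactly 10 leaves values unchanged
  m10 <- normalize_families(raw, c(s1 = 10))
  expect_equal(m10$normalized[, 1], raw[, 1])
  # linearity in the raw coverages at fixed terminus
  m2 <- normalize_families(raw * 3, c(s1 = 50))
  expect_equal(m2$normalized, m$normalized * 3)
  # samples below 10x terminus are excluded with a log entry
  raw2 <- cbind(raw, s2 = c(4, 4, 4))
  expect_message(m3 <- normalize_families(raw2, c(s1 = 50, s2 = 6)),
                 "excluded 1 sample")
  expect_equal(m3$excluded_samples, "s2")
  expect_equal(colnames(m3$normalized), "s1")
})

test_that("variome assignment keys on any sample dipping below 1x and
          only grows with added samples", {
  raw <- matrix(c(2.1, 0.4, 9.8,
                  8, 9, 10,
                  0, 0, 0), 3, 3, byrow = TRUE,
                dimnames = list(c("dip", "core", "gone"),
                                c("s1", "s2", "s3")))
  m <- normalize_families(raw, c(s1 = 10, s2 = 10, s3 = 10))
  v <- assign_variome(m)
  expect_setequal(v$variable, c("dip", "gone"))
  # monotone: restricting to fewer samples can only shrink the variome
  m_less <- normalize_families(raw[, 1:2], c(s1 = 10, s2 = 10))
  v_less <- assign_variome(m_less)
  expect_true(all(v_less$variable %in% v$variable))
})

test_that("strain-private families land in the variome, shared families
          do not", {
  for (seed in 1:5) {
    cfg <- small_cfg()
    ref <- gen_reference(cfg, seed = seed)
    smp <- gen_samples(cfg, ref$truth, ref$db, seed = seed + 50)
    sdp <- names(ref$truth$representative)[1]
    # phylotype terminus = summed SDP termini; use planted truth
    tr <- smp$sample_truth
    ter <- tapply(tr$terminus, tr$sample_id, sum)
    ter <- stats::setNames(as.numeric(ter), names(ter))
    raw <- family_coverage(smp$coverage, ref$db)
    m <- normalize_families(raw, ter)
    v <- assign_variome(m)
    acc <- grep("accfam", rownames(raw), value = TRUE)
    core <- ref$db$families$family_id[ref$db$families$single_copy]
    # every strain-private accessory family is variable
    expect_true(all(acc %in% v$variable))
    # core families present in all genomes are never variable
    expect_false(any(core %in% v$variable))
  }
})

test_that("SDP correlation labels follow the unique-correlate rule", {
  set.seed(4)
  n <- 12
  sdpA <- runif(n, 20, 120)
  sdpB <- runif(n, 20, 120)
  raw <- rbind(propA = 0.3 * sdpA,       # proportional to A: r = 1
               both = 2 * sdpA + 2 * sdpB,
               noise = runif(n, 1, 100))
  colnames(raw) <- sprintf("s%02d", 1:n)
  m <- normalize_families(raw, stats::setNames(rep(20, n), colnames(raw)))
  v <- structure(list(variable = rownames(raw)), class = "VariomeSet")
  sdp_ter <- cbind(A = sdpA, B = sdpB)
  rownames(sdp_ter) <- colnames(raw)
  v <- correlate_with_sdps(v, m, sdp_ter)
  expect_equal(unname(v$sdp_label["propA"]), "A")
  expect_equal(unname(v$sdp_r["propA", "A"]), 1.0, tolerance = 1e-12)
  # a family tracking both SDPs equally must stay unlabelled if both
  # exceed the threshold, labelled A/B only if exactly one does
  hits <- which(!is.na(v$sdp_r["both", ]) & v$sdp_r["both", ] > 0.8)
  if (length(hits) == 2) expect_true(is.na(v$sdp_label[["both"]]))
  # constant vector: correlation undefined, label NA
  raw2 <- rbind(const = rep(5, n))
  colnames(raw2) <- colnames(raw)
  m2 <- normalize_families(raw2, stats::setNames(rep(20, n),
                                                 colnames(raw)))
  v2 <- structure(list(variable = "const"), class = "VariomeSet")
  v2 <- correlate_with_sdps(v2, m2, sdp_ter)
  expect_true(is.na(v2$sdp_label[["const"]]))
})

test_that("island chaining arithmetic matches constructed coordinates", {
  # 6 genes of 2 kb spaced 1 kb apart: one island spanning 17 kb
  mk_db <- function(starts, len = 2000, contig = "c1", genome = "g1") {
    genes <- data.frame(
      gene_id = sprintf("%s_G%d", genome, seq_along(starts)),
      genome_id = genome, contig_id = contig, start = starts,
      end = starts + len, strand = "+", length = len,
      family_id = sprintf("F%d", seq_along(starts)),
      stringsAsFactors = FALSE)
    structure(list(genes = genes,
                   family_members = split(genes$gene_id,
                                          genes$family_id)),
              class = "ReferenceDB")
  }
  db <- mk_db(starts = (0:5) * 3000)
  isl <- build_islands(db, sprintf("F%d", 1:6))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$length, 17000)
  expect_equal(isl$n_genes, 6)
  expect_true(isl$is_big)

  # gap of exactly 5 kb splits, just under joins
  db2 <- mk_db(starts = c(0, 7000))        # gap = 5000
  expect_equal(nrow(build_islands(db2, c("F1", "F2"))), 2)
  db3 <- mk_db(starts = c(0, 6999))        # gap = 4999
  expect_equal(nrow(build_islands(db3, c("F1", "F2"))), 1)
  # two genes 6 kb apart: two singleton islands, neither big
  db4 <- mk_db(starts = c(0, 8000))
  isl4 <- build_islands(db4, c("F1", "F2"))
  expect_equal(nrow(isl4), 2)
  expect_false(any(isl4$is_big))
})

test_that("islands never chain across contigs and are input-order
          invariant", {
  genes <- data.frame(
    gene_id = c("a1", "a2", "b1"),
    genome_id = "g1", contig_id = c("c1", "c1", "c2"),
    start = c(0, 3000, 100), end = c(2000, 5000, 2100), strand = "+",
    length = 2000, family_id = c("F1", "F2", "F3"),
    stringsAsFactors = FALSE)
  db <- structure(list(genes = genes,
                       family_members = split(genes$gene_id,
                                              genes$family_id)),
                  class = "ReferenceDB")
  isl <- build_islands(db, c("F1", "F2", "F3"))
  expect_equal(nrow(isl), 2)
  db_rev <- db
  db_rev$genes <- genes[c(3, 1, 2), ]
  expect_equal(build_islands(db_rev, c("F1", "F2", "F3")), isl)
})

test_that("redundant big islands (family subset of another) are removed", {
  starts <- (0:5) * 3000
  genes <- rbind(
    data.frame(gene_id = sprintf("gX_G%d", 1:6), genome_id = "gX",
               contig_id = "cX", start = starts, end = starts + 2000,
               strand = "+", length = 2000,
               family_id = sprintf("F%d", 1:6)),
    data.frame(gene_id = sprintf("gY_G%d", 1:5), genome_id = "gY",
               contig_id = "cY", start = starts[1:5],
               end = starts[1:5] + 2000, strand = "+", length = 2000,
               family_id = sprintf("F%d", 1:5)))
  db <- structure(list(genes = genes,
                       family_members = split(genes$gene_id,
                                              genes$family_id)),
                  class = "ReferenceDB")
  isl <- build_islands(db, sprintf("F%d", 1:6))
  expect_equal(nrow(isl), 2)
  expect_true(all(isl$is_big))
  # the 5-family island is a subset of the 6-family one
  red <- isl$redundant
  expect_equal(isl$genome_id[red], "gY")
})

test_that("island presence uses an inclusive 80% family threshold", {
  isl <- data.frame(island_id = "I1", genome_id = "g", contig_id = "c",
                    start = 0, end = 17000, length = 17000, n_genes = 5,
                    is_big = TRUE,
                    gene_ids = "a,b,c,d,e",
                    family_ids = "F1,F2,F3,F4,F5", redundant = FALSE)
  mk_m <- function(n_present) {
    norm <- matrix(0.2, 5, 1, dimnames = list(sprintf("F%d", 1:5), "s1"))
    if (n_present > 0) norm[seq_len(n_present), 1] <- 1.0  # boundary
    structure(list(normalized = norm), class = "GeneFamilyMatrix")
  }
  expect_true(island_occurrence(isl, mk_m(4))$present["I1", "s1"])
  expect_false(island_occurrence(isl, mk_m(3))$present["I1", "s1"])
})

test_that("island frequencies track the planted carrier strain", {
  b <- small_bundle()
  ref <- b$ref; smp <- b$smp
  tr <- smp$sample_truth
  ter <- tapply(tr$terminus, tr$sample_id, sum)
  ter <- stats::setNames(as.numeric(ter), names(ter))
  raw <- family_coverage(smp$coverage, ref$db)
  m <- normalize_families(raw, ter)
  v <- assign_variome(m)
  isl <- build_islands(ref$db, v)
  occ <- island_occurrence(isl, m)
  planted <- ref$truth$islands
  for (i in seq_len(nrow(planted))) {
    iid <- isl$island_id[isl$start == planted$start[i] &
                           isl$genome_id == planted$genome_id[i]]
    if (!length(iid) || !iid %in% rownames(occ$present)) next
    carrier <- planted$strain[i]
    sdp <- planted$sdp[i]
    carried <- vapply(colnames(occ$present), function(s)
      carrier %in% names(smp$bee_strains[[s]][[sdp]]), logical(1))
    # presence implies carriage (low-weight carriers can drop below the
    # 1x detection limit, so the converse is only approximate)
    expect_true(all(carried[occ$present[iid, ]]))
    expect_lte(occ$frequency[[iid]], mean(carried) + 0.1)
  }
})

test_that("variome distances match hand counts and metric sanity", {
  # presence sets {a,b,c} vs {b,c,d}: Jaccard distance 2/4
  norm <- matrix(0, 4, 2, dimnames = list(c("a", "b", "c", "d"),
                                          c("s1", "s2")))
  norm[c("a", "b", "c"), "s1"] <- 5
  norm[c("b", "c", "d"), "s2"] <- 5
  m <- structure(list(normalized = norm), class = "GeneFamilyMatrix")
  d <- variome_distance(m, rownames(norm))
  expect_equal(unname(d$dist["s1", "s2"]), 0.5)
  # identical sets at distance 0; symmetry; zero diagonal
  norm2 <- cbind(norm[, 1, drop = FALSE], s2 = norm[, 1])
  m2 <- structure(list(normalized = norm2), class = "GeneFamilyMatrix")
  expect_equal(unname(variome_distance(m2, rownames(norm))$dist["s1",
                                                                "s2"]), 0)
  expect_equal(d$dist, t(d$dist))
  expect_equal(unname(diag(d$dist)), c(0, 0))
  # sample with empty presence is flagged, distance 1
  norm3 <- norm; norm3[, 2] <- 0
  m3 <- structure(list(normalized = norm3), class = "GeneFamilyMatrix")
  d3 <- variome_distance(m3, rownames(norm))
  expect_equal(d3$empty_samples, "s2")
  expect_equal(unname(d3$dist["s1", "s2"]), 1)
})
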