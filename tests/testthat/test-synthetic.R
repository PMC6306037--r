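# synthetic-data generators: determinism, planted truth, degenerate cases

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_pangenome(n_genomes = 8, core_size = 50, kappa = 200,
                          gamma = 0.5, seed = 11)
  b <- simulate_pangenome(n_genomes = 8, core_size = 50, kappa = 200,
                          gamma = 0.5, seed = 11)
  expect_identical(unclass(a), unclass(b))
  ia <- simulate_identity_matrix(c(3, 2), seed = 7)
  ib <- simulate_identity_matrix(c(3, 2), seed = 7)
  expect_identical(unclass(ia$matrix), unclass(ib$matrix))
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  pa <- simulate_predation(tr, n_prey = 4, congruence = 0.5, seed = 3)
  pb <- simulate_predation(tr, n_prey = 4, congruence = 0.5, seed = 3)
  expect_identical(unclass(pa), unclass(pb))
  ca <- simulate_contigs(5000, 10, seed = 9)
  cb <- simulate_contigs(5000, 10, seed = 9)
  expect_identical(ca, cb)
})

test_that("vanishing accessory influx yields a core-only matrix", {
  m <- simulate_pangenome(n_genomes = 6, core_size = 80, kappa = 1e-9,
                          gamma = 0.5, seed = 1)
  expect_equal(nrow(m), 80)
  expect_true(all(unclass(m)))
  p <- partition(m)
  expect_equal(p$counts[1], p$pan_size)   # 100% hard core
})

test_that("pangenome generator validates its parameter ranges", {
  expect_error(simulate_pangenome(kappa = -1), "kappa")
  expect_error(simulate_pangenome(gamma = 1.2), "gamma")
  expect_error(simulate_pangenome(gamma = 0), "gamma")
  expect_error(simulate_pangenome(n_genomes = 1), "n_genomes")
  expect_error(simulate_pangenome(retention = 0), "retention")
})

test_that("identity generator plants recoverable species structure", {
  two <- simulate_identity_matrix(c(2, 2), within = c(96, 99),
                                  between_species = c(85, 90),
                                  noise_sd = 0.1, seed = 5)
  g <- delimit(two$matrix)
  expect_equal(unname(g$species_count_range[["min"]]), 2)
  expect_true(g$genus_ok)
  expect_equal(nrow(g$conflicts), 0)
  one <- simulate_identity_matrix(5, seed = 5)
  g1 <- delimit(one$matrix)
  expect_equal(unname(g1$species_count_range[["max"]]), 1)
})

test_that("identity generator rejects ranges that could overlap after noise", {
  expect_error(
    simulate_identity_matrix(c(2, 2), within = c(94, 99),
                             subspecies_band = c(93, 94.5), noise_sd = 0.5),
    "overlap")
})

test_that("nine-species preset has 11 tight clusters, 9 merged species", {
  nine <- simulate_nine_species(seed = 2)
  expect_equal(length(unique(cluster_at_threshold(nine$matrix, 95))), 11)
  # subspecies band links close the split pairs at the 92% separation tier
  expect_equal(length(unique(cluster_at_threshold(nine$matrix, 92,
                                                  strict = TRUE))), 9)
  expect_equal(nrow(nine$truth), 24)
  expect_equal(length(unique(nine$truth$species)), 9)
  ddh <- simulate_nine_species("dDDH", seed = 2)
  counts <- vapply(ddh_groups(ddh$matrix), function(x) length(unique(x)), 1)
  expect_equal(unname(counts[c("gt50", "gt30")]), c(11, 9))
})

test_that("annotation generator plants recoverable enrichment and no more", {
  m <- simulate_pangenome(n_genomes = 12, core_size = 400, kappa = 1500,
                          gamma = 0.55, seed = 8)
  p <- partition(m)
  base <- c(E = 10, J = 8, Q = 2.6, L = 9, K = 8, C = 7, G = 6, M = 5,
            T = 5, P = 5, F = 4, H = 3, V = 2, W = 0.7)
  none <- simulate_annotations(p, base, planted = numeric(0), seed = 3)
  res0 <- enrich_core_accessory(none$annotations, p)
  expect_true(all(res0$call == "none"))
  planted <- simulate_annotations(p, base, planted = c(Q = log2(2.4)), seed = 3)
  res <- enrich_core_accessory(planted$annotations, p)
  expect_equal(res$call[res$category == "Q"], "enriched")
  expect_error(simulate_annotations(p, base, planted = c(Z = 1)), "absent")
  again <- simulate_annotations(p, base, planted = c(Q = log2(2.4)), seed = 3)
  expect_identical(planted$annotations, again$annotations)
})

test_that("predation diameters are non-negative and congruence limits behave", {
  set.seed(20)
  tr <- ape::rcoal(10)
  for (cg in c(0, 0.5, 1)) {
    pm <- simulate_predation(tr, n_prey = 6, congruence = cg, seed = 4)
    expect_true(all(pm >= 0))
    expect_equal(dim(pm), c(10L, 6L))
  }
  # full congruence, many prey: profile tree matches the source topology
  pm1 <- simulate_predation(tr, n_prey = 200, congruence = 1, seed = 4)
  ptree <- neighbor_joining(distance_from_profile(pm1))
  expect_equal(tanglegram(tr, ptree)$rf, 0)
  expect_error(simulate_predation(tr, congruence = 1.4), "congruence")
  expect_error(simulate_predation(list(), 5, 0.5), "tree")
})

test_that("contig generator respects size, counts and GC", {
  contigs <- simulate_contigs(100000, 25, gc = 0.699, seed = 6)
  expect_equal(sum(nchar(contigs)), 100000)
  expect_equal(length(contigs), 25)
  expect_true(all(grepl("_length_\\d+_cov_", names(contigs))))
  expect_true(abs(gc_content(contigs) - 69.9) <= 1)
  expect_error(simulate_contigs(5, 10), "genome_size")
  one <- simulate_contigs(400, 1, seed = 2)
  expect_equal(nchar(unname(one)), 400)
})
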