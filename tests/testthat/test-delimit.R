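# tiered genomospecies delimitation and grouping concordance

test_that("threshold clustering finds connected components", {
  all96 <- block_ani(within = 96, between = 96, sizes = c(2, 2))
  expect_equal(length(unique(cluster_at_threshold(all96, 95))), 1)
  blocks <- block_ani(within = 96, between = 85, sizes = c(3, 2))
  cl <- cluster_at_threshold(blocks, 95)
  expect_equal(unname(cl), c(1, 1, 1, 2, 2))
  distinct <- block_ani(within = 99, between = 90, sizes = c(1, 1, 1))
  expect_equal(length(unique(cluster_at_threshold(distinct, 100))), 3)
})

test_that("clusters at a higher threshold refine those at a lower one", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    v <- matrix(runif(n * n, 70, 100), n, n)
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    diag(v) <- 100
    dimnames(v) <- list(paste0("g", 1:n), paste0("g", 1:n))
    im <- identity_matrix(v)
    lo <- cluster_at_threshold(im, 80)
    hi <- cluster_at_threshold(im, 93)
    # each high-threshold cluster sits inside one low-threshold cluster
    expect_true(all(tapply(lo, hi, function(x) length(unique(x))) == 1))
  }
})

test_that("subspecies band merges species pairs and sets the count range", {
  pair <- identity_matrix(matrix(c(100, 93.5, 93.5, 100), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
  g <- delimit(pair)
  expect_equal(unname(g$species_count_range), c(1, 2))   # one species, two subspecies
  expect_true(g$genus_ok)
  low <- identity_matrix(matrix(c(100, 74, 74, 100), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
  expect_false(delimit(low)$genus_ok)
})

test_that("delimit reports conflicts instead of adjudicating them", {
  # value in the unnamed gap (92, 93)
  gap <- identity_matrix(matrix(c(100, 92.5, 92.5, 100), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
  g <- delimit(gap)
  expect_equal(nrow(g$conflicts), 1)
  expect_match(g$conflicts$reason, "unnamed gap")
  # transitivity violation: a-b and b-c same species, a-c below threshold
  v <- matrix(c(100, 96, 91,
                96, 100, 96,
                91, 96, 100), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g2 <- delimit(identity_matrix(v))
  expect_equal(unname(g2$species_count_range), c(1, 1))
  expect_true(any(grepl("below species threshold", g2$conflicts$reason)))
})

test_that("delimit is invariant under genome relabelling", {
  nine <- simulate_nine_species(seed = 4)
  g1 <- delimit(nine$matrix)
  set.seed(2)
  perm <- sample(nrow(nine$matrix))
  m2 <- identity_matrix(unclass(nine$matrix)[perm, perm])
  g2 <- delimit(m2)
  expect_equal(unname(g1$species_count_range), unname(g2$species_count_range))
  # same partition up to cluster renaming
  expect_equal(length(unique(g1$merged_species)),
               length(unique(g2$merged_species)))
  co <- compare_groupings(g1$merged_species, g2$merged_species)
  expect_equal(co$rand, 1)
})

test_that("delimit requires an ANI matrix", {
  d <- simulate_nine_species("dDDH", seed = 1)
  expect_error(delimit(d$matrix), "ANI")
})

test_that("dDDH groupings at strict thresholds behave like components", {
  all80 <- identity_matrix(matrix(c(100, 80, 80, 100), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
                           kind = "dDDH")
  gr <- ddh_groups(all80)
  expect_true(all(vapply(gr, function(x) length(unique(x)), 1) == 1))
  blocks <- block_ani(within = 60, between = 20, sizes = c(3, 3))
  blocks <- identity_matrix(unclass(blocks), kind = "dDDH")
  g50 <- ddh_groups(blocks, 50)[[1]]
  expect_equal(length(unique(g50)), 2)
  g70 <- ddh_groups(blocks, 70)[[1]]
  expect_equal(length(unique(g70)), 6)
  # a >70 tier can split one >50 group into three
  v <- matrix(55, 6, 6)
  v[1:2, 1:2] <- 80; v[3:4, 3:4] <- 80; v[5:6, 5:6] <- 80
  diag(v) <- 100
  dimnames(v) <- list(paste0("g", 1:6), paste0("g", 1:6))
  split3 <- identity_matrix(v, kind = "dDDH")
  counts <- vapply(ddh_groups(split3, c(70, 50)),
                   function(x) length(unique(x)), 1)
  expect_equal(unname(counts), c(3, 1))
})

test_that("grouping concordance is pair-counting (Rand) with a brute-force check", {
  a <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 2)
  expect_equal(compare_groupings(a, a)$rand, 1)
  singletons <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  block <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1)
  # brute force: all 6 pairs disagree
  expect_equal(compare_groupings(singletons, block)$rand, 0)
  b <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 3)
  pairs <- combn(names(a), 2)
  agree <- sum(apply(pairs, 2, function(p) {
    (a[p[1]] == a[p[2]]) == (b[p[1]] == b[p[2]])
  }))
  expect_equal(compare_groupings(a, b)$rand, agree / ncol(pairs))
  expect_error(compare_groupings(a, c(x = 1)), "same genome set")
})

test_that("ANI-95 and dDDH-50 groupings agree on planted data", {
  ani <- simulate_nine_species("ANI", seed = 8)
  ddh <- simulate_nine_species("dDDH", seed = 9)
  a95 <- cluster_at_threshold(ani$matrix, 95)
  d50 <- ddh_groups(ddh$matrix, 50)[[1]]
  expect_equal(compare_groupings(a95, d50)$rand, 1)
})
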