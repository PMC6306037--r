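# distances, neighbor joining, bootstrap and tanglegram congruence

test_that("K2P matches the closed form and masks ambiguous sites", {
  same <- c(a = "ACGTACGT", b = "ACGTACGT")
  expect_equal(as.matrix(k2p_distance(same))[1, 2], 0)
  # 100 sites, 10 transitions (A->G), 5 transversions (A->C)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  d <- as.matrix(k2p_distance(c(x = a, y = b)))[1, 2]
  expect_lt(abs(d - 0.1702), 1e-4)
  # a pair differing only at an N site is at distance zero
  n1 <- c(p = "ACGTN", q = "ACGTG")
  expect_equal(as.matrix(k2p_distance(n1))[1, 2], 0)
  # saturated pair: correction undefined -> NA
  sat <- c(p = "AAAA", q = "GGGG")
  expect_true(is.na(as.matrix(k2p_distance(sat))[1, 2]))
})

test_that("K2P agrees with an independent implementation on random alignments", {
  set.seed(17)
  for (i in 1:5) {
    n <- 5; L <- 300
    mat <- matrix(sample(c("a", "c", "g", "t"), n * L, TRUE), n, L,
                  dimnames = list(paste0("s", 1:n), NULL))
    # introduce shared structure so distances are finite
    mat[2, ] <- mat[1, ]; idx <- sample(L, 30); mat[2, idx] <- "g"
    seqs <- apply(mat, 1, paste, collapse = "")
    ours <- as.matrix(k2p_distance(seqs))
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                                   pairwise.deletion = TRUE))
    ok <- is.finite(ref) & !is.na(ours)
    expect_equal(ours[ok], ref[ok], tolerance = 1e-10)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(23)
  for (i in 1:20) {
    tr <- random_additive_tree(sample(4:10, 1))
    d <- ape::cophenetic.phylo(tr)
    rec <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rec)), 0)
    drec <- ape::cophenetic.phylo(rec)[rownames(d), colnames(d)]
    expect_equal(drec, d, tolerance = 1e-8)
  }
})

test_that("three taxa give the closed-form star tree", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)   # = 1
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)   # = 2
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)   # = 3
  expect_warning(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "trivial")
})

test_that("identity and profile distances follow their formulas", {
  im <- block_ani(within = 100, between = 82, sizes = c(2, 1))
  d <- as.matrix(distance_from_identity(im))
  expect_equal(d["g1", "g2"], 0)
  expect_equal(d["g1", "g3"], 0.18)
  # monotone: higher identity, strictly smaller distance
  vals <- seq(80, 99, by = 1)
  dd <- (100 - vals) / 100
  expect_true(all(diff(dd) < 0))
  # jaccard on binary profiles
  b <- rbind(x = c(1, 1, 0), y = c(1, 0, 1))
  expect_equal(as.matrix(distance_from_profile(b, "jaccard"))["x", "y"], 2 / 3)
  # identical rows at distance zero; column permutation changes nothing
  p <- rbind(s1 = c(3, 5, 2, 8), s2 = c(3, 5, 2, 8), s3 = c(1, 9, 4, 2))
  dp <- as.matrix(distance_from_profile(p))
  expect_equal(dp["s1", "s2"], 0)
  dp2 <- as.matrix(distance_from_profile(p[, c(3, 1, 4, 2)]))
  expect_equal(dp2, dp)
  expect_warning(distance_from_profile(cbind(p, k = c(1, 1, 1))),
                 "zero-variance")
})

test_that("bootstrap supports separate clean clades and stay in range", {
  set.seed(31)
  mutate <- function(s, k) {
    idx <- sample(nchar(s), k)
    for (i in idx) substring(s, i, i) <- sample(c("A", "C", "G", "T"), 1)
    s
  }
  block <- function(base, k) vapply(seq_len(k), function(i) mutate(base, 4), "")
  b1 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  b2 <- mutate(b1, 40)   # two clades ~20% apart, far from saturation
  aln <- c(setNames(block(b1, 3), paste0("x", 1:3)),
           setNames(block(b2, 3), paste0("y", 1:3)))
  tr <- bootstrap_support(aln, replicates = 100, seed = 5)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100))
  # the clade splitting x* from y* must be near-unanimous
  expect_gte(max(tr$node.label), 95)
  tr2 <- bootstrap_support(aln, replicates = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("identical trees give zero crossings and zero RF", {
  set.seed(41)
  tr <- ape::rtree(12)
  tg <- tanglegram(tr, tr)
  expect_equal(tg$crossings, 0)
  expect_equal(tg$entanglement, 0)
  expect_equal(tg$rf, 0)
})

test_that("mirrored leaf order untangles to zero by rotations", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):1,(e:1,f:1):1):1);")
  mirror <- ape::read.tree(text = "(((f:1,e:1):1,(d:1,c:1):1):1,(b:1,a:1):1);")
  tg <- tanglegram(tr, mirror)
  expect_equal(tg$crossings, 0)
  expect_equal(tg$rf, 0)
})

test_that("hill climb reaches the exhaustive rotation optimum on small trees", {
  # exhaustive: every leaf order reachable by permuting children blocks
  # at every internal node, enumerated structurally
  exhaustive_min <- function(t1, t2) {
    orders <- function(phy) {
      n <- length(phy$tip.label)
      ch <- vector("list", n + phy$Nnode)
      for (e in seq_len(nrow(phy$edge))) {
        ch[[phy$edge[e, 1]]] <- c(ch[[phy$edge[e, 1]]], phy$edge[e, 2])
      }
      block_perms <- function(k) {
        if (k == 1) return(list(1L))
        do.call(c, lapply(block_perms(k - 1), function(p) {
          lapply(0:(k - 1), function(i) append(p, k, after = i))
        }))
      }
      rec <- function(node) {
        if (node <= n) return(list(phy$tip.label[node]))
        kids <- lapply(ch[[node]], rec)   # per child: list of orders
        out <- list()
        for (perm in block_perms(length(kids))) {
          combos <- expand.grid(lapply(kids[perm], seq_along))
          for (r in seq_len(nrow(combos))) {
            o <- unlist(lapply(seq_along(perm), function(i) {
              kids[[perm[i]]][[combos[r, i]]]
            }))
            out[[length(out) + 1]] <- o
          }
        }
        unique(out)
      }
      rec(n + 1L)
    }
    cross <- function(o1, o2) {
      pos <- match(o1, o2); cr <- 0
      for (i in seq_along(pos)[-length(pos)]) {
        cr <- cr + sum(pos[(i + 1):length(pos)] < pos[i])
      }
      cr
    }
    min(vapply(orders(t1), function(o1) {
      min(vapply(orders(t2), function(o2) cross(o1, o2), numeric(1)))
    }, numeric(1)))
  }
  set.seed(51)
  for (i in 1:5) {
    t1 <- ape::root(ape::rtree(6, rooted = FALSE), "t1", resolve.root = TRUE)
    t2 <- ape::root(ape::rtree(6, rooted = FALSE), "t1", resolve.root = TRUE)
    t2$tip.label <- t1$tip.label[match(t2$tip.label, t1$tip.label)]
    tg <- tanglegram(t1, t2)
    expect_equal(tg$crossings, exhaustive_min(tg$t1, tg$t2))
  }
})

test_that("optimisation never increases crossings and validates leaf sets", {
  set.seed(61)
  for (i in 1:5) {
    t1 <- ape::rtree(10)
    t2 <- ape::rtree(10)
    tg <- tanglegram(t1, t2, seed = i)
    expect_lte(tg$crossings, tg$crossings_initial)
    expect_gte(tg$entanglement, 0)
    expect_lte(tg$entanglement, 1)
  }
  ta <- ape::rtree(5)
  tb <- ape::rtree(5)
  tb$tip.label <- paste0("z", 1:5)
  expect_error(tanglegram(ta, tb), "leaf sets differ")
})
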