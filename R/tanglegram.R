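## Tanglegram congruence between two leaf-labelled trees: crossing
## minimisation by subtree rotation, entanglement normalised against
## random-order baselines, normalised Robinson-Foulds distance, and a
## permutation test of congruence.
##
## Optimisation works on leaf orders. With the opposite tree's order
## fixed, the optimal rotation of a tree is computed exactly bottom-up:
## at each internal node the children blocks are permuted to minimise
## inter-block crossings, which is independent of the blocks' internal
## arrangement and of everything outside the subtree. The two trees are
## optimised alternately until a fixed point, from several random
## rotation starts.

# leaf labels in display (cladewise) order
.tip_order <- function(phy) {
  phy <- stats::reorder(phy, "cladewise")
  phy$tip.label[phy$edge[phy$edge[, 2] <= length(phy$tip.label), 2]]
}

# number of crossings between straight connectors of two leaf orders
.crossings <- function(ord1, ord2) {
  pos <- match(ord1, ord2)
  n <- length(pos)
  cr <- 0L
  for (i in seq_len(n - 1)) {
    cr <- cr + sum(pos[(i + 1):n] < pos[i])
  }
  cr
}

# children-id list per node of a rooted phylo
.children_list <- function(phy) {
  ch <- vector("list", length(phy$tip.label) + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    ch[[p]] <- c(ch[[p]], phy$edge[e, 2])
  }
  ch
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1)) {
    for (i in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = i)
    }
  }
  out
}

# exact optimal tip order of `phy` against fixed positions `pos`
# (named by tip label); optionally start from a random arrangement
.opt_order <- function(phy, pos, random = FALSE) {
  n_tip <- length(phy$tip.label)
  ch <- .children_list(phy)
  root <- n_tip + 1L
  rec <- function(node) {
    if (node <= n_tip) return(phy$tip.label[node])
    blocks <- lapply(ch[[node]], rec)
    k <- length(blocks)
    if (k == 1) return(blocks[[1]])
    if (random) return(unlist(blocks[sample.int(k)]))
    bp <- lapply(blocks, function(b) pos[b])
    cross <- function(a, b) {
      sum(vapply(bp[[a]], function(x) sum(bp[[b]] < x), numeric(1)))
    }
    best <- NULL; best_cr <- Inf
    for (perm in .permutations(k)) {
      cr <- 0
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        cr <- cr + cross(perm[i], perm[j])
      }
      if (cr < best_cr) { best_cr <- cr; best <- perm }
    }
    unlist(blocks[best])
  }
  rec(root)
}

# alternate exact one-sided optimisation until a fixed point
.untangle <- function(t1, t2, restarts = 10, seed = 1L) {
  ord1 <- .tip_order(t1)
  ord2 <- .tip_order(t2)
  n <- length(ord1)
  best <- list(ord1 = ord1, ord2 = ord2, crossings = .crossings(ord1, ord2))
  set.seed(seed)
  for (r in seq_len(restarts + 1)) {
    o1 <- if (r == 1) ord1 else
      .opt_order(t1, stats::setNames(seq_len(n), sample(ord1)), random = TRUE)
    cr_prev <- Inf
    repeat {
      o2 <- .opt_order(t2, stats::setNames(seq_along(o1), o1))
      o1 <- .opt_order(t1, stats::setNames(seq_along(o2), o2))
      cr <- .crossings(o1, o2)
      if (cr >= cr_prev) break
      cr_prev <- cr
    }
    if (cr_prev <= best$crossings) {
      best <- list(ord1 = o1, ord2 = o2, crossings = .crossings(o1, o2))
    }
    if (best$crossings == 0) break
  }
  best
}

# root a tree at a given tip so internal nodes are rotatable blocks
.root_at <- function(phy, tip) {
  if (!ape::is.rooted(phy)) {
    phy <- ape::root(phy, outgroup = tip, resolve.root = TRUE)
  }
  stats::reorder(phy, "cladewise")
}

#' Tanglegram of two trees on the same leaves
#'
#' Rotates subtrees of both trees to minimise the number of crossings
#' between the lines connecting equal leaves (exact one-side-fixed
#' ordering, alternated between the trees, with random restarts). The
#' entanglement score normalises the remaining crossings by the maximum
#' crossing count over `baselines` random leaf orders (0 = no crossings,
#' 1 = as entangled as the worst random layout). The normalised
#' Robinson-Foulds distance between the two topologies is reported
#' alongside.
#'
#' @param t1,t2 [ape::phylo] trees with identical leaf sets.
#' @param baselines number of random-order baselines for normalisation.
#' @param restarts number of random-rotation restarts.
#' @param seed integer seed (restarts and baselines).
#' @return object of class `"tanglegram"`: list with the rooted trees
#'   (`t1`, `t2`), optimised leaf orders `order1`, `order2`,
#'   `crossings`, `crossings_initial`, `entanglement` in [0, 1], and
#'   `rf` (normalised Robinson-Foulds; NA for < 4 leaves).
#' @export
tanglegram <- function(t1, t2, baselines = 100, restarts = 10, seed = 1L) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(t1$tip.label, t2$tip.label),
                 setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  }
  rf <- if (length(t1$tip.label) >= 4) {
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2), normalize = TRUE)
  } else NA_real_
  anchor <- sort(t1$tip.label)[1]
  r1 <- .root_at(t1, anchor)
  r2 <- .root_at(t2, anchor)
  initial <- .crossings(.tip_order(r1), .tip_order(r2))
  opt <- .untangle(r1, r2, restarts = restarts, seed = seed)
  set.seed(seed)
  base_max <- max(vapply(seq_len(baselines), function(i) {
    .crossings(opt$ord1, sample(opt$ord1))
  }, numeric(1)))
  ent <- if (base_max == 0) 0 else min(1, opt$crossings / base_max)
  structure(list(t1 = r1, t2 = r2,
                 order1 = opt$ord1, order2 = opt$ord2,
                 crossings = opt$crossings, crossings_initial = initial,
                 entanglement = ent, rf = rf),
            class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat(sprintf("Tanglegram over %d leaves: %d crossings (from %d), entanglement %.3f\n",
              length(x$order1), x$crossings, x$crossings_initial,
              x$entanglement))
  cat(sprintf("  normalised Robinson-Foulds distance: %s\n",
              ifelse(is.na(x$rf), "NA", sprintf("%.3f", x$rf))))
  invisible(x)
}

#' Permutation test of tree congruence
#'
#' Compares the optimised entanglement of two trees against a null
#' distribution obtained by randomly permuting the leaf labels of the
#' second tree and re-optimising. A small p-value means the trees are
#' more congruent (less entangled) than random labelling; p > 0.05 means
#' their congruence is indistinguishable from the permutation null.
#'
#' @param t1,t2 [ape::phylo] trees with identical leaf sets.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `entanglement`, `null` (vector), `p_value`.
#' @export
entanglement_test <- function(t1, t2, n_perm = 50, seed = 1L) {
  obs <- tanglegram(t1, t2, seed = seed)$entanglement
  set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(i) sample(t2$tip.label))
  null <- vapply(seq_len(n_perm), function(i) {
    tp <- t2
    tp$tip.label <- perms[[i]]
    tanglegram(t1, tp, baselines = 20, restarts = 3,
               seed = seed + i)$entanglement
  }, numeric(1))
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  list(entanglement = obs, null = null, p_value = p)
}

#' Plot a tanglegram
#'
#' Side-by-side base-graphics drawing of the two trees in their
#' optimised leaf orders, with connectors between equal leaves.
#'
#' @param x a `"tanglegram"`.
#' @param ... ignored.
#' @export
plot.tanglegram <- function(x, ...) {
  n <- length(x$order1)
  op <- graphics::par(mar = c(1, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0.5, n + 0.5),
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("entanglement %.3f", x$entanglement))
  y1 <- stats::setNames(seq_len(n), x$order1)
  y2 <- stats::setNames(seq_len(n), x$order2)
  graphics::axis(2, at = y1, labels = names(y1), las = 2, tick = FALSE,
                 cex.axis = 0.7)
  graphics::axis(4, at = y2, labels = names(y2), las = 2, tick = FALSE,
                 cex.axis = 0.7)
  for (lab in names(y1)) {
    graphics::segments(0, y1[[lab]], 1, y2[[lab]], col = "grey40")
  }
  invisible(x)
}
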