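# shared fixture builders; everything is generated in code

# small labelled presence/absence matrix
toy_pa <- function() {
  m <- matrix(c(
    1, 1, 1, 1,   # everywhere
    1, 1, 1, 0,   # 3 of 4
    1, 0, 0, 0,   # singleton
    0, 1, 1, 0,   # pair
    0, 0, 0, 1),  # singleton
    ncol = 4, byrow = TRUE,
    dimnames = list(paste0("og", 1:5), paste0("g", 1:4)))
  pa_matrix(m)
}

# block identity matrix: two planted species
block_ani <- function(within = 96, between = 85,
                      sizes = c(2, 2), labels = NULL) {
  n <- sum(sizes)
  sp <- rep(seq_along(sizes), sizes)
  m <- ifelse(outer(sp, sp, "=="), within, between)
  diag(m) <- 100
  if (is.null(labels)) labels <- paste0("g", seq_len(n))
  dimnames(m) <- list(labels, labels)
  identity_matrix(m)
}

all_orderings <- function(N) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  perms(seq_len(N))
}

# exhaustive pan/core rarefaction curves over all orderings of a small matrix
rarefaction_oracle <- function(m) {
  stopifnot(ncol(m) <= 6)
  N <- ncol(m)
  all_ord <- all_orderings(N)
  pan <- t(vapply(all_ord, function(ord) {
    vapply(seq_len(N), function(n) {
      sum(rowSums(m[, ord[seq_len(n)], drop = FALSE]) > 0)
    }, numeric(1))
  }, numeric(N)))
  core <- t(vapply(all_ord, function(ord) {
    vapply(seq_len(N), function(n) {
      sum(rowSums(m[, ord[seq_len(n)], drop = FALSE]) == n)
    }, numeric(1))
  }, numeric(N)))
  list(pan_median = apply(pan, 2, median),
       core_median = apply(core, 2, median),
       pan = pan, core = core)
}

# random unrooted tree with positive branch lengths
random_additive_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  tr
}
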