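## Distance construction (Kimura 2-parameter, ANI-derived, profile-based)
## and neighbor-joining with bootstrap support.

.purines <- c("A", "G")
.pyrimidines <- c("C", "T")

#' Kimura 2-parameter distances from an alignment
#'
#' For each sequence pair, sites where both sequences carry an
#' unambiguous base (A, C, G or T) are compared (pairwise deletion):
#' with transition proportion P and transversion proportion Q,
#' d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)). Pairs for which the
#' correction is undefined (1 - 2P - Q <= 0 or 1 - 2Q <= 0) get NA.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (as from [read_fasta()]).
#' @return a `dist` object with attribute `source = "k2p"`; NA marks
#'   undefined pairs.
#' @export
k2p_distance <- function(alignment) {
  if (length(alignment) < 2) stop("need >= 2 sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("sequences must be aligned (equal length)")
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(chars) <- names(alignment)
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  unamb <- chars %in% c("A", "C", "G", "T")
  dim(unamb) <- dim(chars)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- unamb[i, ] & unamb[j, ]
    L <- sum(use)
    if (L == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
    a <- chars[i, use]; b <- chars[j, use]
    diff <- a != b
    ts <- sum(diff & ((a %in% .purines & b %in% .purines) |
                        (a %in% .pyrimidines & b %in% .pyrimidines)))
    tv <- sum(diff) - ts
    P <- ts / L; Q <- tv / L
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    d[i, j] <- d[j, i] <- if (w1 <= 0 || w2 <= 0) NA_real_ else
      -0.5 * log(w1 * sqrt(w2))
  }
  out <- stats::as.dist(d)
  attr(out, "source") <- "k2p"
  out
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (via [ape::nj()]) on a distance matrix.
#' With fewer than 3 labels a trivial two-leaf tree is returned with a
#' warning.
#'
#' @param d a `dist` object or symmetric numeric matrix with labels.
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (any(is.na(m))) stop("distance matrix contains undefined entries")
  if (nrow(m) < 3) {
    warning("fewer than 3 labels; returning trivial tree")
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = rep(m[1, 2] / 2, 2),
               tip.label = rownames(m), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(stats::as.dist(m))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ
#' tree for each replicate, and reports per-internal-node support as the
#' percentage of replicates containing the same bipartition
#' (via [ape::prop.clades()]). Supports are stored in `node.label`.
#'
#' @param alignment named character vector of aligned sequences.
#' @param replicates bootstrap replicate count.
#' @param seed integer seed.
#' @return an [ape::phylo] tree whose `node.label` holds percent support.
#' @export
bootstrap_support <- function(alignment, replicates = 500, seed = 1L) {
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(chars) <- names(alignment)
  build <- function(mat) {
    seqs <- apply(mat, 1, paste, collapse = "")
    neighbor_joining(k2p_distance(seqs))
  }
  main <- build(chars)
  set.seed(seed)
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(chars), replace = TRUE)
    boots[[b]] <- build(chars[, cols, drop = FALSE])
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / replicates)
  main
}

#' Distance matrix from a pairwise identity matrix
#'
#' Linear transform d = (100 - identity) / 100.
#'
#' @param m an [identity_matrix()].
#' @return a `dist` object with attribute `source = "identity"`.
#' @export
distance_from_identity <- function(m) {
  stopifnot(inherits(m, "identity_matrix"))
  d <- stats::as.dist((100 - unclass(m)) / 100)
  attr(d, "source") <- "identity"
  d
}

#' Distance matrix from row profiles
#'
#' Continuous profiles (e.g. killing-zone diameters): Euclidean distance
#' on per-column standardised values; zero-variance columns are dropped
#' with a warning. Binary profiles (e.g. BGC or orthogroup
#' presence/absence): Jaccard distance.
#'
#' @param rows numeric matrix, observations in rows (e.g. a
#'   `"predation_matrix"`, or a transposed [pa_matrix()]).
#' @param metric `"euclidean_standardized"` or `"jaccard"`.
#' @return a `dist` object with attribute `source = "profile"`.
#' @export
distance_from_profile <- function(rows,
                                  metric = c("euclidean_standardized",
                                             "jaccard")) {
  metric <- match.arg(metric)
  m <- as.matrix(unclass(rows))
  if (any(is.na(m))) stop("profile matrix must be complete")
  if (metric == "euclidean_standardized") {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance column(s) dropped")
      m <- m[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (!ncol(m)) stop("no informative columns left")
    m <- scale(m)
    d <- stats::dist(m, method = "euclidean")
  } else {
    if (!all(m %in% c(0, 1))) stop("jaccard metric requires binary profiles")
    d <- stats::dist(m, method = "binary")
  }
  attr(d, "source") <- "profile"
  d
}
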