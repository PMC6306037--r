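## Tiered genomospecies delimitation from pairwise identity matrices.
## Clustering is single linkage: groups are connected components of the
## graph whose edges are pairs at or above a threshold. Pairs that fall
## into no named tier, or that contradict the transitive grouping, are
## reported as conflicts rather than silently adjudicated.

# connected components of the >= t (or > t) graph, as an integer
# membership vector named by genome
.components <- function(m, t, strict = FALSE) {
  n <- nrow(m)
  adj <- if (strict) m > t else m >= t
  diag(adj) <- TRUE
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      new <- min(comp[nb])
      if (new < comp[i]) { comp[nb] <- pmin(comp[nb], new); changed <- TRUE }
      else if (any(comp[nb] > comp[i])) { comp[nb] <- comp[i]; changed <- TRUE }
    }
    if (!changed) break
  }
  stats::setNames(match(comp, unique(comp)), rownames(m))
}

#' Single-linkage clusters at an identity threshold
#'
#' Connected components of the graph joining genome pairs whose identity
#' is at least (or, with `strict`, strictly above) the threshold.
#'
#' @param m an [identity_matrix()].
#' @param t threshold percentage in (0, 100].
#' @param strict use `> t` instead of `>= t`.
#' @return named integer vector: cluster membership per genome.
#' @export
cluster_at_threshold <- function(m, t, strict = FALSE) {
  stopifnot(inherits(m, "identity_matrix"))
  if (t <= 0 || t > 100) stop("threshold must lie in (0, 100]")
  .components(unclass(m), t, strict = strict)
}

#' Tiered species delimitation from an ANI matrix
#'
#' Definite species are single-linkage clusters at the same-species
#' threshold (>= 95% by default). Clusters connected by any pair in the
#' subspecies band ([93, 95) by default) are merged into one species
#' whose members form subspecies. The species count is reported as a
#' range: (count after merging, count before merging). `genus_ok` is true
#' iff every pair is at or above the genus threshold (75%).
#'
#' Conflicts reported (never silently resolved): pairs in the unnamed gap
#' between the different-species and subspecies tiers, pairs inside one
#' definite-species cluster falling below the species threshold
#' (transitivity violations), and pairs inside one merged species falling
#' at or below the different-species threshold.
#'
#' @param m an [identity_matrix()] of kind ANI.
#' @param config an [analysis_config()].
#' @return object of class `"species_grouping"`: list with `genus_ok`,
#'   `species` (membership at the definite tier), `merged_species`
#'   (membership after subspecies banding), `subspecies_of` (merged
#'   species id per definite cluster), `species_count_range` (min, max)
#'   and `conflicts` (data.frame genome_a / genome_b / value / reason).
#' @export
delimit <- function(m, config = analysis_config()) {
  stopifnot(inherits(m, "identity_matrix"))
  if (!identical(attr(m, "kind"), "ANI")) {
    stop("delimit() requires an ANI matrix (got ", attr(m, "kind"), ")")
  }
  v <- unclass(m)
  n <- nrow(v)
  labs <- rownames(v)
  t_hi <- config$ani_species_high
  t_lo <- config$ani_species_low
  band <- config$subspecies_band
  definite <- .components(v, t_hi)
  k <- max(definite)
  # merge definite clusters linked by any pair inside the subspecies band
  link <- matrix(0, k, k)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (definite[i] != definite[j] &&
        v[i, j] >= band[1] && v[i, j] < band[2]) {
      link[definite[i], definite[j]] <- 100
      link[definite[j], definite[i]] <- 100
    }
  }
  diag(link) <- 100
  rownames(link) <- colnames(link) <- paste0("c", seq_len(k))
  merged_of <- .components(link, 50)
  merged <- stats::setNames(as.integer(merged_of[definite]), labs)
  conflicts <- list()
  add_conflict <- function(i, j, reason) {
    conflicts[[length(conflicts) + 1]] <<- data.frame(
      genome_a = labs[i], genome_b = labs[j], value = v[i, j],
      reason = reason, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- v[i, j]
    if (val > t_lo && val < band[1]) {
      add_conflict(i, j, sprintf("value in unnamed gap (%g, %g)",
                                 t_lo, band[1]))
    }
    if (definite[i] == definite[j] && val < t_hi) {
      add_conflict(i, j, "below species threshold inside one species cluster")
    }
    if (definite[i] != definite[j] && merged[i] == merged[j] && val <= t_lo) {
      add_conflict(i, j, "different-species value inside one merged species")
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(genome_a = character(), genome_b = character(),
               value = numeric(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(
    genus_ok = all(v[upper.tri(v)] >= config$ani_genus),
    species = definite,
    merged_species = merged,
    subspecies_of = merged_of,
    species_count_range = c(min = max(merged), max = k),
    conflicts = conflicts
  ), class = "species_grouping")
}

#' @export
print.species_grouping <- function(x, ...) {
  rng <- x$species_count_range
  cat(sprintf("Species delimitation: %d definite clusters, %d after subspecies merging\n",
              rng[["max"]], rng[["min"]]))
  cat(sprintf("  species count range: (%d, %d); genus coherent: %s\n",
              rng[["min"]], rng[["max"]], x$genus_ok))
  n_sub <- sum(table(x$subspecies_of) > 1)
  if (n_sub) cat(sprintf("  %d species contain multiple subspecies\n", n_sub))
  if (nrow(x$conflicts)) {
    cat(sprintf("  %d conflicting pair(s) reported\n", nrow(x$conflicts)))
  }
  invisible(x)
}

#' dDDH groupings at several strict thresholds
#'
#' Single-linkage components at each strict-greater threshold, reported
#' side by side (conventionally 70, 50 and 30%).
#'
#' @param m an [identity_matrix()] of kind dDDH.
#' @param thresholds percentages (strict `>` cut-offs).
#' @return named list: one membership vector per threshold, named
#'   `"gt<threshold>"`.
#' @export
ddh_groups <- function(m, thresholds = c(70, 50, 30)) {
  stopifnot(inherits(m, "identity_matrix"))
  if (!identical(attr(m, "kind"), "dDDH")) {
    stop("ddh_groups() requires a dDDH matrix")
  }
  out <- lapply(thresholds, function(t) {
    .components(unclass(m), t, strict = TRUE)
  })
  names(out) <- paste0("gt", thresholds)
  out
}

#' Pair-counting concordance between two groupings
#'
#' Rand index over all genome pairs, plus the genomes whose co-membership
#' pattern differs between the two clusterings.
#'
#' @param a,b named membership vectors over the same genome set.
#' @return list with `rand`, `n_pairs`, `agreeing_pairs` and
#'   `discordant_genomes`.
#' @export
compare_groupings <- function(a, b) {
  if (!setequal(names(a), names(b)) || is.null(names(a))) {
    stop("groupings must be named over the same genome set; difference: ",
         paste(c(setdiff(names(a), names(b)), setdiff(names(b), names(a))),
               collapse = ", "))
  }
  b <- b[names(a)]
  n <- length(a)
  labs <- names(a)
  agree <- 0L; total <- 0L
  disc <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    total <- total + 1L
    if (same_a == same_b) agree <- agree + 1L
    else disc <- union(disc, labs[c(i, j)])
  }
  list(rand = agree / total, n_pairs = total, agreeing_pairs = agree,
       discordant_genomes = sort(disc))
}
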