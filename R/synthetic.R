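## Synthetic-data generators with planted ground truth. Every pipeline
## stage has a generator emulating its input: presence/absence matrices
## whose rarefaction follows Heaps' law with chosen kappa/gamma, identity
## matrices with planted genus/species/subspecies block structure, COG
## annotation tables with planted accessory enrichment, predation assay
## matrices with tunable congruence to a reference tree, and contig sets
## with SPAdes-style coverage headers.

#' Simulate a gene presence/absence matrix with planted Heaps' law
#'
#' Generates an exchangeable incidence matrix whose expected rarefaction
#' pan curve is exactly `core_size + kappa * n^gamma`. The gene frequency
#' spectrum (how many orthogroups occur in exactly k of the N genomes) is
#' obtained by solving the linear system that maps a spectrum to its
#' expected rarefaction curve; class counts are then Poisson-randomised
#' and each orthogroup is placed into a uniformly random k-subset of
#' genomes. Because genomes are exchangeable by construction, rarefaction
#' over random genome orderings recovers the planted curve, and
#' [fit_heaps()] recovers gamma and kappa.
#'
#' `retention` (in (0, 1]) down-weights the sharing of accessory genes:
#' the accessory class-k spectrum is tilted by `retention^(k-1)`. At the
#' default `retention = 1` the planted curve is reproduced exactly;
#' smaller values thin widely shared accessory genes, emulating lineages
#' that lose acquired genes quickly.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param core_size genes present in every genome.
#' @param kappa Heaps coefficient (genes), > 0.
#' @param gamma Heaps exponent in (0, 1) (open pan-genome regime).
#' @param retention sharing tilt in (0, 1].
#' @param seed integer seed.
#' @return a [pa_matrix()] with a `"truth"` attribute (list with
#'   `heaps_kappa`, `heaps_gamma`, `core_size`, `retention`, `rng_seed`).
#' @export
simulate_pangenome <- function(n_genomes = 24, core_size = 1000,
                               kappa = 8000, gamma = 0.55,
                               retention = 1, seed = 1L) {
  if (n_genomes < 2) stop("n_genomes must be >= 2")
  if (kappa <= 0) stop("kappa must be positive")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  if (retention <= 0 || retention > 1) stop("retention must lie in (0, 1]")
  N <- as.integer(n_genomes)
  spectrum <- .heaps_spectrum(N, core_size, kappa, gamma)
  acc <- spectrum
  acc[N] <- max(acc[N] - core_size, 0)
  acc <- acc * retention^(seq_len(N) - 1)
  set.seed(seed)
  counts <- stats::rpois(N, acc)
  counts[N] <- counts[N] + core_size
  total <- sum(counts)
  m <- matrix(FALSE, total, N)
  row_idx <- integer(0); col_idx <- integer(0)
  r <- 0L
  for (k in seq_len(N)) {
    ck <- counts[k]
    if (ck == 0) next
    if (k == N) {
      m[r + seq_len(ck), ] <- TRUE
    } else {
      cols <- vapply(seq_len(ck), function(i) sample.int(N, k), integer(k))
      row_idx <- c(row_idx, rep(r + seq_len(ck), each = k))
      col_idx <- c(col_idx, as.integer(cols))
    }
    r <- r + ck
  }
  if (length(row_idx)) m[cbind(row_idx, col_idx)] <- TRUE
  dimnames(m) <- list(sprintf("og%05d", seq_len(total)),
                      sprintf("G%02d", seq_len(N)))
  out <- pa_matrix(m)
  attr(out, "truth") <- list(heaps_kappa = kappa, heaps_gamma = gamma,
                             core_size = core_size, retention = retention,
                             rng_seed = as.integer(seed))
  out
}

# Frequency spectrum s_k (expected orthogroups in exactly k of N genomes)
# whose expected rarefaction pan curve is core + kappa * n^gamma:
# solve A s = t with A[n, k] = P(a frequency-k gene is seen in a random
# n-genome prefix) = 1 - choose(N-k, n)/choose(N, n).
.heaps_spectrum <- function(N, core, kappa, gamma) {
  A <- outer(seq_len(N), seq_len(N),
             function(n, k) 1 - choose(N - k, n) / choose(N, n))
  t_n <- core + kappa * seq_len(N)^gamma
  s <- solve(A, t_n)
  if (any(s < -1)) {
    warning("target curve implies a negative frequency class; clamping to 0")
  }
  pmax(s, 0)
}

#' Simulate a pairwise identity matrix with planted group structure
#'
#' Pairwise values are drawn uniformly from the range dictated by the
#' true relationship of the pair (same subspecies, same species but
#' different subspecies, same genus group but different species,
#' different genus groups) plus truncated Gaussian noise (cut at +/- 3
#' standard deviations). Ranges are validated to stay disjoint after
#' noise, so planted tiers can never bleed into one another.
#'
#' @param group_sizes integer vector: genomes per species.
#' @param subspecies_splits optional named list: species index ->
#'   integer vector of subspecies sizes (must sum to that species' size).
#' @param species_groups optional vector assigning each species to a
#'   deep subdivision ("genus group"); pairs across groups draw from
#'   `between_genus`. Default: all species in one group.
#' @param between_genus,between_species,subspecies_band,within
#'   two-element ranges (percent), strictly ordered and disjoint.
#' @param noise_sd standard deviation of the truncated noise (points).
#' @param kind `"ANI"` or `"dDDH"`.
#' @param seed integer seed.
#' @return list with `matrix` (an [identity_matrix()]) and `truth`
#'   (data.frame: genome, genus_group, species, subspecies).
#' @export
simulate_identity_matrix <- function(group_sizes,
                                     subspecies_splits = NULL,
                                     species_groups = NULL,
                                     between_genus = c(82, 84),
                                     between_species = c(86, 91),
                                     subspecies_band = c(93.7, 94.3),
                                     within = c(96.5, 99),
                                     noise_sd = 0.1,
                                     kind = c("ANI", "dDDH"),
                                     seed = 1L) {
  kind <- match.arg(kind)
  S <- length(group_sizes)
  if (S < 1 || any(group_sizes < 1)) stop("group_sizes must be positive counts")
  if (is.null(species_groups)) species_groups <- rep("A", S)
  if (length(species_groups) != S) {
    stop("species_groups must have one entry per species")
  }
  ranges <- list(between_genus = between_genus,
                 between_species = between_species,
                 subspecies_band = subspecies_band,
                 within = within)
  for (rg in ranges) {
    if (length(rg) != 2 || diff(rg) < 0) stop("ranges must be [lo, hi] pairs")
  }
  pad <- 3 * noise_sd
  ord <- do.call(rbind, ranges)
  for (i in seq_len(nrow(ord) - 1)) {
    if (ord[i, 2] + pad >= ord[i + 1, 1] - pad) {
      stop(sprintf("ranges %s and %s overlap after +/- 3 * noise_sd",
                   rownames(ord)[i], rownames(ord)[i + 1]))
    }
  }
  if (ord[1, 1] - pad < 0 || ord[nrow(ord), 2] + pad > 100) {
    stop("ranges must stay within [0, 100] after noise")
  }
  # per-genome truth labels
  species <- rep(seq_len(S), group_sizes)
  subspecies <- unlist(lapply(seq_len(S), function(s) {
    sz <- group_sizes[s]
    split <- if (!is.null(subspecies_splits) &&
                 !is.null(subspecies_splits[[as.character(s)]])) {
      subspecies_splits[[as.character(s)]]
    } else sz
    if (sum(split) != sz) {
      stop(sprintf("subspecies sizes for species %d must sum to %d", s, sz))
    }
    rep(seq_along(split), split)
  }))
  n <- sum(group_sizes)
  genus_group <- species_groups[species]
  labels <- sprintf("G%02d", seq_len(n))
  set.seed(seed)
  rtrunc <- function(k) {
    x <- stats::rnorm(k, 0, noise_sd)
    while (any(bad <- abs(x) > pad)) x[bad] <- stats::rnorm(sum(bad), 0, noise_sd)
    x
  }
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rg <- if (genus_group[i] != genus_group[j]) between_genus
      else if (species[i] != species[j]) between_species
      else if (subspecies[i] != subspecies[j]) subspecies_band
      else within
    v <- stats::runif(1, rg[1], rg[2]) + rtrunc(1)
    m[i, j] <- v; m[j, i] <- v
  }
  truth <- data.frame(genome = labels, genus_group = genus_group,
                      species = species, subspecies = subspecies,
                      stringsAsFactors = FALSE)
  list(matrix = identity_matrix(m, kind = kind), truth = truth)
}

#' Nine-species scenario with two subspecies pairs
#'
#' Arguments reproducing a 24-genome genus with two deep subdivisions
#' (17 + 7 genomes), nine species, two of which contain two subspecies,
#' laid out as: group A species of sizes 11 (split 5 + 6), 3, 1, 1, 1 and
#' group B species of sizes 2 (split 1 + 1), 1, 1, 3.
#'
#' @param kind `"ANI"` or `"dDDH"`.
#' @param seed integer seed.
#' @return as [simulate_identity_matrix()].
#' @export
simulate_nine_species <- function(kind = c("ANI", "dDDH"), seed = 1L) {
  kind <- match.arg(kind)
  sizes <- c(11, 3, 1, 1, 1, 2, 1, 1, 3)
  splits <- list(`1` = c(5, 6), `6` = c(1, 1))
  groups <- c("A", "A", "A", "A", "A", "B", "B", "B", "B")
  if (kind == "ANI") {
    simulate_identity_matrix(sizes, splits, groups, seed = seed, kind = "ANI")
  } else {
    # dDDH tiers: same subspecies > 70, subspecies band between 30 and 50,
    # different species below 30
    simulate_identity_matrix(sizes, splits, groups,
                             between_genus = c(5, 10),
                             between_species = c(14, 25),
                             subspecies_band = c(33, 46),
                             within = c(74, 88),
                             noise_sd = 0.5, kind = "dDDH", seed = seed)
  }
}

#' Simulate a gene-to-COG annotation table with planted enrichment
#'
#' Core-set genes draw their COG letter from `base_profile`; accessory
#' genes draw from `base_profile` with the `planted` categories multiplied
#' by `2^fold` and renormalised (over the annotated share). Genes may also
#' stay unannotated with probability `1 - sum(base_profile)/100`.
#'
#' @param partition a `"pan_partition"` from [partition()]; hard and soft
#'   core orthogroups form the core set, the rest the accessory set.
#' @param base_profile named numeric: percent of annotated genes per COG
#'   letter; must sum to <= 100 (remainder is unannotated).
#' @param planted named numeric: COG letter -> log2 fold planted in the
#'   accessory set. Letters must appear in `base_profile`.
#' @param seed integer seed.
#' @return list with `annotations` (data.frame gene/letters),
#'   `core_genes`, `accessory_genes` (character vectors) and `truth`.
#' @export
simulate_annotations <- function(partition, base_profile,
                                 planted = c(Q = 1.25), seed = 1L) {
  stopifnot(inherits(partition, "pan_partition"))
  if (is.null(names(base_profile)) || any(!nzchar(names(base_profile)))) {
    stop("base_profile must be named by COG letters")
  }
  if (sum(base_profile) > 100 + 1e-8) stop("base_profile must sum to <= 100")
  if (length(planted) && !all(names(planted) %in% names(base_profile))) {
    stop("planted category absent from base_profile: ",
         paste(setdiff(names(planted), names(base_profile)), collapse = ", "))
  }
  core_genes <- names(partition$tier)[partition$tier %in%
                                        c("hard_core", "soft_core")]
  accessory_genes <- setdiff(names(partition$tier), core_genes)
  annotated_share <- sum(base_profile) / 100
  draw <- function(genes, profile) {
    p <- profile / sum(profile)
    letters_drawn <- sample(names(profile), length(genes), TRUE, p)
    annotated <- stats::runif(length(genes)) < annotated_share
    ifelse(annotated, letters_drawn, "")
  }
  acc_profile <- base_profile
  acc_profile[names(planted)] <- acc_profile[names(planted)] * 2^planted
  set.seed(seed)
  ann <- data.frame(
    gene = c(core_genes, accessory_genes),
    letters = c(draw(core_genes, base_profile),
                draw(accessory_genes, acc_profile)),
    stringsAsFactors = FALSE)
  list(annotations = ann, core_genes = core_genes,
       accessory_genes = accessory_genes,
       truth = list(planted = planted, base_profile = base_profile,
                    rng_seed = as.integer(seed)))
}

#' Simulate a predation assay matrix with tunable tree congruence
#'
#' Killing-zone diameters are generated as a congruence-weighted mixture
#' of a tree-structured signal (Brownian motion along the reference tree,
#' one independent realisation per prey organism) and i.i.d. Gaussian
#' noise. At `congruence = 1` strain profiles are fully determined by the
#' tree; at 0 they are pure noise. Diameters are shifted to a baseline
#' and clamped at 0 mm.
#'
#' @param tree an [ape::phylo] reference tree (strains at the leaves).
#' @param n_prey number of prey organisms.
#' @param congruence mixture weight in [0, 1].
#' @param baseline mean diameter (mm).
#' @param amplitude mm of spread given to the mixed signal.
#' @param seed integer seed.
#' @return a `"predation_matrix"` (strains x prey, mm).
#' @export
simulate_predation <- function(tree, n_prey = 10, congruence = 0.5,
                               baseline = 15, amplitude = 4, seed = 1L) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) < 2) {
    stop("a reference tree with >= 2 leaves is required")
  }
  if (congruence < 0 || congruence > 1) stop("congruence must lie in [0, 1]")
  n <- length(tree$tip.label)
  set.seed(seed)
  prof <- vapply(seq_len(n_prey), function(j) {
    sig <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    sig <- (sig - mean(sig)) / max(stats::sd(sig), 1e-12)
    eps <- stats::rnorm(n)
    congruence * sig + (1 - congruence) * eps
  }, numeric(n))
  m <- baseline + amplitude * prof
  m <- pmax(m, 0)
  dimnames(m) <- list(tree$tip.label, sprintf("prey%02d", seq_len(n_prey)))
  predation_matrix(m)
}

#' Simulate an assembly as contigs with SPAdes-style headers
#'
#' Contig lengths are a random composition of `genome_size` (each contig
#' >= 1 bp); bases are drawn i.i.d. with the requested GC fraction;
#' headers carry `_length_<L>_cov_<C>` tokens with coverages drawn
#' uniformly from `coverage_range`.
#'
#' @param genome_size total bp (>= n_contigs).
#' @param n_contigs number of contigs (>= 1).
#' @param coverage_range fold-coverage range.
#' @param gc target GC fraction.
#' @param seed integer seed.
#' @return named character vector of sequences (headers as names),
#'   suitable for [write_fasta()].
#' @export
simulate_contigs <- function(genome_size, n_contigs = 1,
                             coverage_range = c(20, 170), gc = 0.7,
                             seed = 1L) {
  if (n_contigs < 1) stop("n_contigs must be >= 1")
  if (genome_size < n_contigs) {
    stop("genome_size must allow >= 1 bp per contig")
  }
  set.seed(seed)
  w <- stats::rexp(n_contigs)
  lens <- pmax(1, floor(w / sum(w) * genome_size))
  # repair the composition to sum exactly to genome_size
  excess <- sum(lens) - genome_size
  i <- 1
  while (excess != 0) {
    step <- -sign(excess)
    if (lens[i] + step >= 1) { lens[i] <- lens[i] + step; excess <- excess + step }
    i <- i %% n_contigs + 1
  }
  cov <- round(stats::runif(n_contigs, coverage_range[1], coverage_range[2]), 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(probs), L, TRUE, probs), collapse = "")
  }, "")
  names(seqs) <- sprintf("NODE_%d_length_%d_cov_%s",
                         seq_len(n_contigs), lens, format(cov, trim = TRUE))
  seqs
}
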