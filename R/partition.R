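## Core/accessory tier partitioning of a presence/absence matrix and
## Table-shaped pan-genome summaries.

.tier_levels <- c("hard_core", "soft_core", "shell", "cloud")

#' Partition orthogroups into pan-genome tiers
#'
#' Assigns each orthogroup to a tier by its presence fraction f across
#' genomes: hard core (f >= `hard_core_min`), soft core
#' (`soft_core_min` <= f < `hard_core_min`), shell
#' (`shell_min` <= f < `soft_core_min`), cloud (f < `shell_min`).
#' With the default thresholds at 24 genomes this reproduces the
#' conventional Roary tiers: 24/24 genomes is hard core, 23/24 soft core.
#'
#' @param m a [pa_matrix()].
#' @param config an [analysis_config()].
#' @return an object of class `"pan_partition"`: list with `tier`
#'   (named factor per orthogroup), `counts` (per tier), `pan_size`,
#'   `mean_genes_per_genome`, `core_fraction_per_genome` (percent of each
#'   genome's genes in the hard+soft core) and `n_genomes`.
#' @export
partition <- function(m, config = analysis_config()) {
  stopifnot(inherits(m, "pa_matrix"))
  n <- ncol(m)
  f <- rowSums(m) / n
  if (any(f == 0)) stop("orthogroup absent from every genome")
  tier <- ifelse(f >= config$hard_core_min, "hard_core",
          ifelse(f >= config$soft_core_min, "soft_core",
          ifelse(f >= config$shell_min, "shell", "cloud")))
  tier <- factor(tier, levels = .tier_levels)
  names(tier) <- rownames(m)
  counts <- table(tier)
  core_rows <- tier %in% c("hard_core", "soft_core")
  genes_per_genome <- colSums(m)
  core_frac <- 100 * colSums(m[core_rows, , drop = FALSE]) / genes_per_genome
  structure(list(
    tier = tier,
    counts = as.integer(counts),
    tier_names = .tier_levels,
    pan_size = nrow(m),
    n_genomes = n,
    mean_genes_per_genome = mean(genes_per_genome),
    core_fraction_per_genome = core_frac
  ), class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  s <- summarize_partition(x)
  cat(sprintf("Pan-genome partition: %d orthogroups over %d genomes\n",
              x$pan_size, x$n_genomes))
  cat(sprintf("  hard core %d (%.1f%%), soft core %d (%.1f%%)\n",
              s$hard_core, s$hard_core_pct, s$soft_core, s$soft_core_pct))
  cat(sprintf("  shell %d (%.1f%%), cloud %d (%.1f%%)\n",
              s$shell, s$shell_pct, s$cloud, s$cloud_pct))
  cat(sprintf("  core total %d (%.1f%%); average %% of genes in the core %.1f%%\n",
              s$core_total, s$core_total_pct, s$avg_pct_genes_in_core))
  invisible(x)
}

#' Summarise a pan-genome partition
#'
#' Emits the conventional pan-genome summary: pan size, hard/soft core,
#' shell and cloud counts with percentages of the pan, core and accessory
#' totals, mean genes per genome, and the average percent of a genome's
#' genes belonging to the core (core total divided by mean genes per
#' genome). Counts may also be supplied directly, which allows
#' recomputation of published summary tables from their printed counts.
#'
#' @param x a `"pan_partition"`, or a named list/vector with counts
#'   `hard_core`, `soft_core`, `shell`, `cloud` and `mean_genes_per_genome`.
#' @param digits decimals for the percentage fields.
#' @return a list of counts and percentages.
#' @export
summarize_partition <- function(x, digits = 1) {
  if (inherits(x, "pan_partition")) {
    counts <- stats::setNames(x$counts, x$tier_names)
    mean_genes <- x$mean_genes_per_genome
  } else {
    x <- as.list(x)
    need <- c("hard_core", "soft_core", "shell", "cloud",
              "mean_genes_per_genome")
    if (!all(need %in% names(x))) {
      stop("need counts: ", paste(need, collapse = ", "))
    }
    counts <- unlist(x[.tier_levels])
    mean_genes <- x$mean_genes_per_genome
  }
  pan <- sum(counts)
  core <- counts[["hard_core"]] + counts[["soft_core"]]
  accessory <- counts[["shell"]] + counts[["cloud"]]
  pct <- function(k) round(100 * k / pan, digits)
  list(
    pan_size = pan,
    hard_core = counts[["hard_core"]], hard_core_pct = pct(counts[["hard_core"]]),
    soft_core = counts[["soft_core"]], soft_core_pct = pct(counts[["soft_core"]]),
    shell = counts[["shell"]], shell_pct = pct(counts[["shell"]]),
    cloud = counts[["cloud"]], cloud_pct = pct(counts[["cloud"]]),
    core_total = core, core_total_pct = pct(core),
    accessory_total = accessory, accessory_total_pct = pct(accessory),
    mean_genes_per_genome = mean_genes,
    avg_pct_genes_in_core = round(100 * core / mean_genes, digits)
  )
}

#' Restrict a presence/absence matrix to a genome subset
#'
#' Orthogroups absent from every retained genome are dropped, so the pan
#' size shrinks accordingly.
#'
#' @param m a [pa_matrix()].
#' @param genomes character vector of genome ids to keep.
#' @return a [pa_matrix()] over the selected genomes.
#' @export
subset_genomes <- function(m, genomes) {
  stopifnot(inherits(m, "pa_matrix"))
  unknown <- setdiff(genomes, colnames(m))
  if (length(unknown)) {
    stop("unknown genome id(s): ", paste(unknown, collapse = ", "))
  }
  sub <- unclass(m)[, genomes, drop = FALSE]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  pa_matrix(sub)
}
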