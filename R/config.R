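#' Analysis configuration
#'
#' Bundles the thresholds used throughout the pipeline: presence-fraction
#' bounds for the pan-genome tiers, ANI percentages for genus/species
#' delimitation, the subspecies ANI band, dDDH thresholds, the enrichment
#' fold/abundance cut-offs, rarefaction permutation count and the contig
#' coverage filter.
#'
#' Defaults follow the conventional literature values: tiers at >=99%
#' (hard core), 95-99% (soft core), 15-95% (shell), <15% (cloud) presence;
#' ANI >=95% same species, <=92% different species, <75% different genera,
#' 93-94% subspecies band; dDDH thresholds 70/50/30%; enrichment requires
#' |log2 ratio| > 1 and abundance > 2%; contigs under 7-fold coverage are
#' discarded.
#'
#' @param hard_core_min minimum presence fraction for the hard core.
#' @param soft_core_min minimum presence fraction for the soft core.
#' @param shell_min minimum presence fraction for the shell.
#' @param ani_genus ANI percentage below which genomes belong to
#'   different genera.
#' @param ani_species_low ANI percentage at or below which genomes belong
#'   to different species.
#' @param ani_species_high ANI percentage at or above which genomes belong
#'   to the same species.
#' @param subspecies_band two percentages; pairwise ANI in
#'   `[subspecies_band[1], subspecies_band[2])` indicates separate
#'   subspecies of one species.
#' @param ddh_thresholds three dDDH percentages (strict `>` cut-offs)
#'   reported side by side.
#' @param enrichment_log2_cutoff minimum |log2 relative-abundance ratio|
#'   for an enrichment call.
#' @param enrichment_abundance_cutoff minimum percentage abundance (in the
#'   favoured set) for an enrichment call.
#' @param rarefaction_permutations number of random genome orderings.
#' @param coverage_min minimum fold coverage for contig retention.
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return an object of class `"openpan_config"` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$ani_species_high
analysis_config <- function(hard_core_min = 0.99,
                            soft_core_min = 0.95,
                            shell_min = 0.15,
                            ani_genus = 75,
                            ani_species_low = 92,
                            ani_species_high = 95,
                            subspecies_band = c(93, 95),
                            ddh_thresholds = c(70, 50, 30),
                            enrichment_log2_cutoff = 1,
                            enrichment_abundance_cutoff = 2,
                            rarefaction_permutations = 100,
                            coverage_min = 7,
                            rng_seed = 1L) {
  frac <- c(hard_core_min = hard_core_min, soft_core_min = soft_core_min,
            shell_min = shell_min)
  if (any(frac < 0 | frac > 1)) {
    stop("tier thresholds must be fractions in [0, 1]")
  }
  if (!(hard_core_min > soft_core_min && soft_core_min > shell_min)) {
    stop("tier thresholds must satisfy hard > soft > shell")
  }
  pct <- c(ani_genus, ani_species_low, ani_species_high,
           subspecies_band, ddh_thresholds)
  if (any(pct < 0 | pct > 100)) {
    stop("identity thresholds must be percentages in [0, 100]")
  }
  if (ani_species_high <= ani_species_low) {
    stop("ani_species_high must exceed ani_species_low")
  }
  if (length(subspecies_band) != 2 || diff(subspecies_band) <= 0) {
    stop("subspecies_band must be an increasing pair of percentages")
  }
  if (rarefaction_permutations < 1) stop("rarefaction_permutations must be >= 1")
  if (coverage_min < 0) stop("coverage_min must be non-negative")
  structure(list(
    hard_core_min = hard_core_min,
    soft_core_min = soft_core_min,
    shell_min = shell_min,
    ani_genus = ani_genus,
    ani_species_low = ani_species_low,
    ani_species_high = ani_species_high,
    subspecies_band = as.numeric(subspecies_band),
    ddh_thresholds = as.numeric(ddh_thresholds),
    enrichment_log2_cutoff = enrichment_log2_cutoff,
    enrichment_abundance_cutoff = enrichment_abundance_cutoff,
    rarefaction_permutations = as.integer(rarefaction_permutations),
    coverage_min = coverage_min,
    rng_seed = as.integer(rng_seed)
  ), class = "openpan_config")
}

#' @export
print.openpan_config <- function(x, ...) {
  cat("openpan analysis configuration\n")
  cat(sprintf("  tiers: hard >= %.2f, soft >= %.2f, shell >= %.2f (fraction of genomes)\n",
              x$hard_core_min, x$soft_core_min, x$shell_min))
  cat(sprintf("  ANI: genus < %g, species <= %g / >= %g, subspecies [%g, %g)\n",
              x$ani_genus, x$ani_species_low, x$ani_species_high,
              x$subspecies_band[1], x$subspecies_band[2]))
  cat(sprintf("  dDDH thresholds: > %s\n",
              paste(x$ddh_thresholds, collapse = ", > ")))
  cat(sprintf("  enrichment: |log2| > %g and abundance > %g%%\n",
              x$enrichment_log2_cutoff, x$enrichment_abundance_cutoff))
  cat(sprintf("  rarefaction permutations: %d; coverage filter: >= %g-fold\n",
              x$rarefaction_permutations, x$coverage_min))
  invisible(x)
}

#' Read / write a key-value configuration file
#'
#' Plain `key = value` lines (comments with `#`). Vector values are
#' comma-separated. Unknown keys are rejected.
#'
#' @param path file path.
#' @return [read_config()] returns an `openpan_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- lapply(kv, function(p) as.numeric(strsplit(trimws(p[2]), ",")[[1]]))
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  names(vals) <- keys
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config an `openpan_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "openpan_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(format(config[[k]], scientific = FALSE),
                                collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
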