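## One machine-readable run report aggregating all stage outputs.

#' Aggregate pipeline results into a single run report
#'
#' Runs partitioning, openness fitting/extrapolation and (optionally)
#' species delimitation, dDDH grouping, core-vs-accessory enrichment and
#' BGC summarisation on the supplied inputs and collects the results in
#' one list, shaped like the conventional pan-genome summary table.
#' Written as JSON it is the single machine-readable surface of a run.
#'
#' @param pa a [pa_matrix()].
#' @param ani optional ANI [identity_matrix()].
#' @param ddh optional dDDH [identity_matrix()].
#' @param annotations optional annotation data.frame (gene/letters).
#' @param bgc optional BGC count data.frame (genome/n_bgc).
#' @param config an [analysis_config()].
#' @param extrapolate_at genome counts for the extrapolation table.
#' @param out optional path; when given, the report is written there as
#'   JSON.
#' @return the report list, invisibly when `out` is given.
#' @export
run_report <- function(pa, ani = NULL, ddh = NULL, annotations = NULL,
                       bgc = NULL, config = analysis_config(),
                       extrapolate_at = c(101, 501, 1001), out = NULL) {
  part <- partition(pa, config)
  summ <- summarize_partition(part)
  op <- openness(pa, extrapolate_at = extrapolate_at, config = config)
  report <- list(
    n_genomes = ncol(pa),
    pan_genome = summ,
    heaps_fit = list(kappa = op$heaps$kappa, gamma = op$heaps$gamma,
                     open = op$heaps$open, method = op$heaps$method),
    extrapolation = op$extrapolation,
    core_extrapolation = list(
      core_at_infinity = round(op$core_fit$intercept),
      pct_of_current_core = round(100 * op$core_fit$intercept /
                                    summ$core_total, 1),
      r_squared = op$core_fit$r_squared),
    novelty_horizon = op$novelty_horizon
  )
  if (!is.null(ani)) {
    grouping <- delimit(ani, config)
    report$species <- list(
      count_range = as.list(grouping$species_count_range),
      genus_ok = grouping$genus_ok,
      n_conflicts = nrow(grouping$conflicts))
  }
  if (!is.null(ddh)) {
    dg <- ddh_groups(ddh, config$ddh_thresholds)
    report$ddh_groups <- lapply(dg, function(g) length(unique(g)))
  }
  if (!is.null(annotations)) {
    enr <- enrich_core_accessory(annotations, part, config)
    report$enrichment <- list(
      accessory_enriched = enr$category[enr$call == "enriched"],
      core_enriched = enr$category[enr$call == "impoverished"])
  }
  if (!is.null(bgc)) report$bgc <- summarize_bgc(bgc)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
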