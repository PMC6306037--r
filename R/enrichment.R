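## COG functional-category profiles and core-vs-accessory enrichment.
## Enrichment is the conventional descriptive filter: a category is
## called when |log2(relative-abundance ratio)| exceeds the fold cut-off
## AND the category's abundance in the favoured set exceeds the abundance
## cut-off. No significance testing is attached.

#' COG category profile of a gene set
#'
#' Relative abundance (percent of annotated genes) per COG letter.
#' Multi-letter assignments (e.g. "EF") are split fractionally across
#' their letters so that abundances stay normalised. Unannotated genes
#' (empty letters) are counted separately and excluded from the
#' denominator.
#'
#' @param annotations data.frame with columns `gene` and `letters`
#'   (see [read_annotations()]).
#' @param genes character vector: the gene set to profile.
#' @return object of class `"cog_profile"`: list with `abundance` (named
#'   percentages summing to 100), `set_size`, `annotated`, `unannotated`.
#' @export
#' @examples
#' ann <- data.frame(gene = c("g1", "g2"), letters = c("EF", "E"))
#' cog_profile(ann, c("g1", "g2"))$abundance  # E 75, F 25
cog_profile <- function(annotations, genes) {
  if (!length(genes)) stop("gene set is empty")
  missing <- setdiff(genes, annotations$gene)
  if (length(missing)) {
    stop("gene(s) absent from annotation table: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  letters <- annotations$letters[match(genes, annotations$gene)]
  annotated <- nzchar(letters)
  if (!any(annotated)) stop("no annotated genes in set")
  lets <- letters[annotated]
  single <- nchar(lets) == 1
  counts <- c(table(lets[single]))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  for (s in lets[!single]) {            # fractional split of multi-letter genes
    ls <- strsplit(s, "")[[1]]
    w <- 1 / length(ls)
    for (l in ls) counts[l] <- (if (is.na(counts[l])) 0 else counts[l]) + w
  }
  counts <- counts[order(names(counts))]
  structure(list(
    abundance = 100 * counts / sum(counts),
    set_size = length(genes),
    annotated = sum(annotated),
    unannotated = sum(!annotated)
  ), class = "cog_profile")
}

#' @export
print.cog_profile <- function(x, ...) {
  cat(sprintf("COG profile over %d genes (%d annotated, %d unannotated)\n",
              x$set_size, x$annotated, x$unannotated))
  top <- sort(x$abundance, decreasing = TRUE)
  top <- utils::head(top, 8)
  cat(" ", paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two COG profiles and call enrichment
#'
#' Per category: log2 of the relative-abundance ratio (set A over set B).
#' A category is `enriched` in A when log2 ratio > cutoff and its
#' abundance in A exceeds the abundance cut-off; `impoverished` in A
#' (i.e. enriched in B) when log2 ratio < -cutoff and its abundance in B
#' exceeds the cut-off. Categories present in only one profile get an
#' `absent` status instead of an infinite ratio; categories absent from
#' both are skipped.
#'
#' @param a,b `"cog_profile"` objects (conventionally a = accessory,
#'   b = core).
#' @param config an [analysis_config()] supplying the cut-offs.
#' @return object of class `"enrichment_result"`: data.frame with
#'   `category`, `abundance_a`, `abundance_b`, `log2_ratio`, `call`
#'   (enriched / impoverished / none / absent).
#' @export
compare_profiles <- function(a, b, config = analysis_config()) {
  stopifnot(inherits(a, "cog_profile"), inherits(b, "cog_profile"))
  cats <- sort(union(names(a$abundance), names(b$abundance)))
  av <- ifelse(cats %in% names(a$abundance), a$abundance[cats], 0)
  bv <- ifelse(cats %in% names(b$abundance), b$abundance[cats], 0)
  lc <- config$enrichment_log2_cutoff
  ac <- config$enrichment_abundance_cutoff
  log2r <- ifelse(av > 0 & bv > 0, log2(av / bv), NA_real_)
  call <- rep("none", length(cats))
  call[av > 0 & bv == 0] <- "absent"
  call[av == 0 & bv > 0] <- "absent"
  ok <- !is.na(log2r)
  call[ok & log2r > lc & av > ac] <- "enriched"
  call[ok & log2r < -lc & bv > ac] <- "impoverished"
  structure(data.frame(category = cats,
                       abundance_a = unname(av), abundance_b = unname(bv),
                       log2_ratio = unname(log2r), call = call,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Core-vs-accessory enrichment of a partitioned pan-genome
#'
#' Convenience wrapper: profiles the accessory (shell + cloud) and core
#' (hard + soft) orthogroup sets and compares them, so `enriched` means
#' accessory-enriched.
#'
#' @param annotations data.frame with `gene` and `letters` columns; gene
#'   ids must match the orthogroup ids of the partition.
#' @param partition a `"pan_partition"`.
#' @param config an [analysis_config()].
#' @return an `"enrichment_result"` (accessory over core) with the two
#'   profiles attached as attributes `profile_accessory`, `profile_core`.
#' @export
enrich_core_accessory <- function(annotations, partition,
                                  config = analysis_config()) {
  stopifnot(inherits(partition, "pan_partition"))
  core <- names(partition$tier)[partition$tier %in% c("hard_core", "soft_core")]
  accessory <- setdiff(names(partition$tier), core)
  pa <- cog_profile(annotations, accessory)
  pc <- cog_profile(annotations, core)
  res <- compare_profiles(pa, pc, config)
  attr(res, "profile_accessory") <- pa
  attr(res, "profile_core") <- pc
  res
}
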