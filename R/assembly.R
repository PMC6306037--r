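## Per-genome assembly statistics (size, %GC, N50/L50, coverage) and the
## contig coverage filter.

#' N50 and L50 of a contig set
#'
#' L50 is the smallest number X of largest contigs that together cover
#' strictly more than half of the total assembly length; N50 is the
#' length of the X-th largest contig. Ties in length are resolved by
#' sorted order.
#'
#' @param contig_lengths numeric vector of contig lengths (bp, >= 1).
#' @return list with `n50` (bp) and `l50` (count).
#' @export
#' @examples
#' n50_l50(c(50, 40, 30, 20, 10))  # N50 40, L50 2
n50_l50 <- function(contig_lengths) {
  if (!length(contig_lengths)) stop("contig length list is empty")
  if (any(contig_lengths < 1)) stop("contig lengths must be >= 1")
  s <- sort(unname(contig_lengths), decreasing = TRUE)
  half <- sum(s) / 2
  l50 <- which(cumsum(s) > half)[1]
  list(n50 = s[l50], l50 = as.integer(l50))
}

# parse the fold-coverage token from a SPAdes-style header
.header_coverage <- function(headers) {
  cov <- rep(NA_real_, length(headers))
  ok <- grepl("_cov_[0-9]*\\.?[0-9]+", headers)
  cov[ok] <- as.numeric(sub("^.*_cov_([0-9]*\\.?[0-9]+).*$", "\\1",
                            headers[ok]))
  if (any(!ok)) {
    stop("no coverage token in contig header(s): ",
         paste(utils::head(headers[!ok], 3), collapse = ", "))
  }
  cov
}

# parse the length token, falling back to the sequence length
.header_length <- function(headers, seqs) {
  ok <- grepl("_length_[0-9]+", headers)
  len <- nchar(seqs)
  len[ok] <- as.numeric(sub("^.*_length_([0-9]+).*$", "\\1", headers[ok]))
  len
}

#' Filter contigs by fold coverage
#'
#' Retains contigs whose header coverage is at least `min_cov` (contigs
#' with coverage strictly below the threshold are removed), preserving
#' input order.
#'
#' @param contigs named character vector as from [read_fasta()]; headers
#'   must carry a `_cov_<C>` token.
#' @param min_cov minimum fold coverage (default 7).
#' @return the retained contigs.
#' @export
filter_by_coverage <- function(contigs, min_cov = 7) {
  cov <- .header_coverage(names(contigs))
  contigs[cov >= min_cov]
}

#' GC content of a sequence set
#'
#' 100 * (G + C) / (A + C + G + T); ambiguous bases (anything other than
#' A, C, G, T) are excluded from both numerator and denominator.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @return percent GC.
#' @export
#' @examples
#' gc_content(c(s = "ATGCN"))  # 50
gc_content <- function(seqs) {
  if (!length(seqs)) stop("empty sequence set")
  bases <- table(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
  gc <- sum(bases[names(bases) %in% c("G", "C")])
  at <- sum(bases[names(bases) %in% c("A", "T")])
  if (gc + at == 0) stop("no unambiguous bases in sequence set")
  100 * gc / (gc + at)
}

#' Assembly statistics for one genome
#'
#' @param contigs named character vector of contig sequences (headers may
#'   carry `_length_` and `_cov_` tokens; coverage is optional here and
#'   reported as NA when absent).
#' @return list with `size` (bp), `gc` (percent), `n_contigs`, `n50`,
#'   `l50` and `mean_coverage` (length-weighted; NA without coverage
#'   tokens).
#' @export
assembly_stats <- function(contigs) {
  if (!length(contigs)) stop("empty contig set")
  lens <- nchar(contigs)
  nl <- n50_l50(lens)
  cov <- tryCatch(.header_coverage(names(contigs)), error = function(e) NULL)
  mean_cov <- if (is.null(cov)) NA_real_ else sum(cov * lens) / sum(lens)
  list(size = sum(lens), gc = gc_content(contigs),
       n_contigs = length(contigs), n50 = nl$n50, l50 = nl$l50,
       mean_coverage = mean_cov)
}

#' Assembly statistics table for several genomes
#'
#' @param fastas named character vector of FASTA paths (names are genome
#'   ids) or a named list of contig sets.
#' @param min_cov optional coverage filter applied before computing
#'   statistics (NULL: no filter).
#' @return data.frame with one row per genome.
#' @export
assembly_stats_table <- function(fastas, min_cov = NULL) {
  get <- function(x) if (is.character(x) && length(x) == 1 &&
                           file.exists(x)) read_fasta(x) else x
  rows <- lapply(fastas, function(f) {
    contigs <- get(f)
    if (!is.null(min_cov)) contigs <- filter_by_coverage(contigs, min_cov)
    as.data.frame(assembly_stats(contigs))
  })
  out <- do.call(rbind, rows)
  out <- cbind(genome = names(fastas), out)
  rownames(out) <- NULL
  out
}
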