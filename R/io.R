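## Readers and writers for the external formats the pipeline consumes:
## gene presence/absence matrices (Roary-style or plain binary CSV),
## square identity matrices (CSV or square PHYLIP), Newick trees, FASTA,
## predation assay matrices, COG annotation and BGC count tables.
## All matrices are label-keyed; input label order is preserved.

# Fixed metadata columns of the Roary gene_presence_absence.csv dialect.
# Matched by header name, not position, to tolerate dialect drift.
.roary_meta_cols <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc")

#' Gene presence/absence matrix
#'
#' Construct the pipeline's central object: a logical incidence matrix
#' with one row per orthogroup and one column per genome.
#'
#' @param m a logical (or 0/1) matrix with orthogroup row names and genome
#'   column names.
#' @return an object of class `"pa_matrix"` (a logical matrix).
#' @export
#' @examples
#' m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2,
#'             dimnames = list(c("og1", "og2"), c("g1", "g2")))
#' pa_matrix(m)
pa_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.numeric(m)) {
    if (!all(m %in% c(0, 1))) stop("incidence values must be 0/1 or logical")
    m <- m > 0
  }
  if (!is.logical(m)) stop("incidence matrix must be logical or 0/1")
  if (ncol(m) < 1) stop("a presence/absence matrix needs >= 1 genome")
  if (is.null(rownames(m))) rownames(m) <- paste0("og", seq_len(nrow(m)))
  if (is.null(colnames(m))) stop("genome (column) names are required")
  if (anyDuplicated(colnames(m))) {
    stop("duplicate genome names: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(m))) stop("duplicate orthogroup names")
  if (any(rowSums(m) == 0)) {
    stop("orthogroup(s) absent from every genome: ",
         paste(utils::head(rownames(m)[rowSums(m) == 0], 3), collapse = ", "))
  }
  class(m) <- c("pa_matrix", class(matrix()))
  m
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("Gene presence/absence matrix: %d orthogroups x %d genomes\n",
              nrow(x), ncol(x)))
  cat("  genomes:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "..." else "", "\n")
  cat(sprintf("  pan size %d, mean genes per genome %.1f\n",
              nrow(x), mean(colSums(x))))
  invisible(x)
}

.check_rect <- function(path, sep = ",") {
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  invisible(nf[1])
}

#' Read a gene presence/absence matrix
#'
#' Supports the Roary `gene_presence_absence.csv` dialect (fixed metadata
#' columns identified by header name, genome columns after them; a cell is
#' a presence iff it is non-empty) and a plain binary dialect (first column
#' orthogroup ids, remaining columns 0/1 per genome).
#'
#' @param path CSV file.
#' @param dialect `"auto"` (default; Roary if the header contains the
#'   Roary metadata columns), `"roary"` or `"binary"`.
#' @return a [pa_matrix()].
#' @export
#' @examples
#' f <- system.file("extdata", "example_gene_presence_absence.csv",
#'                  package = "openpan")
#' read_presence_absence(f)
read_presence_absence <- function(path, dialect = c("auto", "roary", "binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  .check_rect(path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(df)
  if (anyDuplicated(hdr)) {
    stop("duplicate genome names: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  if (dialect == "auto") {
    dialect <- if (sum(names(df) %in% .roary_meta_cols) >= 3) "roary" else "binary"
  }
  if (dialect == "roary") {
    meta <- names(df) %in% .roary_meta_cols
    if (!any(meta)) stop("no Roary metadata columns found in header")
    genomes <- names(df)[!meta]
    if (!length(genomes)) stop("no genome columns after Roary metadata columns")
    inc <- vapply(df[genomes], function(col) {
      !is.na(col) & nzchar(trimws(as.character(col)))
    }, logical(nrow(df)))
    inc <- matrix(inc, nrow = nrow(df),
                  dimnames = list(NULL, genomes))
    ids <- if ("Gene" %in% names(df)) as.character(df$Gene) else
      paste0("og", seq_len(nrow(df)))
    rownames(inc) <- ids
  } else {
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[-1])
    if (!is.numeric(vals)) stop("binary dialect requires numeric 0/1 cells")
    rownames(vals) <- ids
    inc <- vals
  }
  pa_matrix(inc)
}

#' Write a presence/absence matrix as binary CSV
#'
#' @param m a [pa_matrix()].
#' @param path output CSV path.
#' @export
write_presence_absence <- function(m, path) {
  stopifnot(inherits(m, "pa_matrix"))
  df <- data.frame(orthogroup = rownames(m),
                   `storage.mode<-`(unclass(m), "integer"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise identity matrix (ANI or dDDH)
#'
#' Validates and symmetrises a square matrix of pairwise percentages.
#' The diagonal is forced to 100. Off-diagonal asymmetries up to
#' `tolerance` percentage points are averaged; larger asymmetries are an
#' error.
#'
#' @param m square numeric matrix with matching row/column labels.
#' @param kind `"ANI"` or `"dDDH"`.
#' @param tolerance maximum tolerated asymmetry (percentage points).
#' @return an object of class `"identity_matrix"`.
#' @export
identity_matrix <- function(m, kind = c("ANI", "dDDH"), tolerance = 0.5) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("identity matrix must be square (got %d x %d)",
                 nrow(m), ncol(m)))
  }
  if (is.null(rownames(m)) && !is.null(colnames(m))) rownames(m) <- colnames(m)
  if (is.null(colnames(m)) && !is.null(rownames(m))) colnames(m) <- rownames(m)
  if (is.null(rownames(m))) stop("genome labels are required")
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels differ")
  }
  if (any(is.na(m)) || any(m < 0 | m > 100)) {
    stop("identity values must lie in [0, 100]")
  }
  asym <- abs(m - t(m))
  if (any(asym > tolerance)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetry of %.3g points between %s and %s exceeds tolerance %g",
                 max(asym), rownames(m)[idx[1]], colnames(m)[idx[2]], tolerance))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 100
  structure(m, kind = kind, class = c("identity_matrix", class(matrix())))
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("%s identity matrix: %d genomes, off-diagonal range [%.2f, %.2f]\n",
              attr(x, "kind"), nrow(x),
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Read a pairwise identity matrix
#'
#' @param path input file.
#' @param fmt `"csv"` (labelled square CSV, first column row labels) or
#'   `"phylip_square"` (count line, then label + n values per row).
#' @inheritParams identity_matrix
#' @return an [identity_matrix()].
#' @export
read_identity_matrix <- function(path, fmt = c("csv", "phylip_square"),
                                 kind = c("ANI", "dDDH"), tolerance = 0.5) {
  fmt <- match.arg(fmt)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (fmt == "csv") {
    .check_rect(path)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- as.character(df[[1]])
  } else {
    lines <- readLines(path, warn = FALSE)
    n <- as.integer(trimws(lines[1]))
    if (is.na(n) || length(lines) < n + 1) stop("malformed square PHYLIP matrix")
    toks <- strsplit(trimws(lines[2:(n + 1)]), "[ \t]+")
    labs <- vapply(toks, `[`, "", 1)
    m <- t(vapply(toks, function(t) as.numeric(t[-1]), numeric(n)))
    dimnames(m) <- list(labs, labs)
  }
  if (!is.numeric(m)) stop("identity matrix cells must be numeric")
  identity_matrix(m, kind = kind, tolerance = tolerance)
}

#' @rdname read_identity_matrix
#' @param m an [identity_matrix()].
#' @export
write_identity_matrix <- function(m, path, fmt = c("csv", "phylip_square")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(m, "identity_matrix"))
  if (fmt == "csv") {
    df <- data.frame(genome = rownames(m), unclass(m), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(as.character(nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] with
#' validation of the pipeline's tree contract: unique leaf labels and
#' non-negative branch lengths. Round-trips preserve topology, labels and
#' branch lengths (branch lengths written to 6 decimals).
#'
#' @param path Newick file.
#' @return [read_newick()] returns an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    # locate first unbalanced parenthesis for the error message
    bal <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1, 0)))
    pos <- which(bal < 0)[1]
    if (is.na(pos)) pos <- nchar(txt)
    stop(sprintf("malformed Newick near character %d of %s", pos, path))
  }
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch lengths in tree")
  }
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a predation assay matrix
#'
#' Strains in rows, prey organisms in columns, killing-zone diameters in
#' mm. The matrix must be complete and non-negative.
#'
#' @param path CSV with strain labels in the first column.
#' @return a numeric matrix of class `"predation_matrix"`.
#' @export
read_predation_matrix <- function(path) {
  .check_rect(path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  predation_matrix(m)
}

#' @rdname read_predation_matrix
#' @param m strains x prey numeric matrix of killing-zone diameters (mm).
#' @export
predation_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("killing-zone diameters must be numeric")
  if (any(is.na(m))) stop("predation matrix must be complete (no missing cells)")
  if (any(m < 0)) stop("killing-zone diameters must be >= 0")
  if (is.null(rownames(m))) stop("strain labels are required")
  class(m) <- c("predation_matrix", class(matrix()))
  m
}

#' @rdname read_predation_matrix
#' @export
write_predation_matrix <- function(m, path) {
  df <- data.frame(strain = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-to-COG-category annotation table
#'
#' Two-column TSV: gene identifier and COG category letters (a gene may
#' carry several letters, e.g. `"EF"`; empty or `"-"` means unannotated).
#'
#' @param path TSV file with a header line.
#' @return a data.frame with columns `gene` and `letters`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation table needs gene and letters columns")
  names(df)[1:2] <- c("gene", "letters")
  df$gene <- as.character(df$gene)
  df$letters <- toupper(trimws(as.character(df$letters)))
  df$letters[df$letters %in% c("-", "NA")] <- ""
  if (anyDuplicated(df$gene)) stop("duplicate gene identifiers in annotations")
  df[c("gene", "letters")]
}

#' @rdname read_annotations
#' @param annotations data.frame with `gene` and `letters` columns.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[c("gene", "letters")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-genome BGC count table
#'
#' TSV with genome identifiers and biosynthetic gene cluster counts.
#'
#' @param path TSV file (columns: genome, n_bgc).
#' @return a data.frame with columns `genome` and `n_bgc`.
#' @export
read_bgc_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("BGC table needs genome and count columns")
  names(df)[1:2] <- c("genome", "n_bgc")
  if (!is.numeric(df$n_bgc) || any(df$n_bgc < 0)) {
    stop("BGC counts must be non-negative numbers")
  }
  df[c("genome", "n_bgc")]
}

#' Summarise a BGC count table
#'
#' @param bgc data.frame as returned by [read_bgc_counts()].
#' @return list with total count, genome count, and the mean per genome
#'   (both exact and rounded to the nearest integer).
#' @export
summarize_bgc <- function(bgc) {
  total <- sum(bgc$n_bgc)
  n <- nrow(bgc)
  list(total_bgc = total, n_genomes = n,
       mean_per_genome = total / n,
       mean_per_genome_rounded = round(total / n))
}

## Minimal FASTA IO. Sequences are plain character vectors named by their
## full header line (first token used as the contig/sequence id).

#' Read / write FASTA
#'
#' @param path FASTA file.
#' @return [read_fasta()] returns a named character vector of sequences;
#'   names hold the full header (without `>`).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
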