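#' m6aScore: consensus subtyping and PCA-based scoring of m6A regulators
#'
#' Tools to screen N6-methyladenosine (m6A) regulator genes between tissue
#' groups, discover tumor expression subtypes by resampled consensus
#' clustering, validate clusters (silhouette width, SigClust), extract a
#' pairwise differential-expression signature, compute a PCA-based per-sample
#' m6A score, and evaluate the score against metastasis, Gleason grade,
#' survival and stemness.  A seeded synthetic-cohort generator
#' ([simulate_cohort()]) makes every stage testable without external data.
#'
#' @keywords internal
"_PACKAGE"

#' The 21 m6A regulator genes
#'
#' Writers (methyltransferases), erasers (demethylases) and readers
#' (m6A-binding proteins) commonly used to define the m6A feature space in
#' bulk expression analyses.
#'
#' @param role Optional subset: `"writer"`, `"eraser"` or `"reader"`.
#' @return Character vector of gene symbols.
#' @examples
#' m6a_regulators()
#' m6a_regulators("eraser")
#' @export
m6a_regulators <- function(role = NULL) {
  reg <- c(
    METTL3 = "writer", METTL14 = "writer", RBM15 = "writer",
    RBM15B = "writer", WTAP = "writer", KIAA1429 = "writer",
    CBLL1 = "writer", ZC3H13 = "writer",
    ALKBH5 = "eraser", FTO = "eraser",
    YTHDC1 = "reader", YTHDC2 = "reader", YTHDF1 = "reader",
    YTHDF2 = "reader", YTHDF3 = "reader", IGF2BP1 = "reader",
    HNRNPA2B1 = "reader", HNRNPC = "reader", FMR1 = "reader",
    LRPPRC = "reader", ELAVL1 = "reader"
  )
  if (is.null(role)) return(names(reg))
  role <- match.arg(role, c("writer", "eraser", "reader"))
  names(reg)[reg == role]
}

.stop <- function(...) stop(..., call. = FALSE)

#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is a numeric matrix with unique, non-missing gene ids
#' as row names and unique sample ids as column names, and no missing values.
#'
#' @param m Matrix to validate.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    .stop("expression matrix must be a numeric matrix")
  g <- rownames(m); s <- colnames(m)
  if (is.null(g) || is.null(s))
    .stop("expression matrix must have gene row names and sample column names")
  if (anyNA(m)) .stop("expression matrix contains missing values")
  dup <- unique(g[duplicated(g)])
  if (length(dup))
    .stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(s[duplicated(s)])
  if (length(dup))
    .stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  invisible(m)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids (first
#' field `gene_id`) and whose first column holds gene ids.  Values are
#' returned untransformed; use [log2_transform()] for FPKM-like input.
#'
#' @param path Path to a TSV file.
#' @return Numeric gene-by-sample matrix with dimnames.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) .stop("expression TSV needs a gene id column and at least one sample")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    .stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' (row %d, column %d)",
                  body[i, j], genes[i], samples[j], i, j + 1L))
  }
  if (anyNA(num)) {
    i <- which(is.na(num), arr.ind = TRUE)[1, ]
    .stop(sprintf("missing value at gene '%s', sample '%s'", genes[i[1]], samples[i[2]]))
  }
  dimnames(num) <- list(genes, samples)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces them bitwise.
#'
#' @param m Expression matrix (see [validate_expression_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  chr <- array(sprintf("%.17g", m), dim = dim(m))
  out <- cbind(gene_id = rownames(m), chr)
  colnames(out) <- c("gene_id", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform non-negative expression values
#'
#' Standard ingest transform for FPKM-like matrices: every value `x` is
#' replaced by `log2(x + pseudocount)`.  Data already on log scale must skip
#' this step (negative values trigger an error).
#'
#' @param m Expression matrix with non-negative values.
#' @param pseudocount Positive offset, default 1.
#' @return Transformed matrix.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  validate_expression_matrix(m)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    .stop("pseudocount must be a single positive number")
  if (any(m < 0))
    .stop("negative values found; input already on log scale should not be log2-transformed")
  log2(m + pseudocount)
}

#' Z-score each gene row
#'
#' Centers every gene to mean 0 and scales to sample standard deviation 1
#' (n-1 denominator).  Required before PCA scoring and useful before
#' clustering.
#'
#' @param m Expression matrix whose rows all have positive standard deviation.
#' @return Row-standardized matrix.
#' @export
zscore_rows <- function(m) {
  validate_expression_matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  bad <- rownames(m)[!is.finite(sd) | sd <= 0]
  if (length(bad))
    .stop("zero-variance gene row(s): ", paste(bad, collapse = ", "))
  (m - mu) / sd
}

.clinical_cols <- c("sample_id", "tissue", "metastasis", "gleason",
                    "os_time", "os_event", "rfs_time", "rfs_event")

#' Validate a clinical annotation table
#'
#' Checks the cohort annotation contract: unique sample ids; tissue in
#' `tumor`/`normal`; metastasis in `yes`/`no`/`unknown`; Gleason score an
#' integer in 6..10 or `NA`; overall-survival and recurrence-free-survival
#' times non-negative or `NA`; event flags 0/1 or `NA`.  An optional integer
#' `subtype` column is allowed.
#'
#' @param ann Data frame of per-sample clinical annotations.
#' @return `ann` with normalized types, invisibly usable downstream.
#' @export
validate_clinical <- function(ann) {
  if (!is.data.frame(ann)) .stop("clinical annotations must be a data frame")
  miss <- setdiff(.clinical_cols, colnames(ann))
  if (length(miss)) .stop("missing clinical column(s): ", paste(miss, collapse = ", "))
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id))
    .stop("duplicate sample_id in clinical table: ",
          paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  ann$tissue <- as.character(ann$tissue)
  if (!all(ann$tissue %in% c("tumor", "normal")))
    .stop("tissue must be 'tumor' or 'normal'")
  met <- as.character(ann$metastasis)
  met[is.na(met) | met == ""] <- "unknown"
  if (!all(met %in% c("yes", "no", "unknown")))
    .stop("metastasis must be 'yes', 'no' or 'unknown'")
  ann$metastasis <- met
  gl <- suppressWarnings(as.integer(ann$gleason))
  if (any(!is.na(gl) & (gl < 6 | gl > 10)))
    .stop("gleason must be an integer in 6..10 or missing")
  ann$gleason <- gl
  for (v in c("os_time", "rfs_time")) {
    tt <- suppressWarnings(as.numeric(ann[[v]]))
    if (any(!is.na(tt) & tt < 0)) .stop(v, " must be non-negative")
    ann[[v]] <- tt
  }
  for (v in c("os_event", "rfs_event")) {
    ev <- suppressWarnings(as.integer(ann[[v]]))
    if (any(!is.na(ev) & !ev %in% 0:1)) .stop(v, " flags must be 0 or 1")
    ann[[v]] <- ev
  }
  if ("subtype" %in% colnames(ann))
    ann$subtype <- suppressWarnings(as.integer(ann$subtype))
  ann
}

#' Read a clinical annotation TSV
#'
#' Empty fields are read as missing; missing metastasis labels become
#' `"unknown"`.
#'
#' @param path Path to a TSV with the columns of [validate_clinical()].
#' @return Normalized clinical data frame.
#' @export
read_clinical <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  validate_clinical(ann)
}

#' Write a clinical annotation TSV
#'
#' Missing fields are written as empty strings.
#'
#' @param ann Clinical data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(ann, path) {
  ann <- validate_clinical(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Check that annotated samples are present in the expression matrix
#'
#' @param m Expression matrix.
#' @param ann Clinical data frame.
#' @return Invisibly `TRUE`; errors listing absent samples otherwise.
#' @export
check_cohort <- function(m, ann) {
  validate_expression_matrix(m)
  ann <- validate_clinical(ann)
  missing <- setdiff(ann$sample_id, colnames(m))
  if (length(missing))
    .stop("annotated sample(s) absent from expression matrix: ",
          paste(missing, collapse = ", "))
  invisible(TRUE)
}
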