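#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the input order is preserved.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the same order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) .stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Vectorized per-gene pooled two-sample t test on the rows of m.
.row_t_test <- function(m, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  v1 <- apply(m[, idx1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, idx2, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), n1 + n2 - 2),
              as.numeric(diff == 0))
  data.frame(gene_id = rownames(m), log2_fc = diff, t = t, p_value = p,
             stringsAsFactors = FALSE)
}

#' Pairwise differential expression between subtypes and signature extraction
#'
#' For every unordered pair of subtypes, tests each gene with a pooled
#' two-sample t test on log2 values (`log2_fc` is the plain mean difference),
#' adjusts p-values with Benjamini-Hochberg within each comparison, and
#' flags genes with `|log2_fc| > lfc_threshold` and `q < fdr_threshold`.
#' The signature is the union of significant genes over all comparisons,
#' de-duplicated and sorted.
#'
#' @param m Expression matrix (log2 scale), all cohort genes.
#' @param labels Subtype labels named by sample (>= 2 subtypes, each with
#'   >= 2 samples); samples absent from `m` are an error.
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return List with `tables` (one `DegTable` data frame per comparison,
#'   named `"a_vs_b"`) and `signature` (sorted character vector).
#' @export
pairwise_deg_signature <- function(m, labels, lfc_threshold = 2,
                                   fdr_threshold = 0.05) {
  validate_expression_matrix(m)
  if (is.null(names(labels))) .stop("labels must be named by sample id")
  missing <- setdiff(names(labels), colnames(m))
  if (length(missing))
    .stop("labeled sample(s) absent from matrix: ", paste(missing, collapse = ", "))
  groups <- split(names(labels), labels)
  if (length(groups) < 2) .stop("need at least 2 subtypes")
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small))
    .stop("subtype(s) with fewer than 2 samples: ", paste(small, collapse = ", "))

  lv <- names(groups)
  tables <- list()
  for (i in seq_along(lv)[-length(lv)]) {
    for (j in seq((i + 1), length(lv))) {
      tab <- .row_t_test(m, match(groups[[lv[i]]], colnames(m)),
                         match(groups[[lv[j]]], colnames(m)))
      tab$comparison <- paste0(lv[i], "_vs_", lv[j])
      tab$q_value <- bh_adjust(tab$p_value)
      tab$significant <- abs(tab$log2_fc) > lfc_threshold &
        tab$q_value < fdr_threshold
      tables[[tab$comparison[1]]] <-
        tab[, c("gene_id", "comparison", "log2_fc", "t", "p_value",
                "q_value", "significant")]
    }
  }
  signature <- sort(unique(unlist(
    lapply(tables, function(t) t$gene_id[t$significant]))))
  list(tables = tables, signature = signature)
}
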