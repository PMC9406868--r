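#' Fit the PCA-based m6A score model
#'
#' Rows of the signature submatrix are z-scored (the stored per-gene means
#' and standard deviations define the cohort-transfer contract), and the
#' loading vectors are the top-2 eigenvectors of the gene-gene covariance of
#' the standardized data.  The sign of each component is oriented so that
#' the correlation between its sample coordinates and the mean standardized
#' signature expression is non-positive; with this convention samples with
#' high overall signature expression (the m6A-active, metastasis-prone ones)
#' get *low* scores, which fixes the otherwise arbitrary PCA signs and makes
#' the score direction reproducible.
#'
#' @param m Expression matrix (log2 scale).
#' @param signature_genes At least 2 genes, rows of `m`, each with positive
#'   variance; at least 3 samples.
#' @return An `m6a_pca_model`: `signature_genes`, `center`, `scale`,
#'   `loadings` (genes x 2, orthonormal columns), `explained_variance`
#'   (fractions for PC1 and PC2).
#' @export
fit_score_model <- function(m, signature_genes) {
  validate_expression_matrix(m)
  signature_genes <- unique(as.character(signature_genes))
  missing <- setdiff(signature_genes, rownames(m))
  if (length(missing))
    .stop("signature gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (length(signature_genes) < 2) .stop("need at least 2 usable signature genes")
  if (ncol(m) < 3) .stop("need at least 3 samples to fit the score model")
  sub <- m[signature_genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  bad <- signature_genes[!is.finite(sds) | sds <= 0]
  if (length(bad))
    .stop("zero-variance signature gene(s): ", paste(bad, collapse = ", "))
  ctr <- rowMeans(sub)
  Z <- (sub - ctr) / sds
  G <- tcrossprod(Z) / (ncol(Z) - 1)        # gene-gene covariance (= correlation)
  eig <- eigen(G, symmetric = TRUE)
  L <- eig$vectors[, 1:2, drop = FALSE]
  coords <- crossprod(Z, L)
  mean_z <- colMeans(Z)
  for (j in 1:2) {
    r <- suppressWarnings(stats::cor(coords[, j], mean_z))
    if (is.finite(r) && r > 0) L[, j] <- -L[, j]
  }
  ev <- pmax(eig$values, 0)
  rownames(L) <- signature_genes
  colnames(L) <- c("PC1", "PC2")
  structure(list(signature_genes = signature_genes,
                 center = ctr, scale = sds, loadings = L,
                 explained_variance = ev[1:2] / sum(ev)),
            class = "m6a_pca_model")
}

#' @export
print.m6a_pca_model <- function(x, ...) {
  cat(sprintf("m6A PCA score model: %d signature genes; PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
              length(x$signature_genes),
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

#' Compute per-sample m6A scores
#'
#' Each sample is centered and scaled by the model's stored per-gene means
#' and standard deviations, projected onto the oriented PC1 and PC2
#' loadings, and scored as the sum of the two coordinates.  Applying a
#' fitted model to a new cohort reuses the stored centering (use
#' [fit_score_model()] on the new cohort instead to refit).
#'
#' @param model An `m6a_pca_model`.
#' @param m Expression matrix containing every signature gene.
#' @return Data frame with `sample_id`, `pc1`, `pc2`, `m6a_score`.
#' @export
compute_scores <- function(model, m) {
  if (!inherits(model, "m6a_pca_model")) .stop("model must be an m6a_pca_model")
  validate_expression_matrix(m)
  missing <- setdiff(model$signature_genes, rownames(m))
  if (length(missing))
    .stop("signature gene(s) missing from matrix: ", paste(missing, collapse = ", "))
  Z <- (m[model$signature_genes, , drop = FALSE] - model$center) / model$scale
  coords <- crossprod(Z, model$loadings)
  data.frame(sample_id = colnames(m),
             pc1 = coords[, 1], pc2 = coords[, 2],
             m6a_score = coords[, 1] + coords[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize an m6A score model to JSON
#'
#' @param model An `m6a_pca_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_model <- function(model, path) {
  if (!inherits(model, "m6a_pca_model")) .stop("model must be an m6a_pca_model")
  obj <- list(signature_genes = model$signature_genes,
              center = unname(model$center), scale = unname(model$scale),
              loadings_pc1 = unname(model$loadings[, 1]),
              loadings_pc2 = unname(model$loadings[, 2]),
              explained_variance = unname(model$explained_variance))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an m6A score model from JSON
#'
#' @param path Path written by [write_score_model()].
#' @return An `m6a_pca_model`.
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$signature_genes
  L <- cbind(PC1 = obj$loadings_pc1, PC2 = obj$loadings_pc2)
  rownames(L) <- g
  structure(list(signature_genes = g,
                 center = stats::setNames(obj$center, g),
                 scale = stats::setNames(obj$scale, g),
                 loadings = L,
                 explained_variance = obj$explained_variance),
            class = "m6a_pca_model")
}
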