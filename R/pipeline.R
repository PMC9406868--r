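#' Run the full m6A regulator analysis pipeline
#'
#' Orchestrates the whole analysis on one cohort: (1) Mann-Whitney screen of
#' the regulator panel between tumor and normal tissue; (2) resampled
#' consensus clustering of the tumor samples on the selected regulators over
#' `k = 2..k_max` with CDF/delta-area selection of k; (3) final subtype
#' assignment from the consensus matrix, silhouette widths on the
#' correlation distance, and pairwise SigClust significance; (4) pairwise
#' differential expression between subtypes over all genes with
#' Benjamini-Hochberg control and signature extraction; (5) Student's t
#' screen of the tumor/normal-selected regulators between metastatic and
#' non-metastatic tumors, PCA score model fit on the metastasis-associated
#' regulators, and per-tumor m6A scores; (6) evaluation: score-by-subtype
#' and score-by-Gleason ANOVA, Spearman correlation of the score with each
#' regulator, Kaplan-Meier / log-rank for overall and recurrence-free
#' survival by subtype, ROC/AUC of the score for metastasis (low score =
#' metastatic), and optionally a stemness index and its correlation with the
#' score.
#'
#' @param expr Expression matrix (log2 scale), genes x samples.
#' @param clinical Clinical annotation data frame (see
#'   [validate_clinical()]).
#' @param regulators Regulator panel (default the 21 m6A regulators present
#'   in `expr`).
#' @param k_max Largest k for consensus clustering (default 6).
#' @param n_iter Consensus resampling iterations per k (default 1000).
#' @param subsample_fraction Subsample fraction per iteration (default 0.8).
#' @param alpha Raw-p selection threshold for both screens (default 0.05).
#' @param lfc_threshold,fdr_threshold DEG signature thresholds (defaults 2
#'   and 0.05).
#' @param delta_threshold Relative delta-area threshold for k selection
#'   (default 0.2).
#' @param sigclust_n_sim SigClust null simulations per cluster pair
#'   (default 1000).
#' @param stemness_weights Optional named stemness signature weights.
#' @param seed Optional integer seed for the whole run.
#' @return An `m6a_pipeline` list with components `tn_screen`,
#'   `consensus` (per-k results), `k_selection`, `subtypes`, `silhouette`,
#'   `sigclust`, `deg`, `met_screen`, `score_model`, `scores`, `evaluation`.
#' @export
run_m6a_pipeline <- function(expr, clinical,
                             regulators = intersect(m6a_regulators(), rownames(expr)),
                             k_max = 6, n_iter = 1000, subsample_fraction = 0.8,
                             alpha = 0.05, lfc_threshold = 2,
                             fdr_threshold = 0.05, delta_threshold = 0.2,
                             sigclust_n_sim = 1000, stemness_weights = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_cohort(expr, clinical)
  clinical <- validate_clinical(clinical)

  ## 1. tumor-vs-normal regulator screen (Mann-Whitney)
  tn <- screen_regulators(expr, clinical, regulators,
                          contrast = "tumor_vs_normal", alpha = alpha)
  selected <- tn$gene_id[tn$selected]
  if (length(selected) < 2)
    .stop("fewer than 2 regulators pass the tumor-vs-normal screen")

  ## 2. consensus clustering of tumors on the selected regulators
  tumor_ids <- clinical$sample_id[clinical$tissue == "tumor"]
  mt <- expr[selected, tumor_ids, drop = FALSE]
  consensus <- lapply(2:k_max, function(k)
    build_consensus(mt, k, n_iter = n_iter,
                    subsample_fraction = subsample_fraction))
  ksel <- select_k(consensus, delta_threshold = delta_threshold)
  k <- ksel$chosen_k

  ## 3. assignment + validation
  cres <- consensus[[k - 1]]
  subtypes <- assign_subtypes(cres, k)
  D <- correlation_distance(mt)
  sil <- silhouette_widths(D, subtypes[colnames(mt)])
  pairs <- utils::combn(sort(unique(subtypes)), 2)
  sig_p <- apply(pairs, 2, function(pr) {
    ids <- names(subtypes)[subtypes %in% pr]
    sigclust(mt[, ids, drop = FALSE], n_sim = sigclust_n_sim)$p_value
  })
  sigclust_tab <- data.frame(cluster_a = pairs[1, ], cluster_b = pairs[2, ],
                             p_value = sig_p)

  ## 4. pairwise DEG signature over all genes; clusters too small to test
  ## (fewer than 2 samples, e.g. a split-off outlier) are left out
  sizes <- table(subtypes)
  usable <- subtypes[subtypes %in% as.integer(names(sizes)[sizes >= 2])]
  if (length(unique(usable)) < length(sizes))
    warning("excluding ", length(sizes) - length(unique(usable)),
            " subtype(s) with fewer than 2 samples from the DEG comparison")
  deg <- pairwise_deg_signature(expr[, tumor_ids, drop = FALSE], usable,
                                lfc_threshold = lfc_threshold,
                                fdr_threshold = fdr_threshold)

  ## 5. metastasis screen and m6A score
  met <- screen_regulators(expr, clinical, selected,
                           contrast = "metastatic_vs_not", alpha = alpha)
  met_genes <- met$gene_id[met$selected]
  score_model <- NULL; scores <- NULL
  if (length(met_genes) >= 2) {
    score_model <- fit_score_model(mt, met_genes)
    scores <- compute_scores(score_model, mt)
  }

  ## 6. evaluation
  evaluation <- list()
  if (!is.null(scores)) {
    cl <- clinical[match(scores$sample_id, clinical$sample_id), ]
    sc <- scores$m6a_score
    st_groups <- split(sc, subtypes[scores$sample_id])
    st_groups <- st_groups[vapply(st_groups, length, integer(1)) >= 2]
    if (length(st_groups) >= 2)
      evaluation$score_by_subtype <- one_way_anova(st_groups)
    gl_groups <- split(sc, cl$gleason)
    gl_groups <- gl_groups[vapply(gl_groups, length, integer(1)) >= 2]
    if (length(gl_groups) >= 2)
      evaluation$score_by_gleason <- one_way_anova(gl_groups)
    evaluation$score_vs_regulators <- data.frame(
      gene_id = selected,
      spearman_r = vapply(selected, function(g)
        rank_correlation(sc, mt[g, scores$sample_id])$r, numeric(1)),
      row.names = NULL)
    known <- cl$metastasis != "unknown"
    if (length(unique(cl$metastasis[known])) == 2) {
      evaluation$metastasis_roc <-
        roc_auc(sc[known], cl$metastasis[known] == "yes", "low_is_positive")
      evaluation$score_by_metastasis <-
        students_t(sc[known][cl$metastasis[known] == "yes"],
                   sc[known][cl$metastasis[known] == "no"])
    }
    if (!is.null(stemness_weights)) {
      st <- stemness_index(expr[, scores$sample_id, drop = FALSE],
                           stemness_weights)
      evaluation$stemness <- st
      evaluation$score_vs_stemness <- rank_correlation(sc, st$stemness_index)
      sg <- split(st$stemness_index, subtypes[st$sample_id])
      sg <- sg[vapply(sg, length, integer(1)) >= 2]
      if (length(sg) >= 2)
        evaluation$stemness_by_subtype <- one_way_anova(sg)
    }
  }
  for (endpoint in c("os", "rfs")) {
    tt <- clinical[match(names(subtypes), clinical$sample_id), ]
    tm <- tt[[paste0(endpoint, "_time")]]
    ev <- tt[[paste0(endpoint, "_event")]]
    ok <- !is.na(tm) & !is.na(ev)
    if (sum(ok) > 0 && length(unique(subtypes[ok])) >= 2) {
      evaluation[[paste0(endpoint, "_logrank")]] <-
        logrank_test(tm[ok], ev[ok], subtypes[ok])
      evaluation[[paste0(endpoint, "_km")]] <-
        lapply(split(seq_along(tm)[ok], subtypes[ok]),
               function(ii) km_estimate(tm[ii], ev[ii]))
    }
  }

  structure(list(tn_screen = tn, selected_regulators = selected,
                 consensus = consensus, k_selection = ksel,
                 subtypes = subtypes, silhouette = sil,
                 sigclust = sigclust_tab, deg = deg,
                 met_screen = met, metastasis_regulators = met_genes,
                 score_model = score_model, scores = scores,
                 evaluation = evaluation),
            class = "m6a_pipeline")
}

#' @export
print.m6a_pipeline <- function(x, ...) {
  cat("m6A regulator analysis pipeline\n")
  cat(sprintf("  tumor-vs-normal screen: %d/%d regulators selected\n",
              length(x$selected_regulators), nrow(x$tn_screen)))
  cat(sprintf("  consensus clustering: chosen k = %d; mean silhouette %.3f\n",
              x$k_selection$chosen_k, mean(x$silhouette)))
  cat(sprintf("  DEG signature: %d genes\n", length(x$deg$signature)))
  cat(sprintf("  metastasis screen: %d regulators\n",
              length(x$metastasis_regulators)))
  ev <- x$evaluation
  if (!is.null(ev$metastasis_roc))
    cat(sprintf("  metastasis AUC (low score = metastatic): %.3f\n",
                ev$metastasis_roc$auc))
  if (!is.null(ev$rfs_logrank))
    cat(sprintf("  RFS log-rank p = %.3g; OS log-rank p = %.3g\n",
                ev$rfs_logrank$p_value, ev$os_logrank$p_value))
  if (!is.null(ev$score_vs_stemness))
    cat(sprintf("  score vs stemness: Spearman r = %.3f\n",
                ev$score_vs_stemness$r))
  invisible(x)
}
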