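#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of the generative model used by
#' [simulate_cohort()].  Defaults mirror the structure the analysis assumes
#' in a prostate-cancer cohort: 21 m6A regulator genes of which 18 shift
#' between tumor and normal tissue, three latent tumor subtypes with
#' block-structured regulator shifts, a metastasis label driven by one
#' regulator block, subtype-correlated Gleason grades, and censored
#' recurrence-free survival with a subtype-dependent hazard while overall
#' survival carries no subtype effect.
#'
#' @param n_tumor,n_normal Sample counts (default 150 tumors, 30 normals).
#' @param n_regulators Number of regulator genes (default 21; with 21 the
#'   canonical regulator symbols of [m6a_regulators()] are used).
#' @param n_tumor_normal_shifted How many regulators gain `tumor_normal_shift`
#'   in tumors (default 18).
#' @param n_background_genes Unshifted background genes (default 500).
#' @param k_subtypes Latent tumor subtypes (default 3).
#' @param subtype_proportions Simplex vector of subtype frequencies
#'   (default equal).
#' @param subtype_shift Log2 shift added to a subtype's regulator block
#'   (delta, default 2).
#' @param activation_shift Additional uniform log2 shift on the whole
#'   regulator panel in the last (m6A-hyperactive) subtype (default 1).
#' @param tumor_normal_shift Log2 shift added in all tumors to the designated
#'   regulators (tau, default 1).
#' @param gene_baseline_range Range of per-gene baseline means, log2 units
#'   (default `c(2, 8)`).
#' @param gene_noise_sd Residual standard deviation sigma, log2 units
#'   (default 1).
#' @param metastasis_gene_count Regulators driving metastasis (default 7;
#'   taken from the last subtype's block).
#' @param metastasis_beta Logistic slope per z-unit of each metastasis gene
#'   (default 1; the linear predictor is the summed z-score of the set).
#' @param metastasis_intercept Logistic intercept (default -1).
#' @param gleason_cutpoints Ordered-logit cutpoints for Gleason 6..10.
#' @param gleason_shifts Per-subtype ordered-logit shift toward higher grade
#'   (default 0 except the last subtype, +2).
#' @param rfs_hazard_ratios Per-subtype recurrence hazard multipliers
#'   (default 1 except the last subtype, 2.5).
#' @param os_hazard_ratios Per-subtype overall-survival hazard multipliers
#'   (default all 1).
#' @param baseline_hazard Exponential event hazard per month (default 0.01).
#' @param censoring_horizon Uniform censoring horizon in months (default 120).
#' @param seed Integer random seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tumor = 150, n_normal = 30,
                       n_regulators = 21, n_tumor_normal_shifted = 18,
                       n_background_genes = 500,
                       k_subtypes = 3, subtype_proportions = NULL,
                       subtype_shift = 2.0, activation_shift = 1.0,
                       tumor_normal_shift = 1.0,
                       gene_baseline_range = c(2, 8), gene_noise_sd = 1.0,
                       metastasis_gene_count = 7, metastasis_beta = 1.0,
                       metastasis_intercept = -1.0,
                       gleason_cutpoints = stats::qlogis(c(0.15, 0.60, 0.80, 0.95)),
                       gleason_shifts = NULL,
                       rfs_hazard_ratios = NULL, os_hazard_ratios = NULL,
                       baseline_hazard = 0.01, censoring_horizon = 120,
                       seed = 1L) {
  k <- k_subtypes
  if (is.null(subtype_proportions)) subtype_proportions <- rep(1 / k, k)
  if (is.null(gleason_shifts)) gleason_shifts <- c(rep(0, k - 1), 2)
  if (is.null(rfs_hazard_ratios)) rfs_hazard_ratios <- c(rep(1, k - 1), 2.5)
  if (is.null(os_hazard_ratios)) os_hazard_ratios <- rep(1, k)
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal,
              n_regulators = n_regulators,
              n_tumor_normal_shifted = n_tumor_normal_shifted,
              n_background_genes = n_background_genes,
              k_subtypes = k, subtype_proportions = subtype_proportions,
              subtype_shift = subtype_shift,
              activation_shift = activation_shift,
              tumor_normal_shift = tumor_normal_shift,
              gene_baseline_range = gene_baseline_range,
              gene_noise_sd = gene_noise_sd,
              metastasis_gene_count = metastasis_gene_count,
              metastasis_beta = metastasis_beta,
              metastasis_intercept = metastasis_intercept,
              gleason_cutpoints = gleason_cutpoints,
              gleason_shifts = gleason_shifts,
              rfs_hazard_ratios = rfs_hazard_ratios,
              os_hazard_ratios = os_hazard_ratios,
              baseline_hazard = baseline_hazard,
              censoring_horizon = censoring_horizon,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` list.
#' @return `cfg` invisibly if valid, otherwise an error (raised before any
#'   sampling happens).
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) .stop("invalid sim_config: ", msg)
  pos1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  chk(pos1(cfg$n_tumor) && pos1(cfg$n_normal), "sample counts must be positive")
  chk(pos1(cfg$n_regulators), "n_regulators must be positive")
  chk(cfg$n_tumor_normal_shifted >= 0 &&
        cfg$n_tumor_normal_shifted <= cfg$n_regulators,
      "n_tumor_normal_shifted must be in 0..n_regulators")
  chk(cfg$n_background_genes >= 0, "n_background_genes must be non-negative")
  chk(pos1(cfg$k_subtypes) && cfg$k_subtypes >= 1, "k_subtypes must be >= 1")
  k <- cfg$k_subtypes
  chk(length(cfg$subtype_proportions) == k &&
        all(cfg$subtype_proportions > 0) &&
        abs(sum(cfg$subtype_proportions) - 1) < 1e-8,
      "subtype_proportions must be a length-k simplex vector")
  chk(cfg$metastasis_gene_count >= 1 &&
        cfg$metastasis_gene_count <= cfg$n_regulators,
      "metastasis_gene_count must be in 1..n_regulators")
  chk(length(cfg$gene_baseline_range) == 2 &&
        diff(cfg$gene_baseline_range) >= 0, "bad gene_baseline_range")
  chk(pos1(cfg$gene_noise_sd), "gene_noise_sd must be positive")
  chk(is.numeric(cfg$activation_shift) && length(cfg$activation_shift) == 1 &&
        is.finite(cfg$activation_shift) && cfg$activation_shift >= 0,
      "activation_shift must be a non-negative number")
  chk(length(cfg$gleason_cutpoints) == 4 &&
        !is.unsorted(cfg$gleason_cutpoints), "gleason_cutpoints must be 4 ordered values")
  chk(length(cfg$gleason_shifts) == k, "gleason_shifts must have one entry per subtype")
  chk(length(cfg$rfs_hazard_ratios) == k && all(cfg$rfs_hazard_ratios > 0),
      "rfs_hazard_ratios must be k positive values")
  chk(length(cfg$os_hazard_ratios) == k && all(cfg$os_hazard_ratios > 0),
      "os_hazard_ratios must be k positive values")
  chk(pos1(cfg$baseline_hazard), "baseline_hazard must be positive")
  chk(pos1(cfg$censoring_horizon), "censoring_horizon must be positive")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Any field of [sim_config()] may be given; the rest keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    .stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

.sim_gene_ids <- function(cfg) {
  reg <- if (cfg$n_regulators == 21) m6a_regulators()
         else sprintf("REG%02d", seq_len(cfg$n_regulators))
  bg <- if (cfg$n_background_genes > 0)
          sprintf("BG%04d", seq_len(cfg$n_background_genes)) else character()
  list(regulators = reg, background = bg)
}

#' Simulate a synthetic prostate-cancer cohort
#'
#' Generative model (all expression on log2 scale): every gene has a baseline
#' mean drawn uniformly from `gene_baseline_range`; normal samples add
#' Gaussian noise with sd `gene_noise_sd`; tumors additionally gain
#' `tumor_normal_shift` on the designated regulators and `subtype_shift` on
#' the regulator block of their latent subtype (blocks partition the
#' regulator set across subtypes in gene order).  The last subtype is the
#' m6A-hyperactive one: its samples additionally gain a uniform
#' `activation_shift` over the whole regulator panel, so overall regulator
#' expression is highest there while the correlation-based cluster geometry
#' is unchanged.  The metastasis label of a
#' tumor is Bernoulli with logit equal to `metastasis_intercept` plus
#' `metastasis_beta` times the summed per-gene z-score of the metastasis gene
#' set (the last subtype's block), so the metastasis-prone tumors are mostly
#' those of the last subtype.  Gleason grade is drawn from an ordered-logit
#' model shifted per subtype; recurrence-free and overall survival are
#' exponential with per-subtype hazard multipliers and uniform censoring on
#' `[0, censoring_horizon]` independent of all covariates.
#'
#' Identical configurations (including `seed`) give identical cohorts.
#'
#' @param cfg A [sim_config()].
#' @return List with components `expression` (log2 gene-by-sample matrix),
#'   `clinical` (data frame per [validate_clinical()], plus the latent
#'   `subtype` for tumors), and `truth` (latent per-sample subtype, per-gene
#'   role table, and per-tumor metastasis probabilities).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_tumor = 30, n_normal = 10,
#'                                      n_background_genes = 20, seed = 7))
#' dim(cohort$expression)
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  ids <- .sim_gene_ids(cfg)
  genes <- c(ids$regulators, ids$background)
  G <- length(genes)
  k <- cfg$k_subtypes
  n_t <- cfg$n_tumor; n_n <- cfg$n_normal
  tumor_ids <- sprintf("T%04d", seq_len(n_t))
  normal_ids <- sprintf("N%04d", seq_len(n_n))

  ## gene roles
  nreg <- cfg$n_regulators
  block <- rep(seq_len(k), each = ceiling(nreg / k), length.out = nreg)
  shifted <- seq_len(nreg) <= cfg$n_tumor_normal_shifted
  met_pool <- c(which(block == k), which(block != k))
  met_idx <- met_pool[seq_len(cfg$metastasis_gene_count)]

  mu <- stats::runif(G, cfg$gene_baseline_range[1], cfg$gene_baseline_range[2])
  subtype <- sample.int(k, n_t, replace = TRUE, prob = cfg$subtype_proportions)

  X <- matrix(stats::rnorm(G * (n_t + n_n), mean = mu, sd = cfg$gene_noise_sd),
              nrow = G, ncol = n_t + n_n,
              dimnames = list(genes, c(tumor_ids, normal_ids)))
  tum <- seq_len(n_t)
  X[which(shifted), tum] <- X[which(shifted), tum] + cfg$tumor_normal_shift
  for (s in seq_len(k)) {
    cols <- tum[subtype == s]
    rows <- which(block == s)
    if (length(cols) && length(rows))
      X[rows, cols] <- X[rows, cols] + cfg$subtype_shift
  }
  ## the last subtype is the m6A-hyperactive one: a uniform activation offset
  ## over the whole regulator panel.  A per-sample constant cancels exactly in
  ## the Pearson correlation distance, so cluster geometry is untouched, but
  ## per-gene z-scores (score orientation, metastasis model) see it.
  hyper <- tum[subtype == k]
  if (cfg$activation_shift != 0 && length(hyper))
    X[seq_len(nreg), hyper] <- X[seq_len(nreg), hyper] + cfg$activation_shift

  ## metastasis: summed z over the metastasis gene set, tumors only
  zt <- X[met_idx, tum, drop = FALSE]
  zt <- (zt - rowMeans(zt)) / apply(zt, 1, stats::sd)
  lin <- cfg$metastasis_intercept + cfg$metastasis_beta * colSums(zt)
  p_met <- stats::plogis(lin)
  met <- stats::rbinom(n_t, 1, p_met)

  ## Gleason: ordered logit, per-subtype shift toward higher grade
  eta <- cfg$gleason_shifts[subtype]
  cum <- stats::plogis(outer(eta, cfg$gleason_cutpoints, function(e, c) c - e))
  pr <- cbind(cum, 1)[, c(1, 2, 3, 4, 5)] - cbind(0, cum)
  gleason <- vapply(seq_len(n_t),
                    function(i) sample(6:10, 1, prob = pmax(pr[i, ], 0)),
                    integer(1))

  surv_draw <- function(hr) {
    rate <- cfg$baseline_hazard * hr[subtype]
    ev_t <- stats::rexp(n_t, rate)
    cens <- stats::runif(n_t, 0, cfg$censoring_horizon)
    list(time = pmin(ev_t, cens), event = as.integer(ev_t <= cens))
  }
  rfs <- surv_draw(cfg$rfs_hazard_ratios)
  os <- surv_draw(cfg$os_hazard_ratios)

  clinical <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    tissue = rep(c("tumor", "normal"), c(n_t, n_n)),
    metastasis = c(ifelse(met == 1, "yes", "no"), rep("unknown", n_n)),
    gleason = c(gleason, rep(NA_integer_, n_n)),
    os_time = c(os$time, rep(NA_real_, n_n)),
    os_event = c(os$event, rep(NA_integer_, n_n)),
    rfs_time = c(rfs$time, rep(NA_real_, n_n)),
    rfs_event = c(rfs$event, rep(NA_integer_, n_n)),
    subtype = c(subtype, rep(NA_integer_, n_n)),
    stringsAsFactors = FALSE
  )

  gene_roles <- data.frame(
    gene_id = genes,
    is_regulator = c(rep(TRUE, nreg), rep(FALSE, cfg$n_background_genes)),
    tn_shifted = c(shifted, rep(FALSE, cfg$n_background_genes)),
    subtype_block = c(block, rep(NA_integer_, cfg$n_background_genes)),
    metastasis_gene = c(seq_len(nreg) %in% met_idx,
                        rep(FALSE, cfg$n_background_genes)),
    stringsAsFactors = FALSE
  )

  list(expression = X,
       clinical = validate_clinical(clinical),
       truth = list(subtype = stats::setNames(subtype, tumor_ids),
                    gene_roles = gene_roles,
                    metastasis_prob = stats::setNames(p_met, tumor_ids),
                    config = cfg))
}

#' Write a simulated cohort to a directory
#'
#' Writes `expr.tsv`, `clinical.tsv` and `truth.tsv` (per-sample latent
#' subtype and metastasis probability).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(cohort$expression, file.path(dir, "expr.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- data.frame(sample_id = names(cohort$truth$subtype),
                      subtype = cohort$truth$subtype,
                      metastasis_prob = cohort$truth$metastasis_prob)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$gene_roles, file.path(dir, "gene_roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
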