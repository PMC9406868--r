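#' Mann-Whitney U test (two-sided)
#'
#' U counts pairs `(x_i, y_j)` with `x_i > y_j`, plus half-ties (midrank
#' convention).  The two-sided p-value is computed by exact enumeration of
#' all rank assignments when `length(x) + length(y) <= 12` and there are no
#' ties, and otherwise by the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` and `p_value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) .stop("both vectors must be non-empty")
  if (anyNA(x) || anyNA(y)) .stop("missing values not allowed")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(c(x, y))
  if (N <= 12 && all(ties == 1)) {
    ## exact: all C(N, nx) assignments of ranks 1..N to the x-sample
    rank_sets <- utils::combn(N, nx)
    Us <- colSums(rank_sets) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    tie_term <- sum(ties^3 - ties)
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p_value = p)
}

#' Two-sample Student's t test
#'
#' Pooled-variance form by default; set `welch = TRUE` for the Welch
#' (unequal-variance) form.  Two-sided.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param welch Use Welch's variance estimate and degrees of freedom.
#' @return List with `t`, `p_value` and `df`.
#' @examples
#' students_t(c(0, 1), c(10, 11))   # |t| = 10 * sqrt(2)
#' @export
students_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) .stop("each group needs at least 2 values")
  if (anyNA(x) || anyNA(y)) .stop("missing values not allowed")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx <= 0 && vy <= 0) .stop("zero variance in both groups")
  if (welch) {
    se2x <- vx / nx; se2y <- vy / ny
    se <- sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}

#' Screen regulator genes between two sample groups
#'
#' Per-gene two-group tests over a regulator panel: the tumor-vs-normal
#' contrast uses the Mann-Whitney U test, the metastatic-vs-non-metastatic
#' contrast uses Student's t test (the conventional choices for these two
#' comparisons).  Samples with unknown labels are excluded, and no
#' multiple-testing correction is applied at this screening stage: a gene is
#' selected when its raw p-value is below `alpha`.
#'
#' @param m Expression matrix (log2 scale).
#' @param ann Clinical annotations (see [validate_clinical()]).
#' @param regulators Genes to screen; must be rows of `m`.
#' @param contrast `"tumor_vs_normal"` or `"metastatic_vs_not"`.
#' @param alpha Selection threshold on the raw p-value (default 0.05).
#' @param welch Use Welch's t for the metastasis contrast.
#' @return Data frame with one row per regulator: `gene_id`, `statistic`,
#'   `p_value`, `direction` (sign of the first-group minus second-group mean)
#'   and `selected`.
#' @export
screen_regulators <- function(m, ann,
                              regulators = intersect(m6a_regulators(), rownames(m)),
                              contrast = c("tumor_vs_normal", "metastatic_vs_not"),
                              alpha = 0.05, welch = FALSE) {
  contrast <- match.arg(contrast)
  check_cohort(m, ann)
  ann <- validate_clinical(ann)
  missing <- setdiff(regulators, rownames(m))
  if (length(missing))
    .stop("regulator(s) not in expression matrix: ", paste(missing, collapse = ", "))
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) .stop("alpha must be in [0, 1]")

  if (contrast == "tumor_vs_normal") {
    g1 <- ann$sample_id[ann$tissue == "tumor"]
    g2 <- ann$sample_id[ann$tissue == "normal"]
    who <- c("tumor", "normal")
  } else {
    tum <- ann[ann$tissue == "tumor" & ann$metastasis != "unknown", ]
    g1 <- tum$sample_id[tum$metastasis == "yes"]
    g2 <- tum$sample_id[tum$metastasis == "no"]
    who <- c("metastatic", "non-metastatic")
  }
  if (length(g1) == 0) .stop("contrast group empty: ", who[1])
  if (length(g2) == 0) .stop("contrast group empty: ", who[2])

  rows <- lapply(regulators, function(g) {
    x <- m[g, g1]; y <- m[g, g2]
    res <- if (contrast == "tumor_vs_normal") {
      mw <- mann_whitney_u(x, y); list(stat = mw$U, p = mw$p_value)
    } else {
      tt <- students_t(x, y, welch = welch); list(stat = tt$t, p = tt$p_value)
    }
    data.frame(gene_id = g, statistic = res$stat, p_value = res$p,
               direction = sign(mean(x) - mean(y)),
               selected = res$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
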