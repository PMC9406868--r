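# Independent brute-force oracles used to cross-check the implementation.
# Each one is written directly from the defining formula, never by calling
# the code path it checks.

# UPGMA by naive iterative merging: average linkage distance between two
# clusters is the mean of all inter-point distances.  Returns the partition
# (integer labels) after cutting at k clusters.
oracle_upgma_cut <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  cluster_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1), length(clusters))) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < best[1] - 1e-12) best <- c(dd, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  lab <- integer(n)
  for (c_i in seq_along(clusters)) lab[clusters[[c_i]]] <- c_i
  lab
}

# Silhouette width from the definition, pairwise loops only.
oracle_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(sapply(same, function(j) d[i, j]))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(sapply(which(labels == g), function(j) d[i, j])))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Kaplan-Meier product-limit estimate at each distinct event time.
oracle_km <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    at_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, survival = surv)
}

# Two-group log-rank chi-squared from per-event-time O-E and hypergeometric
# variance.
oracle_logrank2 <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  stopifnot(length(unique(g)) == 2)
  ev_times <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Tie-corrected rank statistic U / (n1 n0): probability that a random
# positive outranks a random negative, ties counting one half.
oracle_auc_u <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Spearman correlation as Pearson on midranks, from first principles.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
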