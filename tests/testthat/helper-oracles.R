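# Independent brute-force oracles and small fixture builders used across the
# suite.  Each oracle is written from the defining formula, independent of
# the package's implementation path.

# Pearson r from the textbook covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / sqrt(sum((x - mean(x))^2) / (n - 1)) / sqrt(sum((y - mean(y))^2) / (n - 1))
}

# Pooled-variance two-sample t statistic.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Cohen's D with pooled SD.
oracle_cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

# Benjamini-Hochberg step-up adjusted p-values, literal definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- prev
  }
  pmin(adj, 1)
}

# NMI by literal ranking: top-k of row i by |D|, ties by smaller partner
# index, mean of signed values.
oracle_nmi <- function(D, fraction = 0.10) {
  n <- nrow(D)
  k <- ceiling(fraction * (n - 1))
  sapply(seq_len(n), function(i) {
    partners <- setdiff(seq_len(n), i)
    vals <- D[i, partners]
    ord <- order(-abs(vals), partners)
    mean(vals[ord[seq_len(min(k, length(vals)))]])
  })
}

# Build a list of z-domain fc matrices where a single edge (1,2) takes the
# given per-animal values and everything else is 0.
z_mats_one_edge <- function(edge_vals, n_rois = 4) {
  lapply(edge_vals, function(v) {
    m <- matrix(0, n_rois, n_rois)
    m[1, 2] <- m[2, 1] <- v
    fc_matrix(m, "z")
  })
}

# Tiny z-domain matrices with iid noise entries (valid-by-construction).
random_z_mats <- function(n_animals, n_rois, sd = 0.1) {
  lapply(seq_len(n_animals), function(a) {
    m <- matrix(0, n_rois, n_rois)
    m[upper.tri(m)] <- rnorm(n_rois * (n_rois - 1) / 2, 0, sd)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    fc_matrix(m, "z")
  })
}

# "+" cross fixture: two perpendicular 25-px lines crossing at the centre.
cross_image <- function(n = 31) {
  img <- matrix(FALSE, n, n)
  mid <- (n + 1) %/% 2
  img[mid, 4:(n - 3)] <- TRUE
  img[4:(n - 3), mid] <- TRUE
  img
}
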