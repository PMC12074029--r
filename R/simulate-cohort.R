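#' Specification of a synthetic functional-connectivity cohort
#'
#' Describes a two-group rsfMRI-style cohort with planted edge effects of
#' known size.  Effects are planted in Fisher-z space: a planted edge with
#' target Cohen's D `d` separates the two group-mean z values by
#' `d * sigma_z`, where `sigma_z` is the between-animal spread of z at that
#' edge — so the target effect size is exact by construction in the z domain
#' the downstream t-test operates in.
#'
#' Animal-level variability is two-level: each animal's edge-wise z values
#' are drawn Gaussian around its group mean (sd `sigma_z` at planted edges,
#' `sigma_z_background` elsewhere), and the animal's time series are then
#' drawn multivariate normal matching that animal's correlation matrix.
#' Full-strength independent jitter on all edges of a 31-ROI matrix would
#' almost never be positive definite, hence the reduced background sd; see
#' the methods vignette.
#'
#' @param n_rois Number of ROIs (default 31).
#' @param n_volumes Time points per animal (default 300, i.e. 10 min at 1 s
#'   sampling).
#' @param n_group_a,n_group_b Animals per group (defaults 9 and 8; group A is
#'   the treated group).
#' @param baseline_corr Baseline pairwise correlation of all edges (default
#'   0.1).
#' @param planted_edges Data frame with columns `i`, `j` (1-based ROI
#'   indices, `i != j`) and `d` (target Cohen's D in z space); `NULL` for a
#'   null cohort.
#' @param behavior_coupling Data frame with columns `i`, `j`, `metric`,
#'   `target_corr` coupling a behavioural metric to an edge's animal-level
#'   latent z at the given correlation; `NULL` for none.
#' @param sigma_z Between-animal SD of Fisher z at planted edges (default
#'   0.15).
#' @param sigma_z_background Between-animal SD of z at all other edges
#'   (default 0.03).
#' @param seed Integer seed; all sub-generators derive child seeds from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rois = 31, n_volumes = 300, n_group_a = 9, n_group_b = 8,
                        baseline_corr = 0.1, planted_edges = NULL,
                        behavior_coupling = NULL, sigma_z = 0.15,
                        sigma_z_background = 0.03, seed = 1) {
  n_rois <- assert_count(n_rois, "n_rois", min = 2L)
  n_volumes <- assert_count(n_volumes, "n_volumes", min = 4L)
  n_group_a <- assert_count(n_group_a, "n_group_a")
  n_group_b <- assert_count(n_group_b, "n_group_b")
  assert_scalar_number(baseline_corr, "baseline_corr", lo = -1 + 1e-9, hi = 1 - 1e-9)
  assert_scalar_number(sigma_z, "sigma_z", lo = 0)
  assert_scalar_number(sigma_z_background, "sigma_z_background", lo = 0)
  planted_edges <- normalize_edge_df(planted_edges, n_rois, c("i", "j", "d"))
  if (!is.null(behavior_coupling)) {
    behavior_coupling <- normalize_edge_df(behavior_coupling, n_rois,
                                           c("i", "j", "metric", "target_corr"))
    if (any(abs(behavior_coupling$target_corr) >= 1)) {
      abort("behavior |target_corr| must be < 1")
    }
    if (anyDuplicated(behavior_coupling$metric)) {
      abort("behavior metric names must be unique")
    }
  }
  spec <- structure(
    list(n_rois = n_rois, n_volumes = n_volumes,
         n_group_a = n_group_a, n_group_b = n_group_b,
         baseline_corr = baseline_corr, planted_edges = planted_edges,
         behavior_coupling = behavior_coupling, sigma_z = sigma_z,
         sigma_z_background = sigma_z_background, seed = as.integer(seed)),
    class = "cohort_spec")
  # group-mean correlation matrices must be positive definite up front
  for (g in c("a", "b")) check_group_pd(spec, g)
  spec
}

normalize_edge_df <- function(df, n_rois, cols) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) return(NULL)
  df <- as_tibble(df)
  if (!all(cols %in% names(df))) {
    abort(paste0("edge table needs columns: ", paste(cols, collapse = ", ")))
  }
  df <- df[, cols]
  ii <- pmin(df$i, df$j); jj <- pmax(df$i, df$j)
  if (any(ii == jj) || any(ii < 1) || any(jj > n_rois)) {
    abort("edge indices must be distinct and within 1..n_rois")
  }
  df$i <- as.integer(ii); df$j <- as.integer(jj)
  if (anyDuplicated(df[, c("i", "j")])) abort("duplicate planted edges")
  df
}

# Group-mean z matrix for group "a" or "b".
group_mean_z <- function(spec, group) {
  z0 <- matrix(fisher_z(spec$baseline_corr), spec$n_rois, spec$n_rois)
  diag(z0) <- NA_real_
  pe <- spec$planted_edges
  if (!is.null(pe)) {
    half <- pe$d * spec$sigma_z / 2
    shift <- if (group == "a") half else -half
    for (k in seq_len(nrow(pe))) {
      z0[pe$i[k], pe$j[k]] <- z0[pe$i[k], pe$j[k]] + shift[k]
      z0[pe$j[k], pe$i[k]] <- z0[pe$i[k], pe$j[k]]
    }
  }
  z0
}

check_group_pd <- function(spec, group) {
  z <- group_mean_z(spec, group)
  r <- tanh(z); diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    msg <- sprintf("group %s mean correlation matrix is not positive definite",
                   toupper(group))
    pe <- spec$planted_edges
    if (!is.null(pe)) {
      k <- which.max(abs(tanh(z[cbind(pe$i, pe$j)])))
      msg <- sprintf("%s; offending planted edge (%d, %d)", msg, pe$i[k], pe$j[k])
    }
    abort(msg)
  }
  invisible(TRUE)
}

#' Simulate a two-group ROI time-series cohort with planted edge effects
#'
#' Generates per-animal ROI time-series matrices (default 9 + 8 animals, each
#' 300 x 31), group labels, behaviour scores coupled to chosen edges, and the
#' planted ground truth.  Empirical edge-wise Cohen's D computed by the
#' screening module converges to the planted targets as the number of animals
#' and volumes grows (the observed between-animal z spread is
#' `sqrt(sigma_z^2 + 1/(n_volumes - 3))`, slightly above `sigma_z`, so
#' finite-length recordings attenuate D a little; see the methods vignette).
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `ts` (named list of
#'   `n_volumes x n_rois` matrices), `animals` (tibble `animal_id`, `group`),
#'   `behavior` (tibble `animal_id`, `metric`, `value`), and `truth` (planted
#'   edges, latent per-animal z at planted edges, spec echo).
#' @examples
#' spec <- cohort_spec(n_rois = 8, n_volumes = 60, n_group_a = 3, n_group_b = 3,
#'                     planted_edges = data.frame(i = 1, j = 2, d = 1.5))
#' coh <- simulate_fc_cohort(spec)
#' names(coh$ts)
#' @export
simulate_fc_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_rois
  rois <- if (n == 31) load_atlas()$roi else paste0("ROI", seq_len(n))
  animals <- tibble(
    animal_id = c(paste0("A", seq_len(spec$n_group_a)),
                  paste0("B", seq_len(spec$n_group_b))),
    group = rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  )
  pe <- spec$planted_edges
  latent_z <- if (!is.null(pe)) {
    matrix(NA_real_, nrow(animals), nrow(pe),
           dimnames = list(animals$animal_id, paste0(pe$i, "-", pe$j)))
  }
  ts <- vector("list", nrow(animals))
  names(ts) <- animals$animal_id
  for (a in seq_len(nrow(animals))) {
    set.seed(derive_seed(spec$seed, paste0("animal_", animals$animal_id[a])))
    zg <- group_mean_z(spec, tolower(animals$group[a]))
    ok <- FALSE
    for (try in 1:25) {
      za <- zg + matrix(rnorm(n * n, 0, spec$sigma_z_background), n, n)
      za[lower.tri(za)] <- t(za)[lower.tri(za)]
      if (!is.null(pe)) {
        extra <- rnorm(nrow(pe), 0, sqrt(max(spec$sigma_z^2 - spec$sigma_z_background^2, 0)))
        za[cbind(pe$i, pe$j)] <- za[cbind(pe$i, pe$j)] + extra
        za[cbind(pe$j, pe$i)] <- za[cbind(pe$i, pe$j)]
      }
      ra <- tanh(za); diag(ra) <- 1
      ch <- tryCatch(chol(ra), error = function(e) NULL)
      if (!is.null(ch)) { ok <- TRUE; break }
    }
    if (!ok) {
      abort(sprintf("animal %s: correlation matrix not positive definite after 25 draws; reduce sigma_z or planted effects",
                    animals$animal_id[a]))
    }
    if (!is.null(pe)) latent_z[a, ] <- za[cbind(pe$i, pe$j)]
    x <- MASS::mvrnorm(spec$n_volumes, mu = rep(0, n), Sigma = ra)
    colnames(x) <- rois
    ts[[a]] <- x
  }
  behavior <- simulate_behavior(spec, animals, latent_z)
  structure(
    list(ts = ts, animals = animals, behavior = behavior,
         truth = list(planted_edges = pe, latent_z = latent_z,
                      sigma_z = spec$sigma_z, baseline_corr = spec$baseline_corr),
         spec = spec),
    class = "synthetic_cohort")
}

simulate_behavior <- function(spec, animals, latent_z) {
  bc <- spec$behavior_coupling
  if (is.null(bc)) {
    return(tibble(animal_id = character(), metric = character(), value = numeric()))
  }
  set.seed(derive_seed(spec$seed, "behavior"))
  out <- vector("list", nrow(bc))
  pe_key <- colnames(latent_z)
  for (k in seq_len(nrow(bc))) {
    key <- paste0(bc$i[k], "-", bc$j[k])
    zlat <- if (!is.null(latent_z) && key %in% pe_key) {
      latent_z[, key]
    } else {
      # edge not planted: couple to fresh animal-level latent noise
      rnorm(nrow(animals), 0, spec$sigma_z)
    }
    zs <- as.numeric(scale(zlat))
    rho <- bc$target_corr[k]
    raw <- rho * zs + sqrt(1 - rho^2) * rnorm(nrow(animals))
    out[[k]] <- tibble(animal_id = animals$animal_id, metric = bc$metric[k],
                       value = 60 + 20 * raw)
  }
  dplyr::bind_rows(out)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d + %d animals, %d x %d time series, %d planted edge(s)>\n",
              sum(x$animals$group == "A"), sum(x$animals$group == "B"),
              nrow(x$ts[[1]]), ncol(x$ts[[1]]),
              if (is.null(x$truth$planted_edges)) 0L else nrow(x$truth$planted_edges)))
  invisible(x)
}

#' Per-animal connectivity matrices of a synthetic cohort
#'
#' Convenience wrapper running [pearson_fc()] and optionally [fisher_z()] on
#' every animal of a cohort, split by group.
#'
#' @param cohort A `synthetic_cohort`.
#' @param domain `"z"` (default, ready for [edgewise_ttest()]) or `"r"`.
#' @return A list with elements `a` and `b`, each a list of [fc_matrix()]
#'   objects in the requested domain.
#' @export
cohort_fc <- function(cohort, domain = c("z", "r")) {
  domain <- match.arg(domain)
  one <- function(id) {
    grp <- cohort$animals$group[cohort$animals$animal_id == id]
    fc <- pearson_fc(cohort$ts[[id]], animal_id = id, group = grp)
    if (domain == "z") fisher_z(fc) else fc
  }
  ids <- split(cohort$animals$animal_id, cohort$animals$group)
  list(a = lapply(ids$A, one), b = lapply(ids$B, one))
}
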