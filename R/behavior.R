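#' Correlate edge connectivity with a behavioural metric
#'
#' Pearson correlation across animals between an edge's Fisher-z
#' connectivity and a behavioural score (e.g. wire-hanging time, beam
#' passing time), with a two-sided p-value and a verbal strength label.
#' Groups are pooled by default (the behavioural spread across both groups
#' drives the correlation); set `by_group = TRUE` to correlate within group.
#'
#' @param edge_z Data frame with columns `animal_id` and `z` (one row per
#'   animal), or a named numeric vector of z values.
#' @param behavior Data frame with columns `animal_id` and `value` (and
#'   optionally `group` when `by_group = TRUE`).
#' @param metric Metric name carried into the result.
#' @param by_group Correlate within each group separately (default `FALSE`).
#' @return A tibble with columns `metric`, `group`, `n`, `r`, `p`,
#'   `strength` (and the sign of r reported separately via `sign`).
#' @export
edge_behavior_correlation <- function(edge_z, behavior, metric = "behavior",
                                      by_group = FALSE) {
  if (!is.data.frame(edge_z)) {
    edge_z <- tibble(animal_id = names(edge_z), z = as.numeric(edge_z))
  }
  stopifnot(all(c("animal_id", "z") %in% names(edge_z)),
            all(c("animal_id", "value") %in% names(behavior)))
  orphans <- c(setdiff(edge_z$animal_id, behavior$animal_id),
               setdiff(behavior$animal_id, edge_z$animal_id))
  if (length(orphans)) {
    abort(paste0("animals without matched FC/behavior records: ",
                 paste(unique(orphans), collapse = ", ")))
  }
  merged <- dplyr::inner_join(edge_z, behavior, by = "animal_id")
  groups <- if (by_group) split(merged, merged$group) else list(pooled = merged)
  purrr::imap_dfr(groups, function(df, g) {
    if (nrow(df) < 4L) abort("need at least 4 paired observations")
    ct <- cor.test(df$z, df$value)
    r <- unname(ct$estimate)
    tibble(metric = metric, group = g, n = nrow(df),
           r = r, p = ct$p.value,
           sign = if (r >= 0) "positive" else "negative",
           strength = classify_strength(r))
  })
}

#' Verbal correlation-strength label (Evans scale)
#'
#' Maps |r| to the conventional Evans (1996) adjectives: below 0.2
#' negligible, 0.2-0.39 weak, 0.4-0.59 moderate, 0.6-0.79 strong, 0.8 and
#' above very strong.  The sign is reported separately by the caller.
#'
#' @param r Correlation value(s) in \[-1, 1\].
#' @param bands Named numeric vector of lower |r| bounds defining the scale.
#' @return Character label(s).
#' @examples
#' classify_strength(c(0, -0.45, 0.75))
#' @export
classify_strength <- function(r, bands = c(negligible = 0, weak = 0.2, moderate = 0.4,
                                           strong = 0.6, `very strong` = 0.8)) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) abort("|r| must be <= 1")
  names(bands)[findInterval(abs(r), bands)]
}
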