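#' Circular-equivalent diameter from a segmented area
#'
#' Diameter of the circle with the same area as a segmented contour:
#' \eqn{d = 2\sqrt{A/\pi}}.
#'
#' @param area Area(s) in nm^2, non-negative.
#' @return Diameter(s) in nm.
#' @examples
#' circ_equiv_diameter(pi)  # 2
#' @export
circ_equiv_diameter <- function(area) {
  if (any(area < 0, na.rm = TRUE)) abort("area must be non-negative")
  2 * sqrt(area / pi)
}

#' g-ratio from inner and outer diameters
#'
#' \eqn{g = d_{inner} / d_{outer}}, the inner (axonal) diameter over the
#' outer (fiber including myelin) diameter; values lie in (0, 1) and lower g
#' means thicker myelin.  Rows violating `0 < inner < outer` are rejected
#' with the count reported.
#'
#' @param d_inner,d_outer Diameters in nm.
#' @return g values; invalid rows are `NA` with a warning reporting how many
#'   were rejected.
#' @export
g_ratio <- function(d_inner, d_outer) {
  bad <- !(d_inner > 0 & d_inner < d_outer)
  g <- ifelse(bad, NA_real_, d_inner / d_outer)
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("%d row(s) rejected: need 0 < inner < outer", sum(bad, na.rm = TRUE)))
  }
  g
}

# Normalise an axon table: accept areas (inner_area_nm2/outer_area_nm2) or
# diameters (inner_nm/outer_nm), never mixed per row; returns diameters + g.
prepare_axons <- function(table) {
  table <- as_tibble(table)
  has_d <- all(c("inner_nm", "outer_nm") %in% names(table))
  has_a <- all(c("inner_area_nm2", "outer_area_nm2") %in% names(table))
  if (has_a && !has_d) {
    table$inner_nm <- circ_equiv_diameter(table$inner_area_nm2)
    table$outer_nm <- circ_equiv_diameter(table$outer_area_nm2)
  } else if (!has_d) {
    abort("axon table needs inner_nm/outer_nm or inner_area_nm2/outer_area_nm2 columns")
  }
  if (!"group" %in% names(table)) abort("axon table needs a `group` column")
  table$g <- g_ratio(table$inner_nm, table$outer_nm)
  table
}

#' Stratified g-ratio group comparison
#'
#' Stratifies axons on inner diameter at `threshold_nm` (default 400 nm) and
#' performs a two-sample t-test on g between the two groups within each
#' stratum — the analysis that detects selective myelin thickening of
#' small-calibre axons.
#'
#' @param table Axon table with columns `group` (exactly 2 levels) and
#'   either diameters (`inner_nm`, `outer_nm`) or areas (`inner_area_nm2`,
#'   `outer_area_nm2`).
#' @param threshold_nm Stratification threshold on inner diameter (nm).
#' @param treated Level of `group` treated as the intervention arm; the
#'   reported `delta` is treated minus the other level.  Defaults to the
#'   level `"treated"` when present, else the first level.
#' @return A tibble of class `gratio_result` with one row per populated
#'   stratum: `stratum` (`"below"`/`"at_or_above"`), per-group `n`, `mean`,
#'   `sd`, plus `delta`, `t`, `p`.  Strata with fewer than 2 axons in either
#'   group are skipped with a warning.
#' @export
stratified_compare <- function(table, threshold_nm = 400, treated = NULL) {
  tab <- prepare_axons(table)
  tab <- tab[!is.na(tab$g), ]
  lv <- unique(tab$group)
  if (length(lv) != 2L) abort("need exactly 2 groups")
  treated <- treated %||% if ("treated" %in% lv) "treated" else lv[1]
  other <- setdiff(lv, treated)
  tab$stratum <- ifelse(tab$inner_nm < threshold_nm, "below", "at_or_above")
  rows <- list()
  for (s in c("below", "at_or_above")) {
    g1 <- tab$g[tab$stratum == s & tab$group == treated]
    g2 <- tab$g[tab$stratum == s & tab$group == other]
    if (length(g1) == 0L && length(g2) == 0L) next
    if (length(g1) < 2L || length(g2) < 2L) {
      warn(sprintf("stratum '%s' skipped: fewer than 2 axons in a group", s))
      next
    }
    tt <- t.test(g1, g2, var.equal = TRUE)
    rows[[s]] <- tibble(
      stratum = s, threshold_nm = threshold_nm,
      n_treated = length(g1), n_control = length(g2),
      mean_treated = mean(g1), mean_control = mean(g2),
      sd_treated = sd(g1), sd_control = sd(g2),
      delta = mean(g1) - mean(g2),
      t = unname(tt$statistic), p = tt$p.value)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("gratio_result", class(out)),
            treated = treated, control = other)
}

#' @method glance gratio_result
#' @export
glance.gratio_result <- function(x, ...) {
  tibble(n_strata = nrow(x), treated = attr(x, "treated"),
         min_p = if (nrow(x)) min(x$p) else NA_real_)
}

#' Linear g-ratio vs diameter trend
#'
#' Ordinary least squares of g on inner diameter within one group,
#' summarising how myelin relative thickness varies with axon calibre.
#'
#' @param table Axon table (see [stratified_compare()]).
#' @param group Optional group level to fit; default fits all rows given.
#' @return A tibble with `group`, `slope` (per nm), `intercept`, `r_squared`,
#'   `n`.
#' @export
gratio_diameter_trend <- function(table, group = NULL) {
  tab <- prepare_axons(table)
  if (!is.null(group)) tab <- tab[tab$group == group, ]
  tab <- tab[!is.na(tab$g), ]
  if (nrow(tab) < 3L) abort("need at least 3 axons")
  if (var(tab$inner_nm) == 0) abort("zero diameter variance")
  fit <- lm(g ~ inner_nm, data = tab)
  tibble(group = group %||% "all",
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n = nrow(tab))
}
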