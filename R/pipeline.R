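#' Run the multi-parameter screening pipeline from a configuration
#'
#' Orchestrates the stages in dependency order — connectivity matrices,
#' edge-wise significance and effect-size screening, Node Modulation Index,
#' behaviour correlation of screened edges, EMG band comparison, g-ratio
#' morphometry, fiber skeleton metrics — from a single configuration.
#' Partial configurations run partial pipelines; a stage failure aborts its
#' dependents and is recorded in the report, while independent stages still
#' run.  All numeric outputs are regenerable from the config plus seed; the
#' provenance block carries the config hash and seed.
#'
#' @param config A named list or path to a YAML file.  Recognised blocks:
#'   \describe{
#'     \item{fc}{`ts_dir`: directory with `groups.tsv` and one
#'       `<animal_id>.tsv` time-series file per animal (see
#'       [write_cohort()]); optional `average_domain` (`"z"`/`"r"`).}
#'     \item{screen}{passed to [screen_config()] (`alpha`, `correction`,
#'       `d_threshold`, `test_variant`).}
#'     \item{nmi}{`fraction` (default 0.1), `absolute` (default `FALSE`).}
#'     \item{behavior}{`file`: long table `animal_id`, `metric`, `value`;
#'       correlated against every edge selected by the screen.}
#'     \item{emg}{`dir` with one recording per animal named
#'       `<animal>__<A|B>.tsv`, plus `fs` (default 1000); optional `bands`
#'       data frame, `notch` (default `TRUE`).}
#'     \item{myelin}{`file`: axon table; optional `threshold_nm`
#'       (default 400).}
#'     \item{fibers}{`dir` of PNG/TIFF images; optional `pixel_size_um`.}
#'     \item{out_dir}{if given, tables are written there as delimited text.}
#'     \item{seed}{recorded in provenance (default 1).}
#'   }
#' @return A list of class `run_report`: stage results (`fc`, `edges`,
#'   `screen`, `nmi`, `behavior`, `emg`, `myelin`, `fibers`), `errors`
#'   (named character vector of failed stages), and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  report <- list(errors = c())
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) {
      write.table(tbl, file.path(out_dir, paste0(name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[name] <<- conditionMessage(e)
      NULL
    })
  }

  scfg <- do.call(screen_config, config$screen %||% list())

  # --- FC -> screen -> NMI -> behavior chain -------------------------------
  if (!is.null(config$fc)) {
    cohort <- try_stage("fc", read_cohort(config$fc$ts_dir))
    if (!is.null(cohort)) {
      fcz <- try_stage("fc", cohort_fc(cohort, "z"))
      fcr <- cohort_fc(cohort, "r")
      report$fc <- list(
        group_mean_a = group_mean_fc(fcr$a, config$fc$average_domain %||% "z", group = "A"),
        group_mean_b = group_mean_fc(fcr$b, config$fc$average_domain %||% "z", group = "B"))
      edges <- try_stage("screen", edgewise_ttest(fcz$a, fcz$b, scfg))
      if (!is.null(edges)) {
        report$edges <- edges
        report$screen <- screen_edges(edges, scfg)
        emit(edges, "edge_results")
        emit(export_chord_edgelist(report$screen), "chord_edges")
        D <- cohens_d_matrix(fcz$a, fcz$b)
        nmi_cfg <- config$nmi %||% list()
        report$nmi <- try_stage("nmi", node_modulation_index(
          D, fraction = nmi_cfg$fraction %||% 0.10,
          absolute = nmi_cfg$absolute %||% FALSE))
        if (!is.null(report$nmi)) emit(tidy(report$nmi), "nmi")
        if (!is.null(config$behavior)) {
          report$behavior <- try_stage("behavior", {
            btab <- as_tibble(read.delim(config$behavior$file))
            pick <- report$screen$significance
            zmat <- rbind(stack_edges(fcz$a), stack_edges(fcz$b))
            ids <- c(vapply(fcz$a, attr, "", "animal_id"),
                     vapply(fcz$b, attr, "", "animal_id"))
            eidx <- edge_index(attr(edges, "n_rois"))
            purrr::pmap_dfr(pick[, c("i", "j", "roi_i", "roi_j")], function(i, j, roi_i, roi_j) {
              col <- which(eidx$i == i & eidx$j == j)
              ez <- tibble(animal_id = ids, z = zmat[, col])
              purrr::map_dfr(split(btab, btab$metric), function(bm) {
                edge_behavior_correlation(ez, bm, metric = bm$metric[1])
              }) |>
                dplyr::mutate(roi_i = roi_i, roi_j = roi_j, .before = 1)
            })
          })
          if (!is.null(report$behavior)) emit(report$behavior, "behavior_correlations")
        }
      }
    }
  } else if (!is.null(config$behavior)) {
    report$errors["behavior"] <- "behavior stage skipped: fc stage not configured"
  }

  # --- EMG -----------------------------------------------------------------
  if (!is.null(config$emg)) {
    report$emg <- try_stage("emg", {
      fs <- config$emg$fs %||% 1000
      files <- list.files(config$emg$dir, pattern = "\\.tsv$", full.names = TRUE)
      if (!length(files)) abort("no EMG recordings found")
      parse1 <- function(f) {
        nm <- sub("\\.tsv$", "", basename(f))
        parts <- strsplit(nm, "__", fixed = TRUE)[[1]]
        rec <- read_emg(f, fs, animal_id = parts[1],
                        group = if (length(parts) > 1) parts[2] else "A")
        if (isTRUE(config$emg$notch %||% TRUE)) rec <- notch_filter(rec) else rec
      }
      recs <- lapply(files, parse1)
      grp <- vapply(recs, function(r) r$group, "")
      bands <- if (!is.null(config$emg$bands)) as.data.frame(config$emg$bands) else
        data.frame(lo = c(20, 20, 50), hi = c(150, 50, 150))
      group_band_compare(recs[grp == "A"], recs[grp == "B"], bands = bands)
    })
    if (!is.null(report$emg)) emit(report$emg, "emg_band_comparison")
  }

  # --- myelin morphometry --------------------------------------------------
  if (!is.null(config$myelin)) {
    report$myelin <- try_stage("myelin", {
      tab <- read_axon_table(config$myelin$file)
      thr <- config$myelin$threshold_nm %||% 400
      list(strata = stratified_compare(tab, threshold_nm = thr),
           trends = purrr::map_dfr(unique(tab$group),
                                   function(g) gratio_diameter_trend(tab, g)))
    })
    if (!is.null(report$myelin)) {
      emit(report$myelin$strata, "gratio_strata")
      emit(report$myelin$trends, "gratio_trends")
    }
  }

  # --- fiber skeletons -----------------------------------------------------
  if (!is.null(config$fibers)) {
    report$fibers <- try_stage("fibers", {
      files <- list.files(config$fibers$dir, pattern = "\\.(png|tiff?)$",
                          full.names = TRUE, ignore.case = TRUE)
      if (!length(files)) abort("no fiber images found")
      px <- config$fibers$pixel_size_um %||% 1
      purrr::map_dfr(files, function(f) {
        sm <- skeleton_metrics(binarize(read_fiber_image(f)), pixel_size_um = px)
        tibble(image = basename(f), total_length_um = sm$total_length_um,
               n_branch_points = sm$n_branch_points,
               n_nodes = nrow(sm$graph$nodes))
      })
    })
    if (!is.null(report$fibers)) emit(report$fibers, "fiber_metrics")
  }

  report$provenance <- list(
    config_hash = rlang::hash(config),
    seed = config$seed %||% 1L,
    package_version = as.character(utils::packageVersion("fcscreen")))
  if (length(report$errors)) {
    warn(paste0("stages failed: ", paste(names(report$errors), collapse = ", ")))
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  done <- setdiff(names(x), c("errors", "provenance"))
  cat("<run_report>\n  stages completed:", paste(done, collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("  stages failed:", paste(names(x$errors), collapse = ", "), "\n")
  }
  cat("  config hash:", x$provenance$config_hash, "\n")
  invisible(x)
}
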