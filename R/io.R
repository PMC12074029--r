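# Delimited-text readers/writers for every exchange format the pipeline
# uses.  All tables are tab-separated with a header row.

#' Read and write ROI time-series tables
#'
#' One file per animal: a header row of ROI names, one row per volume.
#'
#' @param file Path.
#' @param ts Numeric matrix (volumes x ROIs) with ROI column names.
#' @return `read_timeseries()` returns the numeric matrix.
#' @export
read_timeseries <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  as_ts_matrix(df)
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, file) {
  write.table(as.data.frame(ts), file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read and write square connectivity matrices
#'
#' Delimited square tables with ROI names as header row and first column.
#'
#' @param file Path.
#' @param fc An [fc_matrix()].
#' @return `read_fc_matrix()` returns an [fc_matrix()].
#' @param domain Domain tag used when reading (`"r"` or `"z"`).
#' @export
read_fc_matrix <- function(file, domain = "r") {
  df <- read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  fc_matrix(m, domain)
}

#' @rdname read_fc_matrix
#' @export
write_fc_matrix <- function(fc, file) {
  df <- data.frame(roi = rownames(fc) %||% paste0("ROI", seq_len(nrow(fc))),
                   unclass(fc), check.names = FALSE)
  colnames(df) <- c("roi", df$roi)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a synthetic cohort to a directory
#'
#' One time-series file per animal (`<animal_id>.tsv`), a group-label table
#' (`groups.tsv`), a behaviour table (`behavior.tsv`) and the planted ground
#' truth (`truth.json`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$ts)) {
    write_timeseries(cohort$ts[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  write.table(cohort$animals, file.path(dir, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$latent_z <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `groups.tsv` and one `<animal_id>.tsv`
#'   per animal (optionally `behavior.tsv`).
#' @return A list with `ts`, `animals`, `behavior` (a `synthetic_cohort`
#'   minus ground truth; usable by [cohort_fc()]).
#' @export
read_cohort <- function(dir) {
  gfile <- file.path(dir, "groups.tsv")
  if (!file.exists(gfile)) {
    abort(sprintf("no cohort found at '%s' (groups.tsv missing)", dir))
  }
  animals <- as_tibble(read.delim(gfile))
  ts <- lapply(animals$animal_id, function(id) {
    read_timeseries(file.path(dir, paste0(id, ".tsv")))
  })
  names(ts) <- animals$animal_id
  bfile <- file.path(dir, "behavior.tsv")
  behavior <- if (file.exists(bfile)) as_tibble(read.delim(bfile)) else
    tibble(animal_id = character(), metric = character(), value = numeric())
  structure(list(ts = ts, animals = animals, behavior = behavior,
                 truth = NULL, spec = NULL),
            class = "synthetic_cohort")
}

#' Read a delimited EMG recording
#'
#' Expects columns `value` and optionally `state` (wake/sleep); sampling
#' rate is supplied by the caller.
#'
#' @param file Path.
#' @param fs Sampling rate in Hz.
#' @param animal_id,group Optional tags.
#' @return A [signal_recording()].
#' @export
read_emg <- function(file, fs, animal_id = NULL, group = NULL) {
  df <- read.delim(file)
  stopifnot("value" %in% names(df))
  signal_recording(df$value, fs, state = df$state %||% NULL,
                   animal_id = animal_id, group = group)
}

#' @rdname read_emg
#' @param rec A [signal_recording()] to write (columns `value`, `state`).
#' @export
write_emg <- function(rec, file) {
  write.table(data.frame(value = rec$samples, state = rec$state), file,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an axon measurement table
#'
#' Delimited text with a `group` column plus inner/outer diameters
#' (`inner_nm`, `outer_nm`) or areas (`inner_area_nm2`, `outer_area_nm2`).
#'
#' @param file Path.
#' @return A tibble.
#' @export
read_axon_table <- function(file) {
  as_tibble(read.delim(file))
}

#' Export a chord-diagram edge list from a screen
#'
#' One row per selected edge: `source`, `target`, `direction`
#' (enhanced/reduced), `weight` (|D|), `p_adj` — the format chord-diagram
#' plotters consume.
#'
#' @param screened A `screen_sets` (uses the significance set) or an edge
#'   tibble with columns `roi_i`, `roi_j`, `direction`, `d`, `p_adj`.
#' @param file Optional path to write to.
#' @param set Which screened set to export when given `screen_sets`
#'   (`"significance"`, `"effect"` or `"intersection"`).
#' @return The edge-list tibble (written to `file` if given).
#' @export
export_chord_edgelist <- function(screened, file = NULL,
                                  set = c("significance", "effect", "intersection")) {
  set <- match.arg(set)
  edges <- if (inherits(screened, "screen_sets")) screened[[set]] else screened
  out <- tibble(source = edges$roi_i, target = edges$roi_j,
                direction = edges$direction,
                weight = abs(edges$d), p_adj = edges$p_adj)
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
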