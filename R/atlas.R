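#' ROI sets: ordered region labels with a major-division hierarchy
#'
#' An `roi_set` holds the ordered ROI labels used to index connectivity
#' matrices, plus a mapping of every ROI to exactly one major anatomical
#' division.  The package ships a 31-subregion / 9-division mouse hierarchy
#' (`load_atlas()`), the granularity at which whole-brain ipsilateral
#' correlation matrices are built.
#'
#' @param names Character vector of unique ROI labels, in matrix order.
#' @param major_region Character vector (same length) giving each ROI's major
#'   division.
#' @return An object of class `roi_set`: a tibble with columns `roi` and
#'   `major_region`, ordered as the matrices are.
#' @examples
#' atlas <- load_atlas()
#' nrow(atlas)                    # 31
#' dplyr::n_distinct(atlas$major_region)  # 9
#' @export
roi_set <- function(names, major_region) {
  if (anyDuplicated(names)) abort("ROI names must be unique")
  if (length(names) != length(major_region) || anyNA(major_region)) {
    abort("every ROI must map to exactly one major division")
  }
  out <- tibble(roi = as.character(names), major_region = as.character(major_region))
  class(out) <- c("roi_set", class(out))
  out
}

#' @rdname roi_set
#' @param file Path to a YAML hierarchy file (`divisions: {division: [roi, ...]}`).
#'   Defaults to the shipped 31-ROI mouse atlas.
#' @export
load_atlas <- function(file = system.file("extdata", "atlas_31roi.yaml",
                                          package = "fcscreen")) {
  spec <- yaml::read_yaml(file)
  divs <- spec$divisions
  roi_set(
    names = unlist(divs, use.names = FALSE),
    major_region = rep(names(divs), lengths(divs))
  )
}
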