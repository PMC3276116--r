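#' Haldane map function: genetic distance to recombination fraction
#'
#' Converts a genetic distance in centiMorgans to the probability of an odd
#' number of crossovers in the interval, assuming crossovers occur as a
#' Poisson process with no interference:
#' \deqn{r = \tfrac{1}{2}\left(1 - e^{-2d/100}\right)}
#' with `d` in cM. The no-interference assumption is what makes line origin
#' along a chromosome a Markov process, so this is the only map function the
#' inference engine supports.
#'
#' @param d Numeric vector of genetic distances in cM; must be non-negative.
#' @return Recombination fractions in `[0, 0.5)`, same length as `d`.
#' @examples
#' haldane_r(c(0, 1, 50))
#' @export
haldane_r <- function(d) {
  if (!is.numeric(d)) stop("`d` must be numeric", call. = FALSE)
  if (any(is.na(d)) || any(d < 0)) {
    stop("genetic distances must be non-negative and non-missing", call. = FALSE)
  }
  0.5 * (1 - exp(-2 * d / 100))
}

#' Interpolate a genetic position between two physical anchors
#'
#' Linear interpolation of genetic position (cM) between two markers with
#' known physical (bp) and genetic coordinates, assuming a locally linear
#' relationship between physical and genetic distance. Extrapolation outside
#' the anchor interval is refused.
#'
#' @param query_bp Physical coordinate(s) to interpolate at.
#' @param left_anchor,right_anchor Length-2 numeric vectors `c(bp, cM)`;
#'   `left_anchor` must precede `right_anchor` physically.
#' @return Genetic position(s) in cM.
#' @examples
#' interpolate_position(5e5, c(0, 0), c(1e6, 10))
#' @export
interpolate_position <- function(query_bp, left_anchor, right_anchor) {
  stopifnot(length(left_anchor) == 2, length(right_anchor) == 2)
  if (left_anchor[1] >= right_anchor[1]) {
    stop("left anchor must be physically before right anchor", call. = FALSE)
  }
  if (any(query_bp < left_anchor[1]) || any(query_bp > right_anchor[1])) {
    stop("query position outside anchor interval; extrapolation is not defined",
         call. = FALSE)
  }
  frac <- (query_bp - left_anchor[1]) / (right_anchor[1] - left_anchor[1])
  left_anchor[2] + frac * (right_anchor[2] - left_anchor[2])
}

#' Resolve tied marker positions by fanning them out over a 0.1 cM window
#'
#' Markers mapped to an identical genetic position `x` (common when positions
#' are taken from a consensus linkage map) are re-spaced evenly from
#' `x - 0.05` to `x + 0.049` cM so that every inter-marker distance is
#' strictly positive before any HMM computation. Runs of a single marker are
#' left untouched.
#'
#' @param positions_cM Non-decreasing numeric vector of marker positions (cM).
#' @return Strictly increasing numeric vector, same length and order.
#' @examples
#' space_tied_markers(c(5, 10, 10, 12))
#' @export
space_tied_markers <- function(positions_cM) {
  if (is.unsorted(positions_cM)) {
    stop("positions must be non-decreasing", call. = FALSE)
  }
  runs <- rle(positions_cM)
  out <- unlist(lapply(seq_along(runs$values), function(k) {
    n <- runs$lengths[k]
    x <- runs$values[k]
    if (n == 1L) x else seq(x - 0.05, x + 0.049, length.out = n)
  }), use.names = FALSE)
  bad <- which(diff(out) <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "tie spacing breaks monotonicity at marker index %s: adjacent distinct positions are closer than the 0.1 cM fan-out",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Construct a genetic map
#'
#' Builds a validated single-chromosome marker map. Tied positions are
#' resolved with [space_tied_markers()]; the chromosome length defaults to
#' the last marker position (the inference grid spans `[0, length_cM]`).
#'
#' @param marker_id Character vector of unique marker names, in map order.
#' @param position_cM Non-decreasing genetic positions (cM).
#' @param chromosome Chromosome label (single value).
#' @param length_cM Chromosome length in cM; must be at least the last marker
#'   position. Defaults to the last marker position.
#' @return A tibble of class `lo_map` with columns `marker_id`, `chromosome`,
#'   `position_cM`, and a `length_cM` attribute.
#' @examples
#' genetic_map(c("m1", "m2", "m3"), c(0, 10, 10))
#' @export
genetic_map <- function(marker_id, position_cM, chromosome = "1",
                        length_cM = NULL) {
  marker_id <- as.character(marker_id)
  if (anyDuplicated(marker_id)) {
    stop("duplicated marker ids: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(marker_id) != length(position_cM)) {
    stop("marker_id and position_cM lengths differ", call. = FALSE)
  }
  if (length(position_cM) == 0) stop("empty map", call. = FALSE)
  if (any(position_cM < 0)) stop("negative map positions", call. = FALSE)
  position_cM <- space_tied_markers(position_cM)
  if (is.null(length_cM)) length_cM <- position_cM[length(position_cM)]
  if (length_cM < position_cM[length(position_cM)]) {
    stop("length_cM is smaller than the last marker position", call. = FALSE)
  }
  out <- tibble::tibble(
    marker_id = marker_id,
    chromosome = as.character(chromosome),
    position_cM = position_cM
  )
  attr(out, "length_cM") <- length_cM
  class(out) <- c("lo_map", class(out))
  out
}

#' @rdname genetic_map
#' @param map An `lo_map` object.
#' @export
map_length <- function(map) {
  l <- attr(map, "length_cM")
  if (is.null(l)) max(map$position_cM) else l
}

#' Read / write a marker map
#'
#' The map file is tab-separated with a header and columns
#' `marker_id  chromosome  position_cM` (an optional `position_bp` column is
#' carried through for interpolation workflows). Only single-chromosome maps
#' are accepted: one chromosome is the unit of computation.
#'
#' @param path File path.
#' @param length_cM Optional chromosome length (cM); defaults to the last
#'   marker position.
#' @return For `read_map()`, an `lo_map` tibble.
#' @export
read_map <- function(path, length_cM = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    chromosome = readr::col_character(),
    position_cM = readr::col_double(),
    .default = readr::col_double()
  ))
  need <- c("marker_id", "chromosome", "position_cM")
  if (!all(need %in% names(df))) {
    stop("map file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(df$chromosome)) != 1) {
    stop("map file contains more than one chromosome; analyse one at a time",
         call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$position_cM)
  m <- genetic_map(df$marker_id, df$position_cM, df$chromosome[1], length_cM)
  if ("position_bp" %in% names(df)) m$position_bp <- df$position_bp
  m
}

#' @rdname read_map
#' @param map An `lo_map` object to serialize.
#' @export
write_map <- function(map, path) {
  readr::write_tsv(as.data.frame(map), path)
  invisible(path)
}
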