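#' Construct a vertebral series
#'
#' A `vertebral_series` is the central container of the package: an ordered,
#' specimen-level collection of caudal vertebra measurements. Each record holds
#' the caudal position index (Ca1 = 1, increasing towards the tail tip), the
#' centrum length and the total height (centrum plus neural spine) in
#' centimetres, and flags saying whether the element is preserved or was
#' imputed. Positions without measurements are tracked in `missing_positions`.
#'
#' @param records data frame with columns `position` (integer, >= 1),
#'   `length_cm`, `height_cm` (positive reals, cm), and optionally `preserved`
#'   (logical, default `TRUE`), `imputed` (logical, default `FALSE`) and `note`
#'   (character). Rows are sorted by position.
#' @param specimen_id character scalar identifying the specimen.
#' @param taxon character scalar, taxon name.
#' @param expected_count integer or `NA`; the anatomically expected number of
#'   caudal vertebrae (may legitimately differ from the number preserved).
#' @param missing_positions integer vector of positions known to lack an
#'   element. Must be disjoint from the preserved record positions.
#'
#' @return An object of class `vertebral_series`: a list with elements
#'   `specimen_id`, `taxon`, `expected_count`, `records` (data frame) and
#'   `missing_positions`.
#' @seealso [read_measurements()], [impute_missing()], [total_length()],
#'   [tail_profile()]
#' @export
#' @examples
#' vs <- vertebral_series(
#'   data.frame(position = 1:3, length_cm = c(10, 9, 8),
#'              height_cm = c(25, 20, 15)),
#'   specimen_id = "demo"
#' )
#' total_length(vs)
vertebral_series <- function(records,
                             specimen_id = "unnamed",
                             taxon = NA_character_,
                             expected_count = NA_integer_,
                             missing_positions = integer()) {
  stopifnot(is.data.frame(records))
  required <- c("position", "length_cm", "height_cm")
  absent <- setdiff(required, names(records))
  if (length(absent) > 0L) {
    stop("records lacks required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(records$preserved)) records$preserved <- TRUE
  if (is.null(records$imputed))   records$imputed <- FALSE
  if (is.null(records$note))      records$note <- NA_character_
  records <- records[c("position", "length_cm", "height_cm",
                       "preserved", "imputed", "note")]
  records$position <- as.integer(records$position)
  records <- records[order(records$position), , drop = FALSE]
  rownames(records) <- NULL

  obj <- structure(
    list(specimen_id = as.character(specimen_id),
         taxon = as.character(taxon),
         expected_count = as.integer(expected_count),
         records = records,
         missing_positions = sort(as.integer(missing_positions))),
    class = "vertebral_series")
  validate_vertebral_series(obj)
  obj
}

#' @keywords internal
validate_vertebral_series <- function(x) {
  r <- x$records
  if (any(r$position < 1L)) {
    stop("positions must be >= 1 (Ca1 is the first caudal)", call. = FALSE)
  }
  if (anyDuplicated(r$position)) {
    dup <- unique(r$position[duplicated(r$position)])
    stop("duplicate position(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  measured <- r$preserved | r$imputed
  bad <- measured & (!is.finite(r$length_cm) | r$length_cm <= 0 |
                     !is.finite(r$height_cm) | r$height_cm <= 0)
  if (any(bad)) {
    stop("non-positive or missing measurement at position(s): ",
         paste(r$position[bad], collapse = ", "), call. = FALSE)
  }
  if (any(r$imputed & r$preserved)) {
    stop("a record cannot be both preserved and imputed", call. = FALSE)
  }
  clash <- intersect(x$missing_positions, r$position[r$preserved])
  if (length(clash) > 0L) {
    stop("missing_positions overlap preserved records at: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.vertebral_series <- function(x, ...) {
  r <- x$records
  cat("Vertebral series: ", x$specimen_id,
      if (!is.na(x$taxon)) paste0(" (", x$taxon, ")"), "\n", sep = "")
  cat("  records: ", nrow(r),
      " (", sum(r$preserved), " preserved, ", sum(r$imputed), " imputed)\n",
      sep = "")
  if (!is.na(x$expected_count)) {
    cat("  expected caudal count: ", x$expected_count, "\n", sep = "")
  }
  if (length(x$missing_positions) > 0L) {
    cat("  missing positions: Ca",
        paste(x$missing_positions, collapse = ", Ca"), "\n", sep = "")
  }
  cat("  summed centrum length (preserved only): ",
      format(total_length(x, include_imputed = FALSE)), " cm\n", sep = "")
  invisible(x)
}

#' Total tail length by centrum summation
#'
#' Sums centrum lengths over the series. No allowance is made for
#' intervertebral space: in these animals the centra articulate closely enough
#' that soft tissue between them contributes negligibly to tail length, so the
#' skeletal sum stands for the tail length in the cone model.
#'
#' @param series a [vertebral_series()].
#' @param include_imputed logical; include records filled in by
#'   [impute_missing()] as well as preserved ones.
#' @return Total length in cm.
#' @export
#' @examples
#' vs <- vertebral_series(data.frame(position = 1:3, length_cm = c(10, 9, 8),
#'                                   height_cm = c(25, 20, 15)))
#' total_length(vs)  # 27
total_length <- function(series, include_imputed = TRUE) {
  stopifnot(inherits(series, "vertebral_series"))
  r <- series$records
  if (nrow(r) == 0L) stop("empty series: no vertebrae to sum", call. = FALSE)
  keep <- r$preserved | (include_imputed & r$imputed)
  sum(r$length_cm[keep])
}

#' Length/height profile of a vertebral series
#'
#' Returns one row per available vertebra with the centrum length, total
#' height and the length-to-height ratio, in position order. The ratio is the
#' quantity whose crossing of 1 defines the transition point to the whip-like
#' distal segment; the returned table is also the data behind the standard
#' length-versus-height profile plot.
#'
#' @param series a [vertebral_series()].
#' @param include_imputed logical; include imputed records.
#' @return A data frame of class `tail_profile` with columns `position`,
#'   `length_cm`, `height_cm`, `ratio`.
#' @seealso [plot.tail_profile()], [find_transition_point()]
#' @export
tail_profile <- function(series, include_imputed = TRUE) {
  stopifnot(inherits(series, "vertebral_series"))
  r <- series$records
  keep <- r$preserved | (include_imputed & r$imputed)
  r <- r[keep, , drop = FALSE]
  if (any(r$height_cm == 0)) {
    stop("zero total height at position(s): ",
         paste(r$position[r$height_cm == 0], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(position = r$position,
                    length_cm = r$length_cm,
                    height_cm = r$height_cm,
                    ratio = r$length_cm / r$height_cm)
  rownames(out) <- NULL
  class(out) <- c("tail_profile", "data.frame")
  out
}

#' Height of the vertebra at a given position
#' @keywords internal
height_at <- function(series, position) {
  r <- series$records
  i <- match(position, r$position)
  if (is.na(i) || !(r$preserved[i] || r$imputed[i])) {
    stop("no measured vertebra at position Ca", position, call. = FALSE)
  }
  r$height_cm[i]
}
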