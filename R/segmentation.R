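#' Find the transition point to the whip-like tail segment
#'
#' Along a reptilian tail the vertebrae shorten and, more steeply, lose
#' height: at some position the centrum becomes longer than the vertebra is
#' tall. That first crossing — the transition point (TP) — marks the onset of
#' the flexible, whip-like distal segment used in lateral strikes. The
#' crossing is strict: a vertebra exactly as long as it is tall does not
#' qualify.
#'
#' @param series a [vertebral_series()].
#' @param persistence logical. When `TRUE` (the default) the crossing must
#'   hold at every available position from the TP to the tail tip, which
#'   guards against spurious single-vertebra crossings caused by taphonomic
#'   distortion of individual elements. When `FALSE` the first crossing is
#'   returned as-is.
#' @return Integer caudal position of the first whip vertebra.
#' @export
#' @examples
#' vs <- vertebral_series(data.frame(position = 1:4,
#'                                   length_cm = c(5, 5, 5, 5),
#'                                   height_cm = c(9, 7, 4.5, 3)))
#' find_transition_point(vs)  # 3
find_transition_point <- function(series, persistence = TRUE) {
  stopifnot(inherits(series, "vertebral_series"))
  r <- series$records
  avail <- r[r$preserved | r$imputed, , drop = FALSE]
  if (nrow(avail) < 2L) {
    stop("need at least two measured vertebrae to detect a transition point",
         call. = FALSE)
  }
  longer <- avail$length_cm > avail$height_cm
  if (!any(longer)) {
    stop("no whip segment detected: centrum length never exceeds total height",
         call. = FALSE)
  }
  tp_idx <- if (persistence) {
    holds_onward <- rev(cumprod(rev(longer))) == 1
    if (!any(holds_onward)) {
      stop("no whip segment detected: crossing does not persist to the tail tip",
           call. = FALSE)
    }
    which(holds_onward)[1L]
  } else {
    which(longer)[1L]
  }
  # imputed vertebrae take part in detection like preserved ones, but values
  # interpolated right at the crossing deserve a flag
  near <- abs(seq_len(nrow(avail)) - tp_idx) <= 1L
  if (any(avail$imputed[near])) {
    warning("imputed vertebrae participate near the length/height crossing (TP = Ca",
            avail$position[tp_idx], ")", call. = FALSE)
  }
  avail$position[tp_idx]
}

#' Segment the tail at a transition point
#'
#' Splits the summed tail length at `tp_position` and reports the whip-segment
#' length, the total length, and the whip fraction. The TP vertebra itself
#' belongs to the whip segment.
#'
#' @param series a [vertebral_series()].
#' @param tp_position integer caudal position of the first whip vertebra;
#'   defaults to [find_transition_point()] on the series.
#' @param include_imputed logical; passed to the length summations.
#' @return An object of class `whip_segmentation`: list with `tp_position`,
#'   `whip_length_cm`, `total_length_cm`, `whip_fraction`.
#' @export
#' @examples
#' vs <- vertebral_series(data.frame(position = 1:3, length_cm = c(10, 10, 10),
#'                                   height_cm = c(30, 20, 5)))
#' segment_whip(vs, tp_position = 3)
segment_whip <- function(series,
                         tp_position = find_transition_point(series),
                         include_imputed = TRUE) {
  stopifnot(inherits(series, "vertebral_series"))
  r <- series$records
  if (!tp_position %in% r$position) {
    stop("tp_position ", tp_position, " is not a position of this series",
         call. = FALSE)
  }
  keep <- r$preserved | (include_imputed & r$imputed)
  total <- sum(r$length_cm[keep])
  whip <- sum(r$length_cm[keep & r$position >= tp_position])
  structure(
    list(tp_position = as.integer(tp_position),
         whip_length_cm = whip,
         total_length_cm = total,
         whip_fraction = whip / total),
    class = "whip_segmentation")
}

#' @export
print.whip_segmentation <- function(x, ...) {
  cat("Whip segmentation\n")
  cat("  transition point: Ca", x$tp_position, "\n", sep = "")
  cat(sprintf("  whip length:  %.1f cm\n", x$whip_length_cm))
  cat(sprintf("  total length: %.1f cm\n", x$total_length_cm))
  cat(sprintf("  whip fraction: %.1f%%\n", 100 * x$whip_fraction))
  invisible(x)
}
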