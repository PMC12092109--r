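#' Read per-vertebra measurements from a delimited text file
#'
#' Ingests measurement tables of the kind distributed as supplementary
#' appendices: one row per caudal vertebra with its position index and the
#' centrum length and total height in centimetres. Comma or tab separation is
#' auto-detected from the header row; the decimal separator is always the dot
#' regardless of locale. Rows whose length or height cell is blank are treated
#' as known-missing elements and recorded in `missing_positions` rather than
#' as measurements.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param schema named character vector mapping the canonical column roles
#'   `position`, `length`, `height` (and optionally `preserved`, `note`) to
#'   the column names used in the file. Defaults to the package's native
#'   schema `position,length_cm,height_cm[,preserved,note]`.
#' @param specimen_id,taxon,expected_count metadata stored on the series.
#' @return A [vertebral_series()] sorted by position.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("position,length_cm,height_cm", "1,10,25", "2,9,20", "3,8,15"), f)
#' read_measurements(f)
read_measurements <- function(path,
                              schema = c(position = "position",
                                         length = "length_cm",
                                         height = "height_cm"),
                              specimen_id = basename(path),
                              taxon = NA_character_,
                              expected_count = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE, na.strings = c("", "NA"))

  role <- function(name, required = TRUE) {
    col <- if (name %in% names(schema)) schema[[name]] else name
    if (!col %in% names(raw)) {
      if (required) {
        stop("required column '", col, "' (role: ", name,
             ") not found in ", path, call. = FALSE)
      }
      return(NULL)
    }
    raw[[col]]
  }

  pos_chr <- role("position")
  len_chr <- role("length")
  hgt_chr <- role("height")
  preserved_chr <- role("preserved", required = FALSE)
  note_chr <- role("note", required = FALSE)

  num <- function(x, what) {
    # dot-decimal only: reject comma decimals rather than silently misparse
    bad <- !is.na(x) & grepl(",", x, fixed = TRUE)
    if (any(bad)) {
      stop("comma decimal separator in ", what, " at row(s) ",
           paste(which(bad), collapse = ", "),
           "; use dot-decimal numbers", call. = FALSE)
    }
    suppressWarnings(as.numeric(x))
  }
  position <- num(pos_chr, "position")
  length_cm <- num(len_chr, "length")
  height_cm <- num(hgt_chr, "height")

  if (any(is.na(position))) {
    stop("unreadable position at row(s) ",
         paste(which(is.na(position)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(position)) {
    stop("duplicate position(s): ",
         paste(unique(position[duplicated(position)]), collapse = ", "),
         call. = FALSE)
  }

  measured <- !is.na(length_cm) & !is.na(height_cm)
  bad <- measured & (length_cm <= 0 | height_cm <= 0)
  if (any(bad)) {
    stop("non-positive measurement at row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }

  preserved <- if (is.null(preserved_chr)) {
    measured
  } else {
    p <- toupper(trimws(preserved_chr)) %in% c("TRUE", "T", "1", "YES")
    p & measured
  }
  imputed <- measured & !preserved
  note <- if (is.null(note_chr)) NA_character_ else as.character(note_chr)

  records <- data.frame(position = position[measured],
                        length_cm = length_cm[measured],
                        height_cm = height_cm[measured],
                        preserved = preserved[measured],
                        imputed = imputed[measured],
                        note = if (length(note) == 1L) note else note[measured],
                        stringsAsFactors = FALSE)
  vertebral_series(records,
                   specimen_id = specimen_id, taxon = taxon,
                   expected_count = expected_count,
                   missing_positions = as.integer(position[!measured]))
}

#' Write a vertebral series back to delimited text
#'
#' Emits the package's native schema
#' `position,length_cm,height_cm,preserved,imputed,note`, with one blank-valued
#' row per missing position, so that a written file re-reads into an identical
#' series.
#'
#' @param series a [vertebral_series()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "vertebral_series"))
  r <- series$records
  out <- data.frame(position = r$position,
                    length_cm = r$length_cm,
                    height_cm = r$height_cm,
                    preserved = r$preserved,
                    imputed = r$imputed,
                    note = ifelse(is.na(r$note), "", r$note))
  if (length(series$missing_positions) > 0L) {
    gaps <- data.frame(position = series$missing_positions,
                       length_cm = NA_real_, height_cm = NA_real_,
                       preserved = FALSE, imputed = FALSE, note = "")
    out <- rbind(out, gaps)
    out <- out[order(out$position), , drop = FALSE]
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
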