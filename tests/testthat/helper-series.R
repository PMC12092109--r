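# builders shared across test files

make_series <- function(lengths, heights, positions = seq_along(lengths),
                        missing = integer(), ...) {
  vertebral_series(
    data.frame(position = positions, length_cm = lengths,
               height_cm = heights),
    missing_positions = missing, ...)
}

# a simple tapering tail: heights fall fast, lengths slowly, crossing mid-way
tapering_series <- function(n = 20, crossing = 10) {
  spec <- synthetic_series_spec(n_vertebrae = n, ca1_height_cm = 20,
                                ca1_length_cm = 5, height_taper = 0.9,
                                tp_true = crossing)
  generate_series(spec)
}

write_series_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
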