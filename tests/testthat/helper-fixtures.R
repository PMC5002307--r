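# Build a landmark field from explicit coordinates (tests only).
new_landmark_field_for_test <- function(id, x, y, saliency, arena) {
  df <- data.frame(id = as.integer(id), x = x, y = y, saliency = saliency)
  structure(df, arena = arena, class = c("landmark_field", "data.frame"))
}

# A one-landmark place code, convenient for analytic firing-rate cases.
single_code <- function(id = 0L, saliency = 1, bearing = 0, distance = 12,
                        step = NA_integer_) {
  new_place_code(id = id, saliency = saliency, bearing = bearing,
                 distance = distance, step = step)
}
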