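# Arena geometry and landmark fields.

#' Define a rectangular arena
#'
#' The coordinate frame has its origin at the south-west corner, with x
#' increasing eastward and y increasing northward; all positions lie in
#' \[0, width\] x \[0, height\]. The baseline arena is 40 m x 40 m.
#'
#' @param width,height arena dimensions in metres; both must be positive.
#' @return An object of class `vpc_arena` with fields `width` and `height`.
#' @examples
#' arena()          # the 40 m x 40 m baseline
#' arena(20, 10)
#' @export
arena <- function(width = 40, height = 40) {
  width <- check_number(width, "width", lower = 0, strict_lower = TRUE)
  height <- check_number(height, "height", lower = 0, strict_lower = TRUE)
  structure(list(width = width, height = height), class = "vpc_arena")
}

#' @export
print.vpc_arena <- function(x, ...) {
  cat(sprintf("<arena %g m x %g m>\n", x$width, x$height))
  invisible(x)
}

# TRUE where (x, y) lies inside the arena (boundary inclusive).
in_arena <- function(arena, x, y, tol = 0) {
  x >= -tol & x <= arena$width + tol & y >= -tol & y <= arena$height + tol
}

#' Generate a random landmark field
#'
#' Landmark positions are sampled independently and uniformly over the
#' arena. Each landmark carries a recognition label (`id`, assigned
#' `0..n-1` in generation order), a position, and a saliency value. With
#' `saliency_mode = "equal"` all saliencies are 1, matching the baseline
#' study conditions; `"uniform_random"` draws i.i.d. saliencies on (0, 1)
#' to exercise the saliency weighting nontrivially.
#'
#' @param arena a [arena()] object.
#' @param n number of landmarks (>= 0).
#' @param saliency_mode `"equal"` (default) or `"uniform_random"`.
#' @param seed optional integer; the same seed reproduces the same field.
#' @return A `landmark_field`: a data.frame with columns `id`, `x`, `y`,
#'   `saliency` and the arena stored in attribute `"arena"`.
#' @examples
#' fld <- generate_landmark_field(arena(), n = 100, seed = 7)
#' nrow(fld)
#' @export
generate_landmark_field <- function(arena, n = 100,
                                    saliency_mode = c("equal", "uniform_random"),
                                    seed = NULL) {
  stopifnot(inherits(arena, "vpc_arena"))
  n <- check_count(n, "n")
  saliency_mode <- match.arg(saliency_mode)
  df <- with_seed_opt(seed, {
    x <- runif(n, 0, arena$width)
    y <- runif(n, 0, arena$height)
    s <- if (saliency_mode == "equal") rep(1, n) else runif(n)
    data.frame(id = seq_len(n) - 1L, x = x, y = y, saliency = s)
  })
  new_landmark_field(df, arena)
}

new_landmark_field <- function(df, arena) {
  structure(df, arena = arena, class = c("landmark_field", "data.frame"))
}

validate_landmark_field <- function(df, arena = NULL, where = "landmark field") {
  need <- c("id", "x", "y", "saliency")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s must have columns %s", where,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  num <- lapply(df[need], function(col) suppressWarnings(as.numeric(col)))
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad)) {
    stop(sprintf("%s: malformed row(s) %s", where,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  df[need] <- num
  dup <- duplicated(df$id)
  if (any(dup)) {
    stop(sprintf("%s: duplicate landmark id(s) %s (row %s)", where,
                 paste(unique(df$id[dup]), collapse = ", "),
                 paste(which(dup), collapse = ", ")), call. = FALSE)
  }
  if (any(df$saliency <= 0)) {
    stop(sprintf("%s: saliency must be > 0 (row %s)", where,
                 paste(which(df$saliency <= 0), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(arena)) {
    out <- !in_arena(arena, df$x, df$y)
    if (any(out)) {
      stop(sprintf("%s: position outside the arena (row %s)", where,
                   paste(which(out), collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Read and write landmark fields as CSV
#'
#' The format is a UTF-8 CSV with header `id,x,y,saliency`, one landmark
#' per row. Reading validates the invariants (unique ids, positive
#' saliency, positions inside the arena when one is given) and reports the
#' offending row on failure. A header-only file yields an empty field.
#'
#' @param path file path.
#' @param arena optional [arena()]; when supplied, coordinates are checked
#'   against it and stored with the returned field.
#' @param field a `landmark_field` to write.
#' @return `read_landmark_csv` returns a `landmark_field`;
#'   `write_landmark_csv` returns `path` invisibly.
#' @export
read_landmark_csv <- function(path, arena = NULL) {
  df <- utils::read.csv(path, colClasses = NA)
  df <- validate_landmark_field(df, arena, where = basename(path))
  df$id <- as.integer(df$id)
  new_landmark_field(df[c("id", "x", "y", "saliency")], arena)
}

#' @rdname read_landmark_csv
#' @export
write_landmark_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field)[c("id", "x", "y", "saliency")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
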