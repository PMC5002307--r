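# Model core: Gaussian similarity firing, saliency weights, winner-take-all
# comparison and FRT-gated recruitment.

#' Firing-function parameters
#'
#' `sigma_d2` and `sigma_theta2` are the adjustment factors of the firing
#' field (AFFF): the squared scales of the Gaussian decay in distance
#' mismatch (m^2) and bearing mismatch (squared degrees). Larger AFFF
#' values widen firing fields. `w_d` and `w_theta` are 0/1 indicators
#' selecting whether distance and orientation enter the similarity
#' measure. `frt` is the firing-rate threshold: when the winning cell's
#' rate falls strictly below it, a new cell is recruited.
#'
#' Defaults are the baseline study conditions: `sigma_d2 = 25` (so
#' sigma_d = 5 m), `sigma_theta2 = 100` (sigma_theta = 10 deg),
#' `w_d = w_theta = 1`, `frt = 0.2`.
#'
#' @param sigma_d2 distance AFFF in m^2 (> 0).
#' @param sigma_theta2 orientation AFFF in squared degrees (> 0).
#' @param w_d,w_theta indicators in {0, 1}.
#' @param frt firing-rate threshold in \[0, 1\].
#' @return An object of class `firing_params`.
#' @export
firing_params <- function(sigma_d2 = 25, sigma_theta2 = 100,
                          w_d = 1, w_theta = 1, frt = 0.2) {
  sigma_d2 <- check_number(sigma_d2, "sigma_d2", lower = 0, strict_lower = TRUE)
  sigma_theta2 <- check_number(sigma_theta2, "sigma_theta2",
                               lower = 0, strict_lower = TRUE)
  if (!w_d %in% c(0, 1)) stop("`w_d` must be 0 or 1", call. = FALSE)
  if (!w_theta %in% c(0, 1)) stop("`w_theta` must be 0 or 1", call. = FALSE)
  frt <- check_number(frt, "frt", lower = 0, upper = 1)
  structure(list(sigma_d2 = sigma_d2, sigma_theta2 = sigma_theta2,
                 w_d = w_d, w_theta = w_theta, frt = frt),
            class = "firing_params")
}

#' Saliency weights of the current place code
#'
#' Each perceived landmark contributes to a cell's firing rate in
#' proportion to its saliency: `w_i = s_i / sum(s_j)`, normalized over all
#' landmarks in the code. With equal saliencies every landmark weighs
#' `1/N`. An empty code yields an empty weight vector.
#'
#' @param code a `place_code`.
#' @return Named numeric vector of weights (names are landmark ids),
#'   summing to 1 for a nonempty code.
#' @examples
#' landmark_weights(new_place_code(id = 1:2, saliency = c(1, 3),
#'                                 bearing = c(0, 90), distance = c(12, 13)))
#' @export
landmark_weights <- function(code) {
  stopifnot(inherits(code, "place_code"))
  if (code$n == 0L) return(stats::setNames(numeric(0), character(0)))
  total <- sum(code$saliency)
  if (total <= 0) stop("total saliency must be positive", call. = FALSE)
  stats::setNames(code$saliency / total, code$id)
}

# Internal place-cell constructor; the stored code is frozen at recruitment.
new_place_cell <- function(cell_id, code, recruited_at = NA_integer_) {
  structure(list(cell_id = as.integer(cell_id), code = code,
                 recruited_at = recruited_at),
            class = "place_cell")
}

#' @export
print.place_cell <- function(x, ...) {
  cat(sprintf("<place cell %d: %d landmark(s), recruited at step %s>\n",
              x$cell_id, x$code$n, format(x$recruited_at)))
  invisible(x)
}

#' Matched landmarks between a cell's stored code and the current code
#'
#' Matching is by recognition label equality; the size of the returned set
#' is the `N_k` of the similarity measure.
#'
#' @param cell a `place_cell`.
#' @param current the current `place_code`.
#' @return Integer vector of ids present in both codes.
#' @export
match_landmarks <- function(cell, current) {
  intersect(cell$code$id, current$id)
}

#' Firing rate of one place cell (Gaussian similarity measure)
#'
#' The rate of cell k at the current percept is
#' \deqn{f_k = \sum_{i \in matched} w_i \exp\!\left(-\left(
#'   w_d \frac{(d_i - d_i^k)^2}{\sigma_d^2} +
#'   w_\theta \frac{(\Delta\theta_i)^2}{\sigma_\theta^2}\right)\right)}
#' where the sum runs over landmarks present in both the stored and the
#' current place code, `d_i`/`theta_i` are the current distance and
#' bearing, `d_i^k`/`theta_i^k` the ones memorized at recruitment, and
#' `w_i` the saliency weights of [landmark_weights()]. Bearing differences
#' are wrapped into \[-180, 180\] degrees before squaring, so bearings just
#' either side of north compare as close. The rate is 0 when no landmark
#' matches and exactly 1 when the current percept equals the stored one.
#'
#' @param cell a `place_cell`.
#' @param current the current `place_code`.
#' @param params a [firing_params()].
#' @param weight_mode `"current"` (default): weights normalized over all
#'   landmarks of the current code, so unmatched current landmarks dilute
#'   the weights and scene change is penalized; `"matched"`: normalized
#'   over matched landmarks only (sensitivity-analysis variant).
#' @return Firing rate in \[0, 1\].
#' @examples
#' pc <- new_place_code(id = 0L, saliency = 1, bearing = 0, distance = 12)
#' cell <- recruit_cell(pc, cell_id = 0L)
#' firing_rate(cell, pc, firing_params())   # 1: exact self-recall
#' @export
firing_rate <- function(cell, current, params,
                        weight_mode = c("current", "matched")) {
  weight_mode <- match.arg(weight_mode)
  firing_rate_core(cell$code, current, params, weight_mode == "current")
}

# Bare per-cell rates for a list of cells (no names, no validation).
evaluate_rates <- function(cells, current, params, norm_current) {
  vapply(cells, function(cl) {
    firing_rate_core(cl$code, current, params, norm_current)
  }, numeric(1))
}

# Validation-free core shared by firing_rate() and the population loop;
# `norm_current` selects the Eq (4)-over-current normalization.
firing_rate_core <- function(stored, current, params, norm_current) {
  if (current$n == 0L || stored$n == 0L) return(0)
  idx <- match(current$id, stored$id)
  m <- which(!is.na(idx))
  if (length(m) == 0L) return(0)
  w <- if (norm_current) {
    current$saliency[m] / sum(current$saliency)
  } else {
    current$saliency[m] / sum(current$saliency[m])
  }
  dd <- current$distance[m] - stored$distance[idx[m]]
  dth <- ((current$bearing[m] - stored$bearing[idx[m]] + 180) %% 360) - 180
  sum(w * exp(-(params$w_d * dd^2 / params$sigma_d2 +
                params$w_theta * dth^2 / params$sigma_theta2)))
}

#' Create an empty place-cell population
#'
#' @param params a [firing_params()].
#' @param weight_mode weight normalization passed to [firing_rate()].
#' @return An object of class `vpc_population` holding zero cells.
#' @export
new_population <- function(params = firing_params(),
                           weight_mode = c("current", "matched")) {
  stopifnot(inherits(params, "firing_params"))
  structure(list(cells = list(), params = params,
                 weight_mode = match.arg(weight_mode)),
            class = "vpc_population")
}

#' @export
print.vpc_population <- function(x, ...) {
  cat(sprintf("<VPC population: %d cell(s), FRT = %g>\n",
              length(x$cells), x$params$frt))
  invisible(x)
}

#' @export
length.vpc_population <- function(x) length(x$cells)

#' Recruit a cell directly from a place code
#'
#' Used internally by [maybe_recruit()] and convenient in tests. The code
#' is copied into the cell and never modified afterwards.
#'
#' @param code the `place_code` to memorize (nonempty).
#' @param cell_id integer id for the new cell.
#' @param recruited_at step index recorded with the cell.
#' @return A `place_cell`.
#' @export
recruit_cell <- function(code, cell_id, recruited_at = code$step) {
  stopifnot(inherits(code, "place_code"))
  if (code$n == 0L) {
    stop("cannot recruit a cell from an empty place code", call. = FALSE)
  }
  new_place_cell(cell_id, code, recruited_at)
}

#' Evaluate every cell of the population at the current percept
#'
#' Computes all firing rates and selects the winner (maximal rate; ties
#' broken deterministically in favour of the lowest cell id, i.e. the
#' earliest-recruited cell).
#'
#' @param pop a `vpc_population`.
#' @param current the current `place_code`.
#' @return A list with `rates` (named by cell id), `winner_id` (or `NA`
#'   for an empty population) and `winner_rate` (`NA` likewise).
#' @export
evaluate_population <- function(pop, current) {
  ncell <- length(pop$cells)
  if (ncell == 0L) {
    return(list(rates = numeric(0), winner_id = NA_integer_,
                winner_rate = NA_real_))
  }
  rates <- evaluate_rates(pop$cells, current, pop$params,
                          pop$weight_mode == "current")
  names(rates) <- vapply(pop$cells, function(cl) as.character(cl$cell_id),
                         character(1))
  win <- which.max(rates)  # first maximum = lowest cell_id (recruitment order)
  list(rates = rates,
       winner_id = pop$cells[[win]]$cell_id,
       winner_rate = unname(rates[win]))
}

#' Recruit a new cell if the winning rate falls below the threshold
#'
#' Implements the recruitment rule: firing rates of all recruited cells
#' are compared, and if the winner is strictly below the firing-rate
#' threshold (FRT) — or no cell exists yet — the current place code is
#' memorized by a newly recruited cell. An empty percept never recruits:
#' it carries no location information and the saliency normalization is
#' undefined.
#'
#' @param pop a `vpc_population`.
#' @param current the current `place_code`.
#' @return A list with `population` (possibly grown by one cell),
#'   `recruited` (logical), `winner_rate` (rate before recruitment; `NA`
#'   when the population was empty) and `cell_id` of the new cell (`NA` if
#'   none).
#' @export
maybe_recruit <- function(pop, current) {
  stopifnot(inherits(pop, "vpc_population"), inherits(current, "place_code"))
  if (current$n == 0L) {
    return(list(population = pop, recruited = FALSE,
                winner_rate = NA_real_, cell_id = NA_integer_))
  }
  ev <- evaluate_population(pop, current)
  ncell <- length(pop$cells)
  if (ncell == 0L || ev$winner_rate < pop$params$frt) {
    cell <- recruit_cell(current, cell_id = ncell)
    pop$cells[[ncell + 1L]] <- cell
    list(population = pop, recruited = TRUE,
         winner_rate = ev$winner_rate, cell_id = cell$cell_id)
  } else {
    list(population = pop, recruited = FALSE,
         winner_rate = ev$winner_rate, cell_id = NA_integer_)
  }
}

#' Write and read the recruited-cell registry as JSON
#'
#' The registry is an array of cells, each
#' `{cell_id, recruited_at, code: [{id, saliency, bearing_deg, distance_m}]}`.
#' Writing then reading reproduces the population's cells exactly (the
#' firing parameters travel separately in the run configuration).
#'
#' @param pop a `vpc_population`.
#' @param path file path.
#' @param params a [firing_params()] used when reconstructing.
#' @return `write_vpc_registry` returns `path` invisibly;
#'   `read_vpc_registry` returns a `vpc_population`.
#' @export
write_vpc_registry <- function(pop, path) {
  cells <- lapply(pop$cells, function(cl) {
    list(cell_id = cl$cell_id,
         recruited_at = cl$recruited_at,
         code = data.frame(id = cl$code$id,
                           saliency = cl$code$saliency,
                           bearing_deg = cl$code$bearing,
                           distance_m = cl$code$distance))
  })
  jsonlite::write_json(cells, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_vpc_registry
#' @export
read_vpc_registry <- function(path, params = firing_params()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  pop <- new_population(params)
  if (length(raw) == 0) return(pop)
  pop$cells <- lapply(seq_len(nrow(raw)), function(i) {
    cd <- raw$code[[i]]
    new_place_cell(raw$cell_id[i],
                   new_place_code(id = cd$id, saliency = cd$saliency,
                                  bearing = cd$bearing_deg,
                                  distance = cd$distance_m,
                                  step = raw$recruited_at[i]),
                   recruited_at = raw$recruited_at[i])
  })
  pop
}
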