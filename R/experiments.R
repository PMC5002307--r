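# End-to-end run orchestration and parameter studies.

#' Build a run configuration
#'
#' Collects every knob of a single exploration run. Defaults are the
#' baseline study conditions: a 40 m x 40 m arena with 100 uniformly
#' placed equal-saliency landmarks, recognition distance 10–15 m, maximal
#' speed 5 m/s with a 1 s update period, 4000 location-update steps,
#' `sigma_d2 = 25`, `sigma_theta2 = 100`, `w_d = w_theta = 1` and
#' `FRT = 0.2`.
#'
#' Landmark layout and trajectory use separate seeds so either can be
#' held fixed across runs; when not given they are derived
#' deterministically from `seed`.
#'
#' @param width,height arena dimensions in metres.
#' @param n_landmarks number of landmarks.
#' @param saliency_mode `"equal"` or `"uniform_random"`.
#' @param d_min,d_max recognition-distance annulus in metres.
#' @param v_max maximal speed in m/s.
#' @param dt location-update period in seconds.
#' @param heading_policy agent heading policy (see [step_agent()]).
#' @param n_steps number of location-update steps.
#' @param sigma_d2,sigma_theta2,w_d,w_theta,frt firing parameters (see
#'   [firing_params()]).
#' @param resolution rate-map bin side in metres.
#' @param seed master seed; every random draw of the run flows from it.
#' @param landmark_seed,trajectory_seed optional explicit sub-seeds.
#' @param weight_mode weight normalization (see [firing_rate()]).
#' @param start optional start position; default the arena centre.
#' @return An object of class `run_config`.
#' @export
run_config <- function(width = 40, height = 40,
                       n_landmarks = 100,
                       saliency_mode = "equal",
                       d_min = 10, d_max = 15,
                       v_max = 5, dt = 1,
                       heading_policy = "wander",
                       n_steps = 4000,
                       sigma_d2 = 25, sigma_theta2 = 100,
                       w_d = 1, w_theta = 1, frt = 0.2,
                       resolution = 0.5,
                       seed = 1,
                       landmark_seed = NULL, trajectory_seed = NULL,
                       weight_mode = "current",
                       start = NULL) {
  problems <- character(0)
  note <- function(cond) problems <<- c(problems, conditionMessage(cond))
  grab <- function(expr) tryCatch(expr, error = function(e) { note(e); NULL })

  ar <- grab(arena(width, height))
  n_landmarks <- grab(check_count(n_landmarks, "n_landmarks"))
  saliency_mode <- grab(match.arg(saliency_mode, c("equal", "uniform_random")))
  d_min <- grab(check_number(d_min, "d_min", lower = 0))
  d_max <- grab(check_number(d_max, "d_max", lower = 0))
  if (!is.null(d_min) && !is.null(d_max) && d_min >= d_max) {
    problems <- c(problems, "`d_min` must be < `d_max`")
  }
  v_max <- grab(check_number(v_max, "v_max", lower = 0, strict_lower = TRUE))
  dt <- grab(check_number(dt, "dt", lower = 0, strict_lower = TRUE))
  heading_policy <- grab(match.arg(heading_policy,
                                   c("wander", "uniform", "fixed")))
  n_steps <- grab(check_count(n_steps, "n_steps", lower = 1L))
  params <- grab(firing_params(sigma_d2, sigma_theta2, w_d, w_theta, frt))
  resolution <- grab(check_number(resolution, "resolution",
                                  lower = 0, strict_lower = TRUE))
  seed <- grab(check_count(seed, "seed"))
  weight_mode <- grab(match.arg(weight_mode, c("current", "matched")))
  if (!is.null(start) && !is.null(ar) &&
      !isTRUE(all(in_arena(ar, start[1], start[2])))) {
    problems <- c(problems, "`start` must lie inside the arena")
  }
  if (length(problems) > 0) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  if (is.null(landmark_seed)) landmark_seed <- seed
  if (is.null(trajectory_seed)) trajectory_seed <- seed + 500000L

  structure(list(
    width = width, height = height,
    n_landmarks = n_landmarks, saliency_mode = saliency_mode,
    d_min = d_min, d_max = d_max,
    v_max = v_max, dt = dt, heading_policy = heading_policy,
    n_steps = n_steps,
    sigma_d2 = params$sigma_d2, sigma_theta2 = params$sigma_theta2,
    w_d = params$w_d, w_theta = params$w_theta, frt = params$frt,
    resolution = resolution,
    seed = seed,
    landmark_seed = as.integer(landmark_seed),
    trajectory_seed = as.integer(trajectory_seed),
    weight_mode = weight_mode,
    start = start
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<run config: %g x %g m arena, %d landmarks (%s), annulus [%g, %g] m,\n",
    "  v_max %g m/s, dt %g s, %s policy, %d steps,\n",
    "  sigma_d2 %g, sigma_theta2 %g, w_d %g, w_theta %g, FRT %g, seed %d>\n"),
    x$width, x$height, x$n_landmarks, x$saliency_mode, x$d_min, x$d_max,
    x$v_max, x$dt, x$heading_policy, x$n_steps,
    x$sigma_d2, x$sigma_theta2, x$w_d, x$w_theta, x$frt, x$seed))
  invisible(x)
}

# Firing rates of all cells at the current percept, computed over a flat
# store of memorized entries (columns: cell index, landmark id, distance,
# bearing). Numerically equivalent to evaluate_rates()/firing_rate(); the
# agreement is pinned by tests against the brute-force evaluation.
store_rates <- function(store, ncell, pc, params, norm_current) {
  rates <- numeric(ncell)
  if (ncell == 0L || length(store$id) == 0L) return(rates)
  pos <- match(store$id, pc$id)
  sel <- which(!is.na(pos))
  if (length(sel) == 0L) return(rates)
  j <- pos[sel]
  cellk <- store$cell[sel]
  dd <- pc$distance[j] - store$d[sel]
  dth <- ((pc$bearing[j] - store$th[sel] + 180) %% 360) - 180
  g <- pc$saliency[j] * exp(-(params$w_d * dd^2 / params$sigma_d2 +
                              params$w_theta * dth^2 / params$sigma_theta2))
  num <- rowsum(g, cellk)
  kk <- as.integer(rownames(num))
  if (norm_current) {
    rates[kk] <- num[, 1] / sum(pc$saliency)
  } else {
    den <- rowsum(pc$saliency[j], cellk)
    rates[kk] <- num[, 1] / den[, 1]
  }
  rates
}

#' Execute one exploration run
#'
#' Generates the landmark field, simulates the random-walk trajectory and
#' then, at every step: perceives the landmarks in the recognition
#' annulus, evaluates all recruited cells, and recruits a new cell when
#' the winning rate is strictly below the FRT. Fully deterministic given
#' the configuration's seeds.
#'
#' @param config a [run_config()].
#' @param field optional pre-built `landmark_field` overriding generation
#'   (used by the sweep harness to hold the layout fixed).
#' @param keep_percepts keep the per-step place codes in the result
#'   (needed for [rate_maps()]; disable to save memory on large sweeps).
#' @return A `run_result` list: `config`, `field`, `trajectory`,
#'   `percepts` (or `NULL`), `population`, `n_vpcs`, and `steps`, a
#'   per-step data.frame with columns `t`, `n_perceived`, `winner_rate`
#'   (before any recruitment at that step; `NA` while the population is
#'   empty), `recruited`, and `winner_rate_post` (after recruitment, the
#'   quantity the coverage guarantee bounds below by FRT).
#' @examples
#' res <- run_single(run_config(n_steps = 200, seed = 42))
#' res$n_vpcs
#' @export
run_single <- function(config, field = NULL, keep_percepts = TRUE) {
  stopifnot(inherits(config, "run_config"))
  ar <- arena(config$width, config$height)
  if (is.null(field)) {
    field <- generate_landmark_field(ar, config$n_landmarks,
                                     config$saliency_mode,
                                     seed = config$landmark_seed)
  }
  traj <- simulate_trajectory(ar, start = config$start,
                              n_steps = config$n_steps,
                              v_max = config$v_max, dt = config$dt,
                              heading_policy = config$heading_policy,
                              seed = config$trajectory_seed)
  params <- firing_params(config$sigma_d2, config$sigma_theta2,
                          config$w_d, config$w_theta, config$frt)
  pop <- new_population(params, config$weight_mode)

  n <- config$n_steps
  n_perceived <- integer(n)
  winner_rate <- winner_rate_post <- rep(NA_real_, n)
  recruited <- logical(n)
  percepts <- if (keep_percepts) vector("list", n) else NULL

  # Lean inner loop: same decision rule as maybe_recruit(), evaluated
  # over a flat store of all memorized landmark entries so the whole
  # population is scored in one vectorized pass per step.
  cells <- list()
  store <- list(cell = integer(0), id = integer(0),
                d = numeric(0), th = numeric(0), s = numeric(0))
  norm_current <- config$weight_mode == "current"
  tx <- traj$x; ty <- traj$y
  for (t in seq_len(n)) {
    pc <- perceive(c(tx[t], ty[t]), field,
                   config$d_min, config$d_max, step = t)
    n_perceived[t] <- pc$n
    if (keep_percepts) percepts[[t]] <- pc
    if (pc$n == 0L) next
    rates <- store_rates(store, length(cells), pc, params, norm_current)
    wr <- if (length(rates)) max(rates) else NA_real_
    winner_rate[t] <- wr
    if (length(cells) == 0L || wr < params$frt) {
      k <- length(cells) + 1L
      cells[[k]] <- new_place_cell(k - 1L, pc, recruited_at = t)
      store$cell <- c(store$cell, rep.int(k, pc$n))
      store$id <- c(store$id, pc$id)
      store$d <- c(store$d, pc$distance)
      store$th <- c(store$th, pc$bearing)
      recruited[t] <- TRUE
      # self-recall of the just-recruited cell; recomputed, not assumed
      winner_rate_post[t] <- max(store_rates(store, k, pc, params,
                                             norm_current))
    } else {
      winner_rate_post[t] <- wr
    }
  }
  pop$cells <- cells

  structure(list(
    config = config, field = field, trajectory = traj,
    percepts = percepts, population = pop,
    n_vpcs = length(pop$cells),
    steps = data.frame(t = seq_len(n), n_perceived = n_perceived,
                       winner_rate = winner_rate, recruited = recruited,
                       winner_rate_post = winner_rate_post)
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run result: %d VPCs recruited over %d steps (seed %d)>\n",
    x$n_vpcs, x$config$n_steps, x$config$seed))
  invisible(x)
}

#' Rasterize the firing fields of a run
#'
#' Builds per-cell rate maps along the run's trajectory and their
#' population overlap map (bin-wise maximum). Requires the run to have
#' been executed with `keep_percepts = TRUE`.
#'
#' @param result a `run_result`.
#' @param cells integer cell ids to rasterize; default all.
#' @param resolution bin side in metres; default the config's.
#' @return A list with `cell_maps` (named by cell id) and `population`
#'   (the overlap `rate_map`).
#' @export
rate_maps <- function(result, cells = NULL, resolution = NULL) {
  stopifnot(inherits(result, "run_result"))
  if (is.null(result$percepts)) {
    stop("run was executed with `keep_percepts = FALSE`; re-run to rasterize",
         call. = FALSE)
  }
  if (is.null(resolution)) resolution <- result$config$resolution
  pop <- result$population
  if (is.null(cells)) {
    use <- pop$cells
  } else {
    ids <- vapply(pop$cells, `[[`, integer(1), "cell_id")
    use <- pop$cells[ids %in% cells]
  }
  if (length(use) == 0L) stop("no cells to rasterize", call. = FALSE)
  maps <- lapply(use, rasterize_cell, trajectory = result$trajectory,
                 percepts = result$percepts, params = pop$params,
                 resolution = resolution,
                 arena = arena(result$config$width, result$config$height),
                 weight_mode = pop$weight_mode)
  names(maps) <- vapply(use, function(cl) as.character(cl$cell_id),
                        character(1))
  list(cell_maps = maps, population = population_map(maps))
}

#' Sweep one parameter across values with replicated runs
#'
#' Runs the model once per (value, replicate) pair. Within a replicate
#' the landmark layout and the trajectory seed are held fixed across all
#' values, so differences in the recruited-cell count isolate the
#' parameter's effect; across replicates both vary.
#'
#' Sweepable parameters: `"sigma_d2"`, `"sigma_theta2"`, `"frt"`,
#' `"n_steps"`; `"annulus"` (each value a numeric `c(d_min, d_max)` pair);
#' and `"afff"`, a convenience that scales `sigma_d2` and `sigma_theta2`
#' jointly by the given factor.
#'
#' @param base a [run_config()] supplying everything not swept.
#' @param param parameter name (see above).
#' @param values vector of values, or for `"annulus"` a list of
#'   `c(d_min, d_max)` pairs; the order given is the order trend checks
#'   use.
#' @param replicates number of replicate runs per value (>= 1).
#' @return A `vpc_sweep` data.frame with columns `param`, `value`
#'   (character label), `value_index` (position in `values`),
#'   `replicate`, `landmark_seed`, `trajectory_seed`, `n_vpcs`.
#' @examples
#' \donttest{
#' base <- run_config(n_steps = 500, seed = 1)
#' tab <- sweep(base, "frt", c(0.1, 0.2, 0.3, 0.4), replicates = 2)
#' trend_check(tab, "increasing")
#' }
#' @export
sweep <- function(base, param, values, replicates = 5) {
  stopifnot(inherits(base, "run_config"))
  allowed <- c("sigma_d2", "sigma_theta2", "frt", "n_steps", "annulus", "afff")
  if (!param %in% allowed) {
    stop(sprintf("unknown sweep parameter `%s`; use one of %s", param,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  replicates <- check_count(replicates, "replicates", lower = 1L)
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  if (param == "annulus" && !is.list(values)) {
    stop("for `annulus`, `values` must be a list of c(d_min, d_max) pairs",
         call. = FALSE)
  }

  label_of <- function(v) {
    if (param == "annulus") sprintf("%g-%g", v[1], v[2]) else format(v)
  }
  apply_value <- function(cfg, v) {
    if (param == "annulus") {
      cfg$d_min <- v[1]; cfg$d_max <- v[2]
    } else if (param == "afff") {
      cfg$sigma_d2 <- base$sigma_d2 * v
      cfg$sigma_theta2 <- base$sigma_theta2 * v
    } else {
      cfg[[param]] <- v
    }
    cfg
  }

  rows <- vector("list", length(values) * replicates)
  k <- 0L
  ar <- arena(base$width, base$height)
  for (r in seq_len(replicates)) {
    lm_seed <- base$seed + 1000L * r
    tr_seed <- base$seed + 1000L * r + 500L
    field <- generate_landmark_field(ar, base$n_landmarks,
                                     base$saliency_mode, seed = lm_seed)
    for (vi in seq_along(values)) {
      v <- if (is.list(values)) values[[vi]] else values[vi]
      cfg <- apply_value(base, v)
      cfg$landmark_seed <- lm_seed
      cfg$trajectory_seed <- tr_seed
      cfg <- do.call(run_config, unclass(cfg))
      res <- run_single(cfg, field = field, keep_percepts = FALSE)
      k <- k + 1L
      rows[[k]] <- data.frame(
        param = param, value = label_of(v), value_index = vi,
        replicate = r, landmark_seed = lm_seed, trajectory_seed = tr_seed,
        n_vpcs = res$n_vpcs
      )
    }
  }
  structure(do.call(rbind, rows),
            class = c("vpc_sweep", "data.frame"))
}

#' Check the trend of replicate-mean cell counts across swept values
#'
#' Aggregates `n_vpcs` to the replicate mean per swept value (in the
#' order the values were given to [sweep()]) and tests the stated
#' direction: `"increasing"` and `"decreasing"` require strictly ordered
#' means; `"saturating"` requires strictly increasing means whose
#' successive differences strictly decrease (growth that levels off).
#'
#' @param table a `vpc_sweep` (or any data.frame with `value`,
#'   `value_index`, `n_vpcs`).
#' @param direction `"increasing"`, `"decreasing"` or `"saturating"`.
#' @return A `trend_check` list: `direction`, `values`, `means`, `diffs`,
#'   `pass`.
#' @export
trend_check <- function(table, direction = c("increasing", "decreasing",
                                             "saturating")) {
  direction <- match.arg(direction)
  stopifnot(all(c("value", "value_index", "n_vpcs") %in% names(table)))
  agg <- stats::aggregate(n_vpcs ~ value_index + value, data = table,
                          FUN = mean)
  agg <- agg[order(agg$value_index), ]
  means <- agg$n_vpcs
  d <- diff(means)
  pass <- switch(direction,
    increasing = length(d) > 0 && all(d > 0),
    decreasing = length(d) > 0 && all(d < 0),
    saturating = length(d) > 0 && all(d > 0) &&
      (length(d) < 2 || all(diff(d) < 0))
  )
  structure(list(direction = direction, values = agg$value,
                 means = means, diffs = d, pass = pass),
            class = "trend_check")
}

#' @export
print.trend_check <- function(x, ...) {
  cat(sprintf("<trend check (%s): %s>\n", x$direction,
              if (x$pass) "PASS" else "FAIL"))
  print(data.frame(value = x$values, mean_n_vpcs = x$means))
  invisible(x)
}
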