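# Random-walk agent with specular reflection at the arena walls.

# Fold a coordinate into [0, width] by repeated specular reflection.
# Uses the 2*width periodic unfolding, which resolves any number of
# bounces (including corner hits, handled axis-wise) in closed form.
# Returns the folded position and whether the direction component flips.
reflect_fold <- function(p, width) {
  m <- p %% (2 * width)
  flipped <- m > width
  list(pos = if (flipped) 2 * width - m else m, flipped = flipped)
}

#' Construct an agent state
#'
#' @param x,y position in metres, inside the arena.
#' @param heading direction of travel in degrees clockwise from north,
#'   in \[0, 360).
#' @param speed current speed in m/s.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(x, y, heading = 0, speed = 1) {
  structure(list(
    x = check_number(x, "x"),
    y = check_number(y, "y"),
    heading = norm_heading(check_number(heading, "heading")),
    speed = check_number(speed, "speed", lower = 0, strict_lower = TRUE)
  ), class = "agent_state")
}

#' Advance the agent by one location-update period
#'
#' Each period a fresh speed is drawn uniformly on (0, `v_max`\] and the
#' heading is updated according to `heading_policy`; the agent then moves
#' `speed * dt` metres along the heading. A segment crossing a wall is
#' reflected specularly (the velocity component normal to the wall is
#' negated, the tangential component preserved), repeatedly if needed, so
#' the returned position is always inside the arena and the distance
#' travelled within the period equals `speed * dt`.
#'
#' Heading policies:
#' \describe{
#'   \item{`wander`}{(default) the heading is perturbed by a turn drawn
#'     uniformly on \[-`turn_range`, +`turn_range`\] degrees, giving dense
#'     exploratory coverage;}
#'   \item{`uniform`}{a fresh heading uniform on \[0, 360) each period;}
#'   \item{`fixed`}{the heading changes only through wall reflections.}
#' }
#'
#' Randomness is taken from the ambient RNG stream; seed at the caller
#' (see [simulate_trajectory()]).
#'
#' @param state an [agent_state()].
#' @param arena a [arena()].
#' @param v_max maximal speed in m/s (> 0).
#' @param dt location-update period in seconds (> 0).
#' @param heading_policy one of `"wander"`, `"uniform"`, `"fixed"`.
#' @param turn_range half-width in degrees of the `wander` turn.
#' @param speed optional fixed speed in (0, `v_max`\] for this period; when
#'   `NULL` (default) a fresh speed is drawn uniformly on (0, `v_max`\].
#' @return The new `agent_state`.
#' @export
step_agent <- function(state, arena, v_max = 5, dt = 1,
                       heading_policy = c("wander", "uniform", "fixed"),
                       turn_range = 30, speed = NULL) {
  stopifnot(inherits(state, "agent_state"), inherits(arena, "vpc_arena"))
  v_max <- check_number(v_max, "v_max", lower = 0, strict_lower = TRUE)
  dt <- check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  heading_policy <- match.arg(heading_policy)

  if (is.null(speed)) {
    speed <- runif(1, 0, v_max)
  } else {
    speed <- check_number(speed, "speed", lower = 0, upper = v_max,
                          strict_lower = TRUE)
  }
  heading <- switch(heading_policy,
    wander  = norm_heading(state$heading + runif(1, -turn_range, turn_range)),
    uniform = runif(1, 0, 360),
    fixed   = state$heading
  )

  h <- heading * pi / 180
  ux <- sin(h)   # east component: clockwise-from-north convention
  uy <- cos(h)
  len <- speed * dt
  fx <- reflect_fold(state$x + ux * len, arena$width)
  fy <- reflect_fold(state$y + uy * len, arena$height)
  if (fx$flipped) ux <- -ux
  if (fy$flipped) uy <- -uy
  agent_state(fx$pos, fy$pos,
              norm_heading(atan2(ux, uy) * 180 / pi), speed)
}

#' Simulate a random exploration trajectory
#'
#' Applies [step_agent()] for `n_steps` periods from `start` and records
#' the post-step state of each period. Deterministic given `seed`.
#'
#' @param arena a [arena()].
#' @param start numeric length-2 start position; defaults to the arena
#'   centre.
#' @param n_steps number of location-update steps (>= 1).
#' @inheritParams step_agent
#' @param seed optional integer seed.
#' @return A `trajectory`: a data.frame with columns `t` (1-based step
#'   index), `x`, `y`, `heading`, `speed`.
#' @examples
#' tr <- simulate_trajectory(arena(), n_steps = 100, seed = 3)
#' max(sqrt(diff(tr$x)^2 + diff(tr$y)^2)) <= 5
#' @export
simulate_trajectory <- function(arena, start = NULL, n_steps = 4000,
                                v_max = 5, dt = 1,
                                heading_policy = c("wander", "uniform", "fixed"),
                                turn_range = 30, seed = NULL) {
  stopifnot(inherits(arena, "vpc_arena"))
  n_steps <- check_count(n_steps, "n_steps", lower = 1L)
  heading_policy <- match.arg(heading_policy)
  if (is.null(start)) start <- c(arena$width / 2, arena$height / 2)
  if (!all(in_arena(arena, start[1], start[2]))) {
    stop("`start` must lie inside the arena", call. = FALSE)
  }

  with_seed_opt(seed, {
    x <- y <- heading <- speed <- numeric(n_steps)
    st <- agent_state(start[1], start[2], heading = runif(1, 0, 360),
                      speed = v_max / 2)
    for (t in seq_len(n_steps)) {
      st <- step_agent(st, arena, v_max = v_max, dt = dt,
                       heading_policy = heading_policy,
                       turn_range = turn_range)
      x[t] <- st$x; y[t] <- st$y
      heading[t] <- st$heading; speed[t] <- st$speed
    }
    structure(
      data.frame(t = seq_len(n_steps), x = x, y = y,
                 heading = heading, speed = speed),
      arena = arena, class = c("trajectory", "data.frame")
    )
  })
}

#' Read and write trajectories as CSV
#'
#' CSV with header `t,x,y,heading,speed`, one row per location-update step.
#'
#' @param trajectory a `trajectory` from [simulate_trajectory()].
#' @param path file path.
#' @return `read_trajectory_csv` returns a `trajectory` data.frame;
#'   `write_trajectory_csv` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[c("t", "x", "y", "heading", "speed")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "heading", "speed")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s must have columns %s", basename(path),
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  structure(df[need], class = c("trajectory", "data.frame"))
}
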