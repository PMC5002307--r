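test_that("run configuration validates and aggregates errors", {
  cfg <- run_config()
  expect_equal(cfg$n_steps, 4000L)
  expect_equal(cfg$frt, 0.2)
  expect_equal(cfg$sigma_d2, 25)
  # sub-seeds derive deterministically from the master seed
  expect_identical(run_config(seed = 5)$trajectory_seed,
                   run_config(seed = 5)$trajectory_seed)

  err <- tryCatch(run_config(d_min = 15, d_max = 10, frt = 2, n_steps = 0),
                  error = function(e) conditionMessage(e))
  expect_match(err, "d_min")
  expect_match(err, "frt")
  expect_match(err, "n_steps")
})

test_that("a single-step run with a nonempty percept recruits one cell", {
  cfg <- run_config(n_steps = 1, seed = 2)
  res <- run_single(cfg)
  expect_equal(res$n_vpcs, 1L)
  expect_equal(res$population$cells[[1]]$cell_id, 0L)
  expect_equal(res$n_vpcs, length(res$population))
})

test_that("runs are deterministic given the configuration", {
  cfg <- run_config(n_steps = 300, seed = 3)
  a <- run_single(cfg)
  b <- run_single(cfg)
  expect_identical(a$steps, b$steps)
  expect_identical(a$n_vpcs, b$n_vpcs)
  expect_identical(as.data.frame(a$field), as.data.frame(b$field))
  expect_identical(a$population$cells, b$population$cells)
})

test_that("the lean run loop matches the step-wise public operations", {
  cfg <- run_config(n_steps = 200, seed = 6)
  res <- run_single(cfg)

  ar <- arena(cfg$width, cfg$height)
  field <- generate_landmark_field(ar, cfg$n_landmarks, cfg$saliency_mode,
                                   seed = cfg$landmark_seed)
  traj <- simulate_trajectory(ar, n_steps = cfg$n_steps, v_max = cfg$v_max,
                              dt = cfg$dt, heading_policy = cfg$heading_policy,
                              seed = cfg$trajectory_seed)
  pop <- new_population(firing_params(cfg$sigma_d2, cfg$sigma_theta2,
                                      cfg$w_d, cfg$w_theta, cfg$frt),
                        cfg$weight_mode)
  for (t in seq_len(cfg$n_steps)) {
    pc <- perceive(c(traj$x[t], traj$y[t]), field, cfg$d_min, cfg$d_max,
                   step = t)
    out <- maybe_recruit(pop, pc)
    pop <- out$population
    expect_equal(out$recruited, res$steps$recruited[t])
    if (pc$n > 0 && length(pop) > 1 && !out$recruited) {
      expect_equal(out$winner_rate, res$steps$winner_rate[t],
                   tolerance = 1e-12)
    }
  }
  expect_equal(length(pop), res$n_vpcs)
})

test_that("sweeps hold the layout fixed within a replicate and tidy up", {
  base <- run_config(n_steps = 150, seed = 1)
  tab <- sweep(base, "frt", c(0.1, 0.4), replicates = 2)
  expect_s3_class(tab, "vpc_sweep")
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$value, c("0.1", "0.4"))
  # same replicate -> same seeds across values
  expect_equal(tab$landmark_seed[tab$replicate == 1][1],
               tab$landmark_seed[tab$replicate == 1][2])
  # different replicates -> different trajectory seeds
  expect_false(tab$trajectory_seed[tab$replicate == 1][1] ==
                 tab$trajectory_seed[tab$replicate == 2][1])

  # a degenerate sweep reproduces run_single under the same sub-seeds
  one <- sweep(base, "frt", 0.2, replicates = 1)
  cfg <- run_config(n_steps = 150, seed = 1,
                    landmark_seed = one$landmark_seed[1],
                    trajectory_seed = one$trajectory_seed[1])
  expect_equal(one$n_vpcs[1], run_single(cfg)$n_vpcs)

  expect_error(sweep(base, "bogus", 1), "unknown sweep parameter")
  expect_error(sweep(base, "annulus", c(5, 10)), "list")
})

test_that("trend checks compare replicate means in the stated direction", {
  fake <- function(means) {
    do.call(rbind, lapply(seq_along(means), function(i) {
      data.frame(param = "frt", value = as.character(i), value_index = i,
                 replicate = 1, n_vpcs = means[i])
    }))
  }
  expect_true(trend_check(fake(c(30, 50, 65, 80)), "increasing")$pass)
  expect_false(trend_check(fake(c(30, 50, 45, 80)), "increasing")$pass)
  expect_true(trend_check(fake(c(80, 65, 50)), "decreasing")$pass)
  expect_false(trend_check(fake(c(80, 85, 50)), "decreasing")$pass)
  # gaps 15, 9, 4 shrink: saturating growth
  expect_true(trend_check(fake(c(20, 35, 44, 48)), "saturating")$pass)
  expect_false(trend_check(fake(c(20, 35, 50, 70)), "saturating")$pass)
  expect_false(trend_check(fake(c(20, 35, 30, 48)), "saturating")$pass)
})

test_that("rate_maps requires kept percepts and covers all cells", {
  cfg <- run_config(n_steps = 200, seed = 8)
  light <- run_single(cfg, keep_percepts = FALSE)
  expect_error(rate_maps(light), "keep_percepts")

  full <- run_single(cfg)
  maps <- rate_maps(full, resolution = 2)
  expect_length(maps$cell_maps, full$n_vpcs)
  expect_s3_class(maps$population, "rate_map")
  expect_equal(dim(maps$population$grid), c(20, 20))
})
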