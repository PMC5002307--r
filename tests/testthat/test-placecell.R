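test_that("saliency weights normalize over the whole place code", {
  equal4 <- new_place_code(id = 0:3, saliency = rep(2, 4),
                           bearing = rep(0, 4), distance = rep(12, 4))
  expect_equal(unname(landmark_weights(equal4)), rep(0.25, 4))

  skew <- new_place_code(id = 0:1, saliency = c(1, 3),
                         bearing = c(0, 90), distance = c(11, 13))
  expect_equal(unname(landmark_weights(skew)), c(0.25, 0.75))

  expect_equal(unname(landmark_weights(single_code())), 1)
  expect_length(landmark_weights(new_place_code()), 0)

  withr::with_seed(13, {
    for (i in 1:20) {
      code <- random_code(n_max = 5)
      if (code$n == 0) next
      expect_equal(sum(landmark_weights(code)), 1, tolerance = 1e-12)
      expect_true(all(landmark_weights(code) > 0))
    }
  })
})

test_that("landmark matching is id intersection", {
  stored <- new_place_code(id = 1:3, saliency = rep(1, 3),
                           bearing = c(0, 10, 20), distance = c(11, 12, 13))
  cell <- recruit_cell(stored, cell_id = 0L)
  current <- new_place_code(id = 2:4, saliency = rep(1, 3),
                            bearing = c(0, 10, 20), distance = c(11, 12, 13))
  expect_setequal(match_landmarks(cell, current), 2:3)
  expect_length(match_landmarks(cell, new_place_code()), 0)
  expect_length(match_landmarks(cell, stored), 3)
})

test_that("firing rate reproduces the closed-form analytic cases", {
  p <- firing_params(sigma_d2 = 25, sigma_theta2 = 100,
                     w_d = 1, w_theta = 1, frt = 0.2)

  # exact self-recall: every term has zero exponent, weights sum to 1
  stored <- new_place_code(id = 0:4, saliency = runif(5, 0.5, 2),
                           bearing = runif(5, 0, 360),
                           distance = runif(5, 10, 15))
  cell <- recruit_cell(stored, 0L)
  expect_equal(firing_rate(cell, stored, p), 1, tolerance = 1e-12)

  # single matched landmark, 5 m distance error
  cell1 <- recruit_cell(single_code(distance = 12), 0L)
  expect_equal(firing_rate(cell1, single_code(distance = 17), p),
               exp(-1), tolerance = 1e-12)

  # bearing error across north wraps: 350 vs 10 is 20 degrees
  cellw <- recruit_cell(single_code(bearing = 350), 0L)
  expect_equal(firing_rate(cellw, single_code(bearing = 10), p),
               exp(-4), tolerance = 1e-12)

  # indicators disable both mismatch terms
  p0 <- firing_params(25, 100, w_d = 0, w_theta = 0, frt = 0.2)
  expect_equal(firing_rate(cell1, single_code(bearing = 123, distance = 3), p0),
               1, tolerance = 1e-12)

  # no matched landmark, or nothing perceived -> silent
  other <- single_code(id = 99L)
  expect_equal(firing_rate(cell1, other, p), 0)
  expect_equal(firing_rate(cell1, new_place_code(), p), 0)
})

test_that("firing rate stays in [0, 1] and is monotone in the model knobs", {
  withr::with_seed(99, {
    for (i in 1:100) {
      stored <- random_code()
      current <- random_code()
      p <- random_params()
      if (stored$n == 0) next
      cell <- recruit_cell(stored, 0L)
      for (wm in c("current", "matched")) {
        f <- firing_rate(cell, current, p, weight_mode = wm)
        expect_gte(f, 0)
        expect_lte(f, 1 + 1e-12)
      }
    }
  })

  p <- firing_params()
  cell <- recruit_cell(single_code(distance = 12, bearing = 0), 0L)
  # non-increasing in |distance error|
  f_d <- sapply(c(0, 1, 2, 4, 8), function(dd) {
    firing_rate(cell, single_code(distance = 12 + dd), p)
  })
  expect_true(all(diff(f_d) < 0))
  # non-increasing in wrapped |bearing error|
  f_th <- sapply(c(0, 5, 20, 90, 179), function(dth) {
    firing_rate(cell, single_code(bearing = dth), p)
  })
  expect_true(all(diff(f_th) < 0))
  # widening either firing-field factor can only raise the rate
  probe <- single_code(distance = 15, bearing = 20)
  f_base <- firing_rate(cell, probe, firing_params(25, 100))
  expect_gt(firing_rate(cell, probe, firing_params(100, 100)), f_base)
  expect_gt(firing_rate(cell, probe, firing_params(25, 400)), f_base)
})

test_that("population evaluation picks the maximal-rate cell deterministically", {
  p <- firing_params()
  pop <- new_population(p)
  ev <- evaluate_population(pop, single_code())
  expect_length(ev$rates, 0)
  expect_true(is.na(ev$winner_id))

  pc_a <- single_code(id = 1L)
  pc_b <- single_code(id = 2L, bearing = 90)
  pop$cells <- list(recruit_cell(pc_a, 0L), recruit_cell(pc_b, 1L))

  ev <- evaluate_population(pop, pc_a)
  expect_equal(ev$winner_id, 0L)
  expect_equal(ev$winner_rate, 1)

  # exact tie (identical stored codes): lowest cell id wins
  pop$cells <- list(recruit_cell(pc_a, 0L), recruit_cell(pc_a, 1L))
  expect_equal(evaluate_population(pop, pc_a)$winner_id, 0L)
})

test_that("recruitment fires exactly when the winner is strictly below FRT", {
  p <- firing_params(frt = 0.2)
  pop <- new_population(p)

  # bootstrap: first nonempty percept always recruits
  out <- maybe_recruit(pop, single_code())
  expect_true(out$recruited)
  expect_equal(out$cell_id, 0L)
  expect_length(out$population, 1)

  # empty percepts never recruit
  out2 <- maybe_recruit(out$population, new_place_code())
  expect_false(out2$recruited)
  expect_length(out2$population, 1)

  # winner above threshold: no recruitment
  out3 <- maybe_recruit(out$population, single_code())
  expect_false(out3$recruited)
  expect_equal(out3$winner_rate, 1)

  # winner exactly at FRT: "below" is strict, so no recruitment
  probe <- single_code(distance = 12 + sqrt(-25 * log(0.2)))
  tied <- out$population
  tied$params <- firing_params(frt = firing_rate(tied$cells[[1]], probe,
                                                 tied$params))
  out4 <- maybe_recruit(tied, probe)
  expect_false(out4$recruited)
  expect_equal(out4$winner_rate, tied$params$frt)

  # strictly below: recruits, and ids follow recruitment order
  out5 <- maybe_recruit(out$population, single_code(id = 5L))
  expect_true(out5$recruited)
  expect_equal(out5$cell_id, 1L)
})

test_that("firing rate matches the brute-force oracle on random instances", {
  withr::with_seed(7, {
    for (i in 1:200) {
      stored <- random_code()
      current <- random_code()
      if (stored$n == 0) next
      p <- random_params()
      cell <- recruit_cell(stored, 0L)
      for (wm in c("current", "matched")) {
        expect_equal(firing_rate(cell, current, p, weight_mode = wm),
                     oracle_firing_rate(stored, current, p, weight_mode = wm),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("the VPC registry JSON round-trips the population", {
  withr::with_seed(31, {
    pop <- new_population(firing_params())
    for (k in 1:3) {
      code <- random_code(n_max = 5)
      while (code$n == 0) code <- random_code(n_max = 5)
      code$step <- k
      pop$cells[[k]] <- recruit_cell(code, k - 1L, recruited_at = k)
    }
  })
  path <- withr::local_tempfile(fileext = ".json")
  write_vpc_registry(pop, path)
  back <- read_vpc_registry(path)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back$cells[[k]]$cell_id, pop$cells[[k]]$cell_id)
    expect_equal(back$cells[[k]]$recruited_at, pop$cells[[k]]$recruited_at)
    expect_equal(back$cells[[k]]$code$id, pop$cells[[k]]$code$id)
    expect_equal(back$cells[[k]]$code$distance, pop$cells[[k]]$code$distance)
    expect_equal(back$cells[[k]]$code$bearing, pop$cells[[k]]$code$bearing)
  }
})
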