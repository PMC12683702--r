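km <- 1 / (6371 * pi / 180)  # degrees of latitude per km

test_that("closure expansion captures reefs by radius and ground", {
  reefs <- make_reefs(lon = c(0, 0, 0), lat = c(0, 1.5 * km, 6 * km),
                      closure = c(1L, NA, NA))
  g <- c(0.5, 0.2, 0.2)
  res <- expand_closures(reefs, g, radius_km = 2, same_ground_only = TRUE)
  expect_equal(res$g, c(0.5, 0.5, 0.2))
  expect_equal(res$newly_included, 2L)
  expect_equal(res$g_changed_up, 2L)
  expect_length(res$g_changed_down, 0)

  # zero radius captures nothing
  res0 <- expand_closures(reefs, g, radius_km = 0, same_ground_only = TRUE)
  expect_equal(res0$g, g)
  expect_length(res0$newly_included, 0)

  # a different fishing ground blocks the 2-km capture
  other <- make_reefs(lon = c(0, 0), lat = c(0, 1.5 * km),
                      ground = c(1L, 2L), closure = c(1L, NA))
  resg <- expand_closures(other, c(0.5, 0.2), radius_km = 2,
                          same_ground_only = TRUE)
  expect_equal(resg$g, c(0.5, 0.2))
  # ... and is ignored when ground boundaries are relaxed
  resg5 <- expand_closures(other, c(0.5, 0.2), radius_km = 5,
                           same_ground_only = FALSE)
  expect_equal(resg5$g, c(0.5, 0.5))
})

test_that("multiply-captured reefs average the capturing closures' rates", {
  reefs <- make_reefs(lon = c(0, 0, 0), lat = c(0, 1 * km, 2 * km),
                      closure = c(1L, NA, 2L))
  g <- c(0.4, 0.2, 0.6)
  res <- expand_closures(reefs, g, radius_km = 1.5, same_ground_only = TRUE)
  expect_equal(res$g[2], 0.5)  # mean of 0.4 and 0.6
  # the two original closure reefs are out of each other's radius: unchanged
  expect_equal(res$g[c(1, 3)], c(0.4, 0.6))

  expect_error(expand_closures(make_reefs(lon = 0, lat = 0), 0.3,
                               radius_km = 2),
               class = "reefstates_structural_error")
})

test_that("the newly-included set grows with radius", {
  world <- default_world(seed = 4, n_reefs = 40)
  sys <- build_system(world$reefs, world$K, world$N, scenario = "medium")
  small <- expand_closures(world$reefs, sys$g, radius_km = 2,
                           same_ground_only = FALSE)
  large <- expand_closures(world$reefs, sys$g, radius_km = 5,
                           same_ground_only = FALSE)
  expect_true(all(small$newly_included %in% large$newly_included))
})

test_that("water-quality improvement rescales mortality multiplicatively", {
  expect_equal(improve_water_quality(0.1, 25), 0.075)
  expect_equal(improve_water_quality(c(0.2, 0.4), 100), c(0, 0))
  d <- c(0.1, 0.2, 0.3)
  masked <- improve_water_quality(d, 50, subset = 2L)
  expect_equal(masked, c(0.1, 0.1, 0.3))
  expect_error(improve_water_quality(d, 0),
               class = "reefstates_parameter_error")
  expect_error(improve_water_quality(d, 150),
               class = "reefstates_parameter_error")
  # never increases mortality
  withr::with_seed(3, {
    for (i in 1:10) {
      d <- runif(8, 0, 1)
      expect_true(all(improve_water_quality(d, runif(1, 1, 100)) <= d))
    }
  })
})

test_that("intervention specs validate their required fields", {
  expect_error(intervention("expand_closures"),
               class = "reefstates_parameter_error")
  expect_error(intervention("water_quality", wq_percent = 150),
               class = "reefstates_parameter_error")
  expect_error(intervention("combined", radius_km = 2),
               class = "reefstates_parameter_error")
  expect_error(intervention("water_quality", wq_percent = 10,
                            wq_scope = "scattered"),
               class = "reefstates_parameter_error")
  spec <- intervention("combined", radius_km = 2, wq_percent = 25)
  expect_equal(spec$label, "M3-2km+25%")
  expect_true(spec$same_ground_only)  # 2-km default respects grounds
  spec5 <- intervention("expand_closures", radius_km = 5)
  expect_false(spec5$same_ground_only)
  expect_equal(length(default_interventions()), 6)
})

test_that("combined interventions commute because g and d are disjoint", {
  world <- default_world(seed = 5, n_reefs = 30)
  sys <- build_system(world$reefs, world$K, world$N, scenario = "medium")
  dist <- reef_distances(world$reefs)

  combined <- apply_intervention(sys, world$reefs,
                                 intervention("combined", radius_km = 2,
                                              wq_percent = 25), dist)
  exp_first <- apply_intervention(sys, world$reefs,
                                  intervention("expand_closures",
                                               radius_km = 2), dist)
  wq_after <- apply_intervention(exp_first$system, world$reefs,
                                 intervention("water_quality",
                                              wq_percent = 25), dist)
  wq_first <- apply_intervention(sys, world$reefs,
                                 intervention("water_quality",
                                              wq_percent = 25), dist)
  exp_after <- apply_intervention(wq_first$system, world$reefs,
                                  intervention("expand_closures",
                                               radius_km = 2), dist)
  expect_equal(combined$system$g, wq_after$system$g)
  expect_equal(combined$system$d, wq_after$system$d)
  expect_equal(combined$system$g, exp_after$system$g)
  expect_equal(combined$system$d, exp_after$system$d)

  # water quality alone leaves grazing untouched
  expect_equal(wq_first$system$g, sys$g)
  # closure expansion alone leaves mortality untouched
  expect_equal(exp_first$system$d, sys$d)
})

test_that("scattered water quality touches exactly the 2-km expansion set", {
  world <- default_world(seed = 1, n_reefs = 40)
  sys <- build_system(world$reefs, world$K, world$N, scenario = "medium")
  dist <- reef_distances(world$reefs)
  scat <- apply_intervention(sys, world$reefs,
                             intervention("water_quality", wq_percent = 25,
                                          wq_scope = "scattered",
                                          radius_km = 2), dist)
  expansion <- expand_closures(world$reefs, sys$g, dist, radius_km = 2,
                               same_ground_only = TRUE)
  idx <- match(expansion$newly_included, world$reefs$reef_id)
  changed <- which(scat$system$d != sys$d)
  expect_setequal(changed, idx)
  if (length(idx)) {
    expect_equal(scat$system$d[idx], sys$d[idx] * 0.75)
  }
  expect_equal(scat$system$g, sys$g)
})

test_that("an empty scattered set leaves mortality unchanged", {
  # isolated closure reef: nothing within 2 km
  reefs <- make_reefs(lon = c(0, 1), lat = c(0, 1), closure = c(1L, NA))
  sys <- build_system(reefs, matrix(0.1, 2, 2), matrix(0.1, 2, 2))
  scat <- apply_intervention(sys, reefs,
                             intervention("water_quality", wq_percent = 25,
                                          wq_scope = "scattered",
                                          radius_km = 2))
  expect_equal(scat$system$d, sys$d)
  expect_length(scat$newly_included, 0)
})
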