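test_that("simulation is reproducible and synchronic by construction", {
  cfg <- simulation_config(n_species = 2, n_characters = 3, seed = 1)
  s1 <- simulate_schedules(cfg)
  s2 <- simulate_schedules(cfg)
  expect_identical(s1, s2)
  expect_equal(normalize_schedule(s1[[1]]), normalize_schedule(s1[[2]]))
})

test_that("injected shifts move exactly the named onsets", {
  cfg <- simulation_config(n_species = 2, n_characters = 5, seed = 2,
                           heterochronies = list(list(species = 1,
                                                      characters = 3,
                                                      shift = 20)))
  sch <- simulate_schedules(cfg)
  p1 <- normalize_schedule(sch[[1]])
  p2 <- normalize_schedule(sch[[2]])
  expect_equal(p1[3] - p2[3], 20)
  expect_equal(p1[-3], p2[-3])
})

test_that("configuration errors are rejected up front", {
  expect_error(simulation_config(missing_rate = 1),
               class = "ontochron_config_error")
  expect_error(simulation_config(n_characters = 3, onsets = c(10, 20)),
               class = "ontochron_config_error")
  expect_error(simulation_config(heterochronies = list(list(species = 1))),
               class = "ontochron_config_error")
  cfg <- simulation_config(n_characters = 2, onsets = c(95, 50),
                           heterochronies = list(list(species = 1,
                                                      characters = 1,
                                                      shift = 150)))
  expect_error(simulate_schedules(cfg), class = "ontochron_config_error")
})

test_that("onsets shifted past 100% stay absent until the terminal row", {
  cfg <- simulation_config(n_species = 2, n_characters = 2,
                           onsets = c(40, 60),
                           heterochronies = list(list(species = 1,
                                                      characters = 2,
                                                      shift = 80)))
  m <- build_matrix_from_schedules(simulate_schedules(cfg),
                                   time_frame(c(25, 50, 75)))
  expect_equal(unname(m$states["Sim_sp1_75%", 2]), 0L)   # onset at 140
  expect_equal(unname(m$states["Sim_sp1_100%", 2]), 1L)  # terminal repertoire
})

test_that("a noise-free injected delay is recovered exactly", {
  # the minimal two-species scenario: the delayed species is recovered,
  # but with a single peer the late/advanced polarity is symmetric, so the
  # mirrored report halves precision
  cfg2 <- simulation_config(n_species = 2, n_characters = 6,
                            onsets = c(10, 30, 45, 60, 80, 95),
                            heterochronies = list(list(species = 1,
                                                       characters = 3,
                                                       shift = 20)))
  out2 <- recovery_experiment(cfg2, time_frame(c(25, 50, 75)))
  expect_equal(out2$recall, 1)
  # three species polarize the comparison and remove the mirror events
  cfg3 <- simulation_config(n_species = 3, n_characters = 6,
                            onsets = c(10, 30, 45, 60, 80, 95),
                            heterochronies = list(list(species = 1,
                                                       characters = 3,
                                                       shift = 20)))
  out3 <- recovery_experiment(cfg3, time_frame(c(25, 50, 75)))
  expect_equal(out3$recall, 1)
  expect_equal(out3$precision, 1)
  # the strict late set at the straddled landmark is exactly the injected set
  m <- build_matrix_from_schedules(simulate_schedules(cfg3),
                                   time_frame(c(25, 50, 75)))
  expect_equal(late_set(m, "Sim_sp1", 50), 3L)
})

test_that("recovery without injections is vacuously perfect", {
  cfg <- simulation_config(n_species = 3, n_characters = 10, seed = 9)
  out <- recovery_experiment(cfg, time_frame(c(25, 50, 75)))
  expect_equal(out$precision, 1)
  expect_equal(out$recall, 1)
  expect_equal(out$n_reported, 0L)
})

test_that("recall does not increase with the missing-data rate (property)", {
  frame <- time_frame(c(25, 50, 75))
  # masked matrices have few repeated rows, so force the heuristic with a
  # light ratchet rather than exact enumeration of noisy patterns
  opts <- search_options(mode = "heuristic", ratchet_iter = 10L, ratchet_k = 5L)
  recalls <- vapply(c(0, 0.2, 0.45), function(rate) {
    hits <- vapply(1:6, function(seed) {
      cfg <- simulation_config(n_species = 4, n_characters = 12, seed = seed,
                               missing_rate = rate,
                               heterochronies = list(list(species = 2,
                                                          characters = 4:6,
                                                          shift = 35)))
      recovery_experiment(cfg, frame, opts)$recall
    }, 0)
    mean(hits)
  }, 0)
  expect_true(all(diff(recalls) <= 1e-9))
})
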