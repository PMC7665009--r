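test_that("normalization maps degree-days linearly onto percent", {
  s <- staging_schedule("X_y", c(100, 0, 400, NA), t0 = 0, t100 = 400)
  expect_equal(normalize_schedule(s), c(25, 0, 100, NA))
  expect_error(staging_schedule("X_y", c(10), t0 = 5, t100 = 5),
               class = "ontochron_span_error")
  # events after the boundary event exceed 100
  s2 <- staging_schedule("X_y", c(500), t0 = 100, t100 = 400)
  expect_equal(normalize_schedule(s2), 400 / 3)
})

test_that("matrix building applies the closed-boundary threshold rule", {
  s1 <- staging_schedule("A_a", c(30, 25, NA) / 100 * 400, t0 = 0, t100 = 400)
  s2 <- staging_schedule("B_b", c(30, 25, 10) / 100 * 400, t0 = 0, t100 = 400)
  m <- build_matrix_from_schedules(list(s1, s2), time_frame(c(25, 50)))
  g <- function(otu) unname(m$states[otu, ])
  expect_equal(g("A_a_25%")[1], 0L)      # onset 30% invisible at 25
  expect_equal(g("A_a_50%")[1], 1L)      # visible at 50
  expect_equal(g("A_a_25%")[2], 1L)      # onset exactly at the landmark counts
  expect_equal(g("A_a_0%"), c(0L, 0L, 0L))     # 0% definitionally pre-onset
  expect_true(is.na(g("A_a_25%")[3]))    # unknown onset stays unknown
  expect_true(is.na(g("A_a_100%")[3]))
  expect_equal(g("A_a_100%")[1:2], c(1L, 1L))
})

test_that("states are cumulative across landmarks (property)", {
  set.seed(21)
  for (i in 1:10) {
    cfg <- simulation_config(n_species = 3, n_characters = 15, seed = i)
    m <- build_matrix_from_schedules(simulate_schedules(cfg),
                                     time_frame(c(10, 25, 50, 75)))
    for (sp in unique(m$species)) {
      rows <- m$states[m$species == sp, , drop = FALSE]
      rows <- rows[order(m$landmark[m$species == sp]), , drop = FALSE]
      d <- diff(rows)
      expect_true(all(d >= 0, na.rm = TRUE))
    }
  }
})

test_that("staging CSVs load into per-species schedules", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,character_index,onset_degdays",
               "A_a,1,50", "A_a,3,200", "B_b,1,80", "B_b,2,120", "B_b,3,NA"),
             tf)
  bounds <- data.frame(species = c("A_a", "B_b"), t0 = c(0, 0),
                       t100 = c(400, 480))
  sched <- read_staging(tf, bounds)
  expect_named(sched, c("A_a", "B_b"))
  expect_equal(normalize_schedule(sched$A_a), c(12.5, NA, 50))
  expect_equal(normalize_schedule(sched$B_b), c(80, 120, NA) / 480 * 100)
  expect_error(read_staging(tf, bounds[1, ]), class = "ontochron_parse_error")
})

test_that("frame selection keeps the right OTUs and reports absentees", {
  m <- load_fixture_table1()
  expect_equal(nrow(select_frame(m, time_frame(c(25, 50, 75)))$states), 20L)
  expect_equal(nrow(select_frame(m, time_frame(c(5, 10, 20, 25, 50, 75)))$states), 32L)
  err <- tryCatch(select_frame(m, time_frame(30)), error = identity)
  expect_s3_class(err, "ontochron_lookup_error")
  expect_match(conditionMessage(err), "30")
  expect_error(time_frame(numeric(0)), class = "ontochron_frame_error")
  expect_error(time_frame(c(0, 50)), class = "ontochron_frame_error")
})

test_that("the synchronic expectation tree is the landmark caterpillar", {
  tr <- synchronic_tree(c("Sp_1", "Sp_2"), time_frame(c(25, 50, 75)))
  expect_equal(sort(tr$tip.label),
               sort(as.vector(outer(c("Sp_1_", "Sp_2_"),
                                    c(0, 25, 50, 75, 100),
                                    function(a, b) paste0(a, b, "%")))))
  # each landmark forms one nested cluster with everything after it
  expected <- from_newick(paste0(
    "(Sp_1_0%,Sp_2_0%,(Sp_1_25%,Sp_2_25%,(Sp_1_50%,Sp_2_50%,",
    "(Sp_1_75%,Sp_2_75%,(Sp_1_100%,Sp_2_100%)))));"))
  expect_equal(ontochron:::.canonical_key(tr),
               ontochron:::.canonical_key(expected))
  ladder <- synchronic_tree("Solo_sp", time_frame(c(50)))
  expect_equal(length(ladder$tip.label), 3L)
  expect_error(synchronic_tree(character(0), time_frame(50)),
               class = "ontochron_frame_error")
})
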