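test_that("fitch_length counts single origins and ignores uninformative cells", {
  m <- character_matrix(matrix(c(0, 0, 1, 1,      # one origin
                                 NA, NA, NA, NA), # no information
                               4, 2, dimnames = list(paste0("S", 1:4, "_x_", 1:4, "%"), NULL)))
  tr <- from_newick("((S1_x_1%,S2_x_2%),(S3_x_3%,S4_x_4%));")
  expect_equal(fitch_length(tr, m), 1L)
  expect_equal(fitch_length(tr, subset_otus(m, 1:4)), 1L)
  m0 <- character_matrix(matrix(NA_integer_, 4, 1,
                                dimnames = list(rownames(m$states), NULL)))
  expect_equal(fitch_length(tr, m0), 0L)
  expect_error(fitch_length(from_newick("(A,(B,C));"), m),
               class = "ontochron_label_error")
})

test_that("fitch_length equals the per-character set-operation oracle (property)", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    m <- random_matrix(n, sample(3:12, 1), miss = 0.15, all_zero_row = FALSE)
    tr <- ape::rtree(n, tip.label = sample(rownames(m$states)), br = NULL)
    expect_equal(fitch_length(tr, m), oracle_fitch(tr, m))
    # and a third route through phangorn on the same instance
    pd <- ontochron:::.as_phyDat(m$states)
    expect_equal(fitch_length(tr, m), phangorn::parsimony(tr, pd))
  }
})

test_that("per-character step bounds follow definite state counts", {
  expect_equal(char_min_steps(c(rep(0, 4), rep(1, 16))), 1L)
  expect_equal(char_max_steps(c(rep(0, 4), rep(1, 16))), 4L)
  expect_equal(char_min_steps(rep(1, 5)), 0L)
  expect_equal(char_max_steps(rep(1, 5)), 0L)
  expect_equal(char_min_steps(c(0, 1, NA, NA)), 1L)
  expect_equal(char_max_steps(c(0, 1, NA, NA)), 1L)
})

test_that("ACCTRAN places a single origin on the subtending branch", {
  m <- character_matrix(matrix(c(0, 0, 1, 1), 4, 1,
                               dimnames = list(paste0("S", 1:4, "_x_", 1:4, "%"), NULL)))
  tr <- from_newick("((S1_x_1%,S2_x_2%),(S3_x_3%,S4_x_4%));")
  ch <- acctran_changes(tr, m)
  expect_equal(nrow(ch$changes), 1L)
  expect_equal(ch$changes$direction, "gain")
  clade <- ontochron:::.node_clades(tr)[[ch$changes$child]]
  expect_setequal(clade, c("S3_x_3%", "S4_x_4%"))
})

test_that("ACCTRAN favors an early gain with reversal over parallel gains", {
  # A and B carry the character, C and the root-adjacent D do not; the
  # stem gain with a reversal in C ties with two parallel gains in A and B
  m <- character_matrix(matrix(c(1, 1, 0, 0), 4, 1,
                               dimnames = list(c("A_x_1%", "B_x_2%",
                                                 "C_x_3%", "D_x_4%"), NULL)))
  tr <- from_newick("(D_x_4%,(A_x_1%,(B_x_2%,C_x_3%)));")
  ch <- acctran_changes(tr, m)
  expect_equal(sort(ch$changes$direction), c("gain", "loss"))
  gain <- ch$changes[ch$changes$direction == "gain", ]
  expect_setequal(ontochron:::.node_clades(tr)[[gain$child]],
                  c("A_x_1%", "B_x_2%", "C_x_3%"))
  loss <- ch$changes[ch$changes$direction == "loss", ]
  expect_equal(ontochron:::.node_clades(tr)[[loss$child]], "C_x_3%")
})

test_that("ACCTRAN change totals equal the rooted Fitch length (property)", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    m <- random_matrix(n, sample(3:10, 1), miss = 0.2)
    tr <- ape::rtree(n, tip.label = sample(rownames(m$states)), br = NULL)
    ch <- acctran_changes(tr, m)
    expect_equal(nrow(ch$changes), fitch_length(tr, m, root_state = 0))
    # per-character counts sit within the analytic bounds; fixing the root
    # of an arbitrary binary tree to all-absent can add one step per root
    # edge over the unrooted per-character maximum
    per_char <- table(factor(ch$changes$character, levels = seq_len(ncol(m$states))))
    for (k in seq_len(ncol(m$states))) {
      expect_gte(per_char[k], char_min_steps(m$states[, k]))
      expect_lte(per_char[k], char_max_steps(m$states[, k]) + 2L)
    }
  }
})

test_that("on ancestor-rooted search trees ACCTRAN counts obey the step bounds", {
  m <- select_frame(load_fixture_table1(), time_frame(c(25, 50, 75)))
  res <- branch_and_bound_search(m)
  for (tr in res$trees) {
    ch <- acctran_changes(tr, m)
    expect_equal(nrow(ch$changes), res$best_length)
    per_char <- table(factor(ch$changes$character, levels = 1:53))
    for (k in 1:53) {
      expect_gte(per_char[k], char_min_steps(m$states[, k]))
      expect_lte(per_char[k], char_max_steps(c(m$states[, k], 0L)))
    }
  }
})

test_that("identical all-absent leaves condense into one polytomy", {
  s <- matrix(0L, 4, 3, dimnames = list(paste0("S", 1:4, "_x_0%"), NULL))
  m <- character_matrix(s, validate = FALSE)
  tr <- from_newick("((S1_x_0%,S2_x_0%),(S3_x_0%,S4_x_0%));")
  for (rule in c("min-zero", "max-zero")) {
    out <- condense_and_dedupe(list(tr), m, rule)
    expect_length(out, 1L)
    expect_equal(out[[1]]$Nnode, 1L)
  }
  # two trees identical after collapse deduplicate
  tr2 <- from_newick("((S1_x_0%,S3_x_0%),(S2_x_0%,S4_x_0%));")
  expect_length(condense_and_dedupe(list(tr, tr2), m, "min-zero"), 1L)
})

test_that("exact search scores obey the analytic envelope (properties)", {
  set.seed(51)
  for (i in 1:8) {
    m <- random_matrix(sample(4:7, 1), sample(4:8, 1), miss = 0.1)
    res <- branch_and_bound_search(m)
    s <- rbind(m$states, 0L)
    M <- sum(apply(s, 2, char_min_steps))
    G <- sum(apply(s, 2, char_max_steps))
    expect_gte(res$best_length, M)
    expect_lte(res$best_length, G)
    # removing a character never increases the best length
    drop1 <- character_matrix(m$states[, -1, drop = FALSE])
    expect_lte(branch_and_bound_search(drop1)$best_length, res$best_length)
    # duplicating a row never changes the best length
    dup <- m$states[c(seq_len(nrow(m$states)), nrow(m$states)), ]
    rownames(dup)[nrow(dup)] <- sub("_[0-9]+%$", "_99%", rownames(dup)[nrow(dup)])
    dupm <- character_matrix(dup)
    dupm$states[nrow(dup), ] <- m$states[nrow(m$states), ]
    expect_equal(branch_and_bound_search(dupm)$best_length, res$best_length)
  }
})

test_that("heuristic search is deterministic and never beats the optimum", {
  set.seed(61)
  m <- random_matrix(7, 10, miss = 0.1)
  opts <- search_options(seed = 99)
  h1 <- heuristic_search(m, opts)
  h2 <- heuristic_search(m, opts)
  expect_equal(h1$best_length, h2$best_length)
  expect_equal(vapply(h1$trees, ontochron:::.canonical_key, ""),
               vapply(h2$trees, ontochron:::.canonical_key, ""))
  expect_gte(h1$best_length, branch_and_bound_search(m)$best_length)
})

test_that("ensemble indices use truncation and expose both conventions", {
  m <- load_fixture_table1()
  res <- branch_and_bound_search(select_frame(m, time_frame(c(25, 50, 75))))
  fit <- ensemble_indices(res, select_frame(m, time_frame(c(25, 50, 75))))
  expect_equal(fit$M, 53L)
  expect_equal(fit$S, 62L)
  expect_equal(fit$ci, 53 / 62)
  expect_equal(fit$reported_ci, 0.85)
  expect_true(fit$ci_informative <= 1 && fit$ci_informative > 0)
  # truncation, not rounding: 53/71 must report 0.74
  expect_equal(ontochron:::trunc2(53 / 71), 0.74)
  expect_equal(ontochron:::trunc2(53 / 61), 0.86)
  # an all-constant matrix has no varying character at all
  con0 <- character_matrix(matrix(0L, 3, 2,
                                  dimnames = list(paste0("S", 1:3, "_x_", 1:3, "%"), NULL)),
                           validate = FALSE)
  expect_error(ontochron:::ensemble_indices_matrix(con0, 0),
               class = "ontochron_index_error")
  # all-present characters vary only against the ancestor: CI defined, RI not
  con1 <- character_matrix(matrix(1L, 3, 2,
                                  dimnames = list(paste0("S", 1:3, "_x_", 1:3, "%"), NULL)))
  fit1 <- ontochron:::ensemble_indices_matrix(con1, 2)
  expect_equal(fit1$ci, 1)
  expect_true(is.na(fit1$ri))
})
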