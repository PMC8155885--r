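count_ones_fitness <- function(bits) sum(bits) / length(bits)

test_that("initial populations are seeded, nonempty and reproducible", {
  cfg <- abc_config(n_sources = 20, seed = 1)
  set.seed(1)
  s1 <- init_sources(cfg, 45, count_ones_fitness)
  set.seed(1)
  s2 <- init_sources(cfg, 45, count_ones_fitness)
  expect_identical(s1, s2)
  expect_length(s1, 20L)
  expect_true(all(vapply(s1, function(s) sum(s$bits) > 0, TRUE)))
  # d = 1: the only admissible source is the single bit 1
  set.seed(2)
  s3 <- init_sources(cfg, 1, count_ones_fitness)
  expect_true(all(vapply(s3, function(s) s$bits == 1L, TRUE)))
  # different seeds give different populations
  set.seed(3)
  s4 <- init_sources(cfg, 45, count_ones_fitness)
  expect_false(identical(lapply(s1, `[[`, "bits"), lapply(s4, `[[`, "bits")))
})

test_that("candidates only change disagreeing positions", {
  set.seed(4)
  cand <- replicate(200, abc_candidate(c(0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L)))
  seen <- unique(apply(cand, 2, paste, collapse = ""))
  expect_setequal(seen, c("0111", "0110", "0101", "0100"))
  # agreement is always preserved
  for (i in 1:50) {
    a <- as.integer(runif(12) < 0.5)
    b <- as.integer(runif(12) < 0.5)
    v <- abc_candidate(a, b)
    same <- a == b
    expect_identical(v[same], a[same])
  }
  expect_identical(abc_candidate(c(1L, 0L), c(1L, 0L)), c(1L, 0L))
  expect_error(abc_candidate(c(1L), c(1L, 0L)), "equal length")
})

test_that("disagreeing positions are re-drawn uniformly", {
  set.seed(5)
  draws <- replicate(4000, paste(abc_candidate(c(1L, 0L), c(0L, 1L)),
                                 collapse = ""))
  tab <- table(factor(draws, levels = c("00", "01", "10", "11")))
  # each of the four 2-bit vectors has probability 1/4; 3 sigma band
  expect_true(all(abs(tab - 1000) < 3 * sqrt(4000 * 0.25 * 0.75)))
})

test_that("selection probabilities normalize fitness", {
  expect_equal(selection_probabilities(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(selection_probabilities(c(0.6, 0.3, 0.1)), c(0.6, 0.3, 0.1))
  set.seed(6)
  for (i in 1:20) {
    p <- selection_probabilities(runif(7))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  expect_message(u <- selection_probabilities(c(0, 0, 0)), "uniform")
  expect_equal(u, rep(1 / 3, 3))
  expect_error(selection_probabilities(c(-0.1, 1)), "nonnegative")
})

test_that("roulette visit frequencies follow fitness proportions", {
  set.seed(7)
  p <- selection_probabilities(c(0.9, 0.1))
  visits <- sample.int(2, 2000, replace = TRUE, prob = p)
  expect_lt(abs(mean(visits == 1) - 0.9), 3 * sqrt(0.9 * 0.1 / 2000))
})

test_that("greedy replacement is strict and abandonment counts advance", {
  sources <- list(list(bits = c(1L, 0L), fitness = 0.5, ac = 0L),
                  list(bits = c(0L, 1L), fitness = 0.5, ac = 0L))
  # fitness that never improves: candidates tie or lose
  flat <- function(bits) 0.5
  out <- employed_phase(sources, flat)
  expect_equal(vapply(out, `[[`, 0L, "ac"), c(1L, 1L))
  expect_identical(lapply(out, `[[`, "bits"), lapply(sources, `[[`, "bits"))
  # strictly better candidates replace and reset the counter
  improving <- function(bits) sum(bits) / length(bits)
  src <- list(list(bits = c(1L, 0L), fitness = 0.5, ac = 3L),
              list(bits = c(1L, 1L), fitness = 1.0, ac = 0L))
  set.seed(8)
  out2 <- employed_phase(src, improving)
  # source 1's only neighbor is the all-ones source; any improvement
  # must come from flipping its zero bit to one
  if (out2[[1]]$fitness > 0.5) expect_equal(out2[[1]]$ac, 0L)
})

test_that("scouts respawn only strictly beyond the limit", {
  fit <- function(bits) 0.1
  sources <- list(list(bits = c(1L, 1L), fitness = 0.9, ac = 5L),
                  list(bits = c(1L, 0L), fitness = 0.8, ac = 6L))
  set.seed(9)
  out <- scout_phase(sources, fit, limit = 5L, d = 2L)
  expect_identical(out[[1]], sources[[1]])   # ac == limit: untouched
  expect_equal(out[[2]]$ac, 0L)              # ac == limit + 1: reinitialized
  expect_equal(out[[2]]$fitness, 0.1)
})

test_that("the best-so-far tracker is monotone and survives scouts", {
  for (s in 1:5) {
    tr <- run_abc(10, count_ones_fitness,
                  abc_config(n_sources = 6, limit = 2, max_iter = 25, seed = s))
    expect_false(is.unsorted(tr$curve))
    expect_equal(tr$best_fitness, max(tr$curve))
  }
})

test_that("zero iterations return the best of the initial population", {
  cfg <- abc_config(n_sources = 8, max_iter = 0, seed = 10)
  tr <- run_abc(6, count_ones_fitness, cfg)
  expect_length(tr$curve, 1L)
  set.seed(10)
  init <- init_sources(cfg, 6, function(b) if (all(b == 0)) 0 else count_ones_fitness(b))
  expect_equal(tr$best_fitness, max(vapply(init, `[[`, 0, "fitness")))
})

test_that("runs are reproducible from the seed and cache fitness calls", {
  cfg <- abc_config(n_sources = 8, limit = 4, max_iter = 12, seed = 11)
  t1 <- run_abc(10, count_ones_fitness, cfg)
  t2 <- run_abc(10, count_ones_fitness, cfg)
  expect_identical(t1$best_bits, t2$best_bits)
  expect_identical(t1$curve, t2$curve)
  expect_gt(t1$cache_hits, 0L)
  # evaluations + hits = total fitness queries; cache bounds evaluations
  expect_lte(t1$evaluations, 2^10)
})

test_that("feature selection recovers a planted informative subset", {
  # tables at the study's balanced class size (175 per class)
  sp <- toy_space()
  hits <- vapply(1:20, function(s) {
    tbl <- gen_feature_table(sp, informative = 1:3, n_per_class = 175,
                             tau_max = 5, seed = s)
    tr <- abc_select(tbl, classifier_spec("knn", "medium"),
                     abc_config(n_sources = 10, limit = 5, max_iter = 30,
                                seed = s))
    jaccard_bits(tr$best_bits, 1:3) >= 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate tables are rejected", {
  sp <- toy_space()
  tbl <- gen_feature_table(sp, informative = 1, n_per_class = 10,
                           tau_max = 2, seed = 1)
  tbl$label <- factor(rep("fast", nrow(tbl$x)), levels = c("fast", "slow"))
  expect_error(abc_select(tbl), "both classes")
})
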