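test_that("the default cooling schedule matches its loop oracle", {
  s <- sa_schedule()
  # independent oracle: iterate T <- T / mu_t from t_initial while T > t_min
  n <- 0L; t <- 5000
  while (t > 0.005) { n <- n + 1L; t <- t / 1.002 }
  levels <- temperature_levels(s)
  expect_equal(length(levels), n)
  expect_equal(length(levels), 6915)
  expect_equal(total_iterations(s), n * 2000L)
  expect_gte(total_iterations(s), 1.3e7)
  expect_true(all(diff(levels) < 0))
})

test_that("schedule boundaries and validation", {
  one <- sa_schedule(t_initial = 2, mu_t = 2, t_min = 1)
  expect_equal(length(temperature_levels(one)), 1L)
  expect_error(sa_schedule(mu_t = 1), class = "seqevolve_usage_error")
  expect_error(sa_schedule(t_initial = 1, t_min = 2), class = "seqevolve_usage_error")
})

test_that("proposals change exactly one position with background frequencies", {
  r <- mt_rng(40)
  s <- random_sequence(30, rng = r)
  for (k in 1:100) {
    s2 <- propose_move(s, r)
    diffs <- sum(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
    expect_equal(diffs, 1L)
  }
  # replacement frequencies follow the table renormalized without the current
  s1 <- strrep("L", 1)
  repl <- character(2e4)
  for (k in seq_along(repl)) repl[k] <- propose_move(s1, r)
  emp <- table(factor(repl, levels = AA_CODES)) / length(repl)
  f <- aa_frequencies()
  f["L"] <- 0
  f <- f / sum(f)
  expect_true(all(abs(as.numeric(emp) - f) < 0.01))
})

test_that("Metropolis acceptance has the right limits and rate", {
  r <- mt_rng(41)
  expect_true(metropolis_accept(0, 10, 1, r))
  expect_true(metropolis_accept(5, 1e-9, 1, r))
  # delta = -kT ln 2 accepts about half the time
  acc <- replicate(1e4, metropolis_accept(-2 * log(2), 2, 1, r))
  expect_equal(mean(acc), 0.5, tolerance = 0.04)
  # the frozen limit rejects all deteriorations
  acc0 <- replicate(500, metropolis_accept(-0.1, 1e-300, 1, r))
  expect_false(any(acc0))
})

test_that("annealing is bit-reproducible and monotone in its invariants", {
  sch <- short_schedule(50)
  a <- anneal(std$model, structure = std$target$structure, schedule = sch,
              seed = 101, record_every = 200)
  b <- anneal(std$model, structure = std$target$structure, schedule = sch,
              seed = 101, record_every = 200)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$trajectory, b$trajectory)
  c <- anneal(std$model, structure = std$target$structure, schedule = sch,
              seed = 102, record_every = 200)
  expect_false(identical(a$sequence, c$sequence))
  expect_true(all(diff(a$trajectory$best_fitness) >= 0))
  expect_true(all(diff(a$trajectory$temperature) <= 0))
  expect_equal(max(a$trajectory$step), total_iterations(sch))
  # tracked fitness equals full re-evaluation of the best sequence
  expect_equal(a$fitness, fitness(a$sequence, std$model), tolerance = 1e-6)
})

test_that("start modes behave as documented", {
  sch <- sa_schedule(t_initial = 2, mu_t = 2, t_min = 1, iters_fixed_t = 5)
  native <- std$target$sequence
  rn <- anneal(std$model, "native", native = native, schedule = sch, seed = 1,
               record_every = 5)
  expect_equal(rn$start_sequence, native)
  expect_equal(rn$trajectory$identity[1], 1.0)
  rs <- anneal(std$model, "shuffled", native = native, schedule = sch, seed = 1,
               record_every = 5)
  expect_identical(sort(strsplit(rs$start_sequence, "")[[1]]),
                   sort(strsplit(native, "")[[1]]))
  expect_error(anneal(std$model, "shuffled", schedule = sch, seed = 1),
               class = "seqevolve_usage_error")
})

test_that("the optimizer improves on its start in nearly all runs", {
  sch <- short_schedule(50)
  improved <- 0
  for (seed in 1:20) {
    res <- anneal(std$model, structure = std$target$structure, schedule = sch,
                  seed = seed, record_every = 5000)
    if (res$fitness > res$trajectory$fitness[1]) improved <- improved + 1
  }
  expect_gte(improved, 19)
})

test_that("annealing attains the enumerated optimum on a reduced toy problem", {
  lib <- make_library(6, seed = 51, n_res = 14)
  target <- make_helix(10, seed = 52)
  model <- build_energy_model(target$structure, library = lib,
                              n_random = 60, rng = mt_rng(1))
  alphabet <- c("A", "E", "L")
  # exhaustive enumeration of all 3^10 sequences
  idx <- match(alphabet, AA_CODES)
  grid <- as.matrix(expand.grid(rep(list(idx), 10)))
  wos <- model$weights * model$normalizers$orient
  best_fit <- -Inf
  for (k in seq_len(nrow(grid))) {
    raw <- seqevolve:::raw_terms_int(grid[k, ], model)
    f <- 1 + sum(model$weights * seqevolve:::z_terms(raw, model))
    if (f > best_fit) best_fit <- f
  }
  sch <- sa_schedule(t_initial = 2, mu_t = 1.05, t_min = 0.002,
                     iters_fixed_t = 100)
  hits <- 0
  for (seed in 1:20) {
    res <- anneal(model, structure = target$structure, schedule = sch,
                  seed = seed, record_every = 1e6, alphabet = alphabet)
    if (abs(res$fitness - best_fit) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("identity to native rises well above its random-start level", {
  sch <- sa_schedule(t_initial = 50, mu_t = 1.03, t_min = 0.05,
                     iters_fixed_t = 100)
  res <- anneal(std$model, structure = std$target$structure, schedule = sch,
                seed = 7, record_every = 1000)
  tr <- res$trajectory
  early <- mean(head(tr$identity, 5))
  final <- sequence_identity(res$sequence, std$target$sequence)
  expect_gt(final, early)
  expect_gt(final, 0.10) # clearly above the ~5-8% random level
})

test_that("the anti-clustering term suppresses same-class runs", {
  max_run <- function(seq) {
    cls <- default_class_map()[strsplit(seq, "")[[1]]]
    max(rle(cls)$lengths)
  }
  m_off <- std$model
  w <- m_off$weights
  w["antigroup"] <- 0
  m_off$weights <- w / sum(w)
  sch <- short_schedule(100)
  runs_on <- runs_off <- numeric(3)
  for (k in 1:3) {
    runs_on[k] <- max_run(anneal(std$model, structure = std$target$structure,
                                 schedule = sch, seed = 200 + k,
                                 record_every = 1e6)$sequence)
    runs_off[k] <- max_run(anneal(m_off, structure = std$target$structure,
                                  schedule = sch, seed = 200 + k,
                                  record_every = 1e6)$sequence)
  }
  expect_lte(mean(runs_on), mean(runs_off))
})
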