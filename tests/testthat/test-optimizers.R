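sphere <- function(x) sum(x^2)
sp5 <- search_space(-1, 1, D = 5)

test_that("population initialisation respects bounds and the seed", {
  sp <- search_space(c(0, -2), c(1, 2))
  pop <- init_population(sp, 30, seed = 4)
  expect_equal(dim(pop), c(30, 2))
  expect_true(all(pop[, 1] >= 0 & pop[, 1] <= 1))
  expect_true(all(pop[, 2] >= -2 & pop[, 2] <= 2))
  expect_identical(pop, init_population(sp, 30, seed = 4))

  eps <- 1e-6
  tight <- init_population(search_space(0.5 - eps, 0.5 + eps, D = 3), 10)
  expect_true(all(abs(tight - 0.5) <= eps))

  expect_error(search_space(1, 1, D = 2), "elementwise")
})

test_that("all four optimizers keep traces non-increasing, stay in bounds and reproduce bit-for-bit", {
  for (alg in c("DS", "SFLA", "WS", "AMO")) {
    cfg <- optimizer_config(alg, NP = 20, max_iter = 40, seed = 3)
    res <- run_optimizer(sphere, sp5, cfg)
    expect_true(all(diff(res$trace) <= 0))
    expect_equal(res$best_fitness, res$trace[length(res$trace)])
    expect_true(all(res$best_position >= -1 & res$best_position <= 1))
    res2 <- run_optimizer(sphere, sp5, cfg)
    expect_identical(res$best_position, res2$best_position)
    expect_identical(res$trace, res2$trace)
    expect_gt(res$evaluations, 20)
  }
})

test_that("a constant fitness yields a flat trace at that constant", {
  flat <- function(x) 4.2
  for (alg in c("DS", "SFLA", "WS", "AMO")) {
    res <- run_optimizer(flat, sp5,
                         optimizer_config(alg, NP = 8, max_iter = 10,
                                          memeplexes = 2, seed = 1))
    expect_true(all(res$trace == 4.2))
    expect_equal(res$best_fitness, 4.2)
  }
})

test_that("optimizer configs validate their structural constraints", {
  expect_error(optimizer_config("SFLA", NP = 10, memeplexes = 4),
               "multiple")
  expect_error(optimizer_config("DS", NP = 2), "NP")
  expect_error(optimizer_config("DS", p1 = 1.5), "rates")
  expect_error(run_ws(sphere, sp5, optimizer_config("WS", NP = 4)), NA)
})

test_that("wolf-search control parameter hits its endpoints", {
  expect_equal(ws_alpha_schedule(0, 200), 2)
  expect_equal(ws_alpha_schedule(200, 200), 0)
  expect_equal(ws_alpha_schedule(100, 200), 1)
})

test_that("the migration ring neighborhood wraps as documented", {
  NP <- 50
  expect_equal(amo_neighborhood(1, NP), c(NP - 1, NP, 1, 2, 3))
  expect_equal(amo_neighborhood(25, NP), 23:27)
  expect_equal(amo_neighborhood(NP, NP), c(NP - 2, NP - 1, NP, 1, 2))
  expect_length(amo_neighborhood(3, NP, halfwidth = 4), 9)
})

test_that("migration replacement probability follows fitness rank", {
  fit <- c(5, 1, 3, 2, 4)
  pa <- amo_update_prob(fit)
  expect_equal(pa[which.min(fit)], 1 / 5)  # best
  expect_equal(pa[which.max(fit)], 1)      # worst
  expect_equal(sort(pa), (1:5) / 5)
})

test_that("quantization fitness equals the brute-force distortion", {
  set.seed(21)
  for (i in 1:10) {
    v <- runif(60, 0, 0.5)
    x <- runif(8, 0, 0.5)
    expect_equal(quantization_fitness(v)(x), quant_brute(v, x))
  }
})

test_that("stream optimization exploits its reduced-vector seeding", {
  cfg <- optimizer_config("WS", NP = 10, max_iter = 5, seed = 2)

  # constant stream: the seeded representative hits fitness 0 immediately
  res <- optimize_stream(rep("DDDDDDD", 30), cfg, L = 5)
  expect_equal(res$best_fitness, 0)
  expect_length(res$best_position, 5)

  # two distinct values, L = 2: one representative per value, fitness 0
  two <- rep(c("AAAAAAA", "EEEEEEE"), 10)
  res2 <- optimize_stream(two, cfg, L = 2)
  expect_equal(res2$best_fitness, 0, tolerance = 1e-12)

  # optimized fitness never exceeds the raw reduced vector's fitness
  fx <- small_cohort()
  sub <- fx$words[fx$words$subject_id == fx$words$subject_id[1], ]
  f <- quantization_fitness(sub$value)
  raw <- f(reduce_stream(sub, L = 20))
  res3 <- optimize_stream(sub, optimizer_config("AMO", NP = 10,
                                                max_iter = 10, seed = 5),
                          L = 20)
  expect_lte(res3$best_fitness, raw)
})

test_that("tidy/glance/autoplot expose the optimizer run", {
  res <- run_optimizer(sphere, sp5,
                       optimizer_config("DS", NP = 10, max_iter = 15))
  td <- tidy(res)
  expect_equal(nrow(td), 15)
  expect_named(td, c("iteration", "best_fitness"))
  gl <- glance(res)
  expect_equal(gl$algorithm, "DS")
  expect_s3_class(autoplot(res), "ggplot")
})
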