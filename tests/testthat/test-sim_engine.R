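# Forward-simulator unit and property tests.  Stochastic assertions use
# fixed seeds and Monte-Carlo error bounds computed from the replicates
# themselves (4 standard errors unless noted).

test_that("fitness follows the clamped synergistic form", {
  expect_identical(fitness(0, 4e-4, 1.3), 1)
  expect_equal(fitness(100, 4e-4, 1.3), 1 - 4e-4 * 100^1.3,
               tolerance = 1e-12)
  expect_equal(fitness(100, 4e-4, 1.3), 0.8407571, tolerance = 1e-6)
  # clamping: 4e-4 * g^1.3 crosses 1 at g = 2500^(1/1.3) ~ 411.0
  expect_identical(fitness(412, 4e-4, 1.3), 0)
  expect_gt(fitness(410, 4e-4, 1.3), 0)
  # monotone non-increasing in g; x = 0 is flat at 1
  g <- 0:500
  expect_true(all(diff(fitness(g, 4e-4, 1.3)) <= 0))
  expect_true(all(fitness(g, 0, 1.3) == 1))
})

test_that("mating probabilities normalize, preserve order, and signal extinction", {
  expect_equal(mating_probabilities(rep(0.37, 5)), rep(0.2, 5))
  expect_equal(mating_probabilities(c(0.8, 0.4, 0.8)), c(0.4, 0.2, 0.4))
  w <- runif(50)
  p <- mating_probabilities(w)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_identical(order(p), order(w))
  expect_equal(mating_probabilities(c(1, 0, 1)), c(0.5, 0, 0.5))
  expect_error(mating_probabilities(c(1, 0)), class = "te_extinction")
  expect_error(mating_probabilities(c(0, 0, 0)), class = "te_extinction")
})

test_that("gametes from identical or unlinked haplotypes behave exactly", {
  gm <- tiny_map()
  h <- sort(sample.int(10000, 40) - 1L)
  set.seed(1)
  expect_identical(make_gamete(list(h, h), gm), h)
  # zero genetic length: gamete is an unmodified copy of one haplotype
  gm0 <- norecomb_map()
  a <- c(10L, 20L); b <- c(300L, 400L, 500L)
  picks <- replicate(200, {
    g <- make_gamete(list(a, b), gm0)
    if (identical(g, a)) "a" else if (identical(g, b)) "b" else "other"
  })
  expect_true(all(picks %in% c("a", "b")))
  expect_gt(sum(picks == "a"), 60)   # fair coin, 200 draws
  expect_gt(sum(picks == "b"), 60)
})

test_that("recombination exchanges material between arms independently", {
  gm <- tiny_map(1e4, morgans = 0.5)  # 4 arms of 2500 sites
  a <- c(0L, 2500L, 5000L, 7500L)      # one site on each arm
  b <- integer(0)
  set.seed(2)
  g <- replicate(500, length(make_gamete(list(a, b), gm)))
  # each arm segregates ~ independently with mean 1/2
  expect_equal(mean(g), 2, tolerance = 0.15)
  expect_gt(var(g), 0.5)
})

test_that("transposition matches its binomial semantics", {
  gm <- tiny_map()
  expect_identical(transpose(list(c(1L, 5L), c(7L)), 0, gm),
                   list(c(1L, 5L), c(7L)))
  expect_identical(transpose(list(integer(0), integer(0)), 0.5, gm),
                   list(integer(0), integer(0)))
  # g = 10, v = 0.003: mean new insertions ~ 0.03 over 1e5 draws
  h1 <- as.integer(0:4); h2 <- as.integer(10:14)
  set.seed(3)
  new_counts <- replicate(1e5, {
    r <- TEpopdyn:::cpp_transpose(h1, h2, 0.003, 10000L)
    length(r[[1]]) + length(r[[2]]) - 10L
  })
  m <- mean(new_counts)
  se <- sd(new_counts) / sqrt(length(new_counts))
  expect_lt(abs(m - 0.03), 4 * se + 1e-4)
  # occupied-site collisions are discarded: haplotype stays duplicate-free
  set.seed(4)
  r <- transpose(list(as.integer(0:99), integer(0)), 1, tiny_map(200))
  expect_false(any(duplicated(r[[1]])))
  expect_false(any(duplicated(r[[2]])))
})

test_that("one generation conserves fixed sites and total copies in expectation", {
  gm <- tiny_map()
  N <- 50
  # a fixed insertion cannot be lost without excision
  haps <- lapply(seq_len(2 * N), function(i) c(77L))
  pop <- te_population(haps, x = 0)
  p <- sim_params(gm, N = N, v = 0, x = 0, generations = 1,
                  sample_haplotypes = 10)
  set.seed(5)
  pop2 <- step_generation(step_generation(pop, p), p)
  expect_true(all(vapply(pop2$haplotypes, function(h) 77L %in% h,
                         logical(1))))
  # neutral martingale: mean change of total copy count ~ 0
  set.seed(6)
  haps <- lapply(seq_len(2 * N), function(i)
    sort(sample.int(10000, 5) - 1L))
  pop <- te_population(haps, x = 0)
  tot0 <- sum(copy_numbers(pop))
  deltas <- replicate(300, sum(copy_numbers(step_generation(pop, p))) - tot0)
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 4 * se)
})

test_that("zero-fitness individuals never parent offspring", {
  gm <- tiny_map()
  N <- 20
  # individual 1 carries a huge load, everyone else is empty
  haps <- c(list(as.integer(0:499), as.integer(500:999)),
            rep(list(integer(0)), 2 * N - 2))
  pop <- te_population(haps, x = 4e-4, t = 1.3)
  expect_identical(pop$fitness[1], 0)
  p <- sim_params(gm, N = N, v = 0, x = 4e-4, generations = 1,
                  sample_haplotypes = 10)
  set.seed(7)
  for (i in 1:20) {
    nxt <- step_generation(pop, p)
    expect_identical(sum(copy_numbers(nxt)), 0L)
  }
})

test_that("run_simulation is reproducible, bounded, and handles edge cases", {
  gm <- tiny_map()
  p <- sim_params(gm, N = 50, v = 0.002, generations = 100, m0 = 5,
                  sample_haplotypes = 40)
  set.seed(11); tr1 <- run_simulation(p)
  set.seed(11); tr2 <- run_simulation(p)
  expect_identical(tr1$mean_copy, tr2$mean_copy)
  expect_identical(tr1$sample$c, tr2$sample$c)
  expect_identical(tr1$sample$sites, tr2$sample$sites)
  expect_length(tr1$mean_copy, 101)
  expect_true(all(tr1$n_fixed >= 0 & tr1$n_seg >= 0))
  # generations = 0: trajectory of length 1, initial state
  p0 <- sim_params(gm, N = 50, v = 0.002, generations = 0, m0 = 5,
                   sample_haplotypes = 40)
  set.seed(12); tr0 <- run_simulation(p0)
  expect_length(tr0$mean_copy, 1)
  expect_equal(tr0$mean_copy[1], 10)  # 2 * m0
  # lethal load: extinction reported with its generation
  px <- sim_params(gm, N = 20, v = 0, x = 1, generations = 50, m0 = 10,
                   sample_haplotypes = 10)
  set.seed(13); trx <- run_simulation(px)
  expect_true(trx$extinct)
  expect_identical(trx$extinct_generation, 1L)
  expect_null(trx$sample)
})

test_that("neutral drift preserves mean copy number and fixation probability", {
  gm <- tiny_map()
  # conservation across replicates
  p <- sim_params(gm, N = 100, v = 0, x = 0, generations = 100, m0 = 10,
                  sample_haplotypes = 40)
  set.seed(21)
  finals <- replicate(50, {
    tr <- run_simulation(p, track_sites = FALSE, keep_population = FALSE)
    tail(tr$mean_copy, 1)
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 20), 4 * se)

  # single-insertion fixation probability ~ initial frequency (0.1)
  N <- 50
  p1 <- sim_params(gm, N = N, v = 0, x = 0, generations = 1,
                   sample_haplotypes = 10)
  set.seed(22)
  outcomes <- replicate(300, {
    haps <- c(rep(list(0L), 10), rep(list(integer(0)), 2 * N - 10))
    pop <- te_population(haps, x = 0)
    for (i in 1:1500) {
      pop <- step_generation(pop, p1)
      k <- sum(copy_numbers(pop))
      if (k == 0 || k == 2 * N) break
    }
    k == 2 * N
  })
  n_fix <- sum(outcomes)
  # binomial(300, 0.1): 4 sd band around 30
  expect_gt(n_fix, 30 - 4 * sqrt(300 * 0.1 * 0.9))
  expect_lt(n_fix, 30 + 4 * sqrt(300 * 0.1 * 0.9))
})

test_that("without selection copy number grows geometrically at rate 1+v", {
  gm <- tiny_map()
  v <- 0.02
  p <- sim_params(gm, N = 200, v = v, x = 0, generations = 100, m0 = 5,
                  sample_haplotypes = 40)
  set.seed(31)
  rates <- replicate(5, {
    tr <- run_simulation(p, track_sites = FALSE, keep_population = FALSE)
    (tail(tr$mean_copy, 1) / tr$mean_copy[1])^(1 / 100)
  })
  se <- sd(rates) / sqrt(length(rates)) + 1e-4
  expect_lt(abs(mean(rates) - (1 + v)), 4 * se)
})

test_that("long-run mean copy number agrees with the mean-field recursion", {
  # tolerance 25%: the recursion ignores drift and linkage, which the
  # pilot runs place at 8-15% systematic deviation at these settings
  gm <- tiny_map(1e5)
  for (v in c(0.002, 0.003)) {
    oracle <- equilibrium_recursion(v)
    set.seed(41)
    means <- replicate(2, {
      p <- sim_params(gm, N = 500, v = v, generations = 2000, m0 = 10)
      tr <- run_simulation(p, track_sites = FALSE, keep_population = FALSE)
      mean(tail(tr$mean_copy, 400))
    })
    expect_lt(abs(mean(means) - oracle) / oracle, 0.25)
  }
})

test_that("pool sampling counts sites by minimum sampled count", {
  # population of 5 diploids = 10 haplotypes; site 3 on 5 of them,
  # site 9 on 2 of them
  haps <- c(rep(list(c(3L, 9L)), 2), rep(list(3L), 3),
            rep(list(integer(0)), 5))
  pop <- te_population(haps, x = 0)
  set.seed(51)
  s <- sample_pool(pop, n_haplotypes = 10, min_count = 3)
  expect_identical(s$c, 1L)
  expect_identical(s$sites$site, 3L)
  expect_identical(s$sites$freq, 0.5)
  # a fixed site is always counted at frequency 1
  haps <- rep(list(42L), 10)
  s <- sample_pool(te_population(haps, x = 0), 7, 3)
  expect_identical(s$c, 1L)
  expect_identical(s$sites$freq, 1)
  # oversampling errors
  expect_error(sample_pool(pop, 11, 3), "exceeds")
})
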