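test_that("cell diameter follows cube-root scaling from quota", {
  expect_equal(diameter_from_quota(1), 1.25)
  expect_equal(diameter_from_quota(0.5), 1.25 * 0.5^(1 / 3))
  expect_equal(round(diameter_from_quota(0.5), 2), 0.99)  # the printed ~1 um
  expect_equal(diameter_from_quota(0.125), 0.625)
  expect_error(diameter_from_quota(0), "> 0")
})

test_that("founding communities have 100 active cells with half-full quotas", {
  su <- tiny_setup(seed = 4, S = 50)
  withr::with_seed(8, {
    init <- initialize_community(su$params, su$traits)
    expect_equal(individual_count(init$inds), 100L)
    expect_true(all(init$inds$quota >= 0.5 & init$inds$quota <= 1.0))
    expect_true(all(init$inds$active))
    expect_equal(init$quota_in, sum(init$inds$quota))
    pos_ok <- c(init$inds$x, init$inds$y, init$inds$z)
    expect_true(all(pos_ok >= 0 & pos_ok <= su$params$domain_length))
  })
  # log-series seeding: aggregated abundance declines with species rank
  withr::with_seed(9, {
    counts <- integer(50)
    for (k in 1:200) {
      init <- initialize_community(su$params, su$traits)
      counts <- counts + tabulate(init$inds$species, 50)
    }
    expect_gte(counts[1], counts[2])
    expect_gt(counts[1], counts[10])
    expect_gt(mean(counts[1:5]), mean(counts[46:50]))
  })
})

test_that("immigration is Bernoulli with uniform species and half-full quota", {
  su <- tiny_setup(seed = 4, S = 50,
                   overrides = list(immigration_rate = 0))
  inds <- new_individuals()
  withr::with_seed(10, {
    for (k in 1:100)
      expect_equal(immigrate(inds, su$params, su$traits, 1L)$arrived, 0L)
  })
  su5 <- tiny_setup(seed = 4, S = 50,
                    overrides = list(immigration_rate = 0.05))
  withr::with_seed(11, {
    arrivals <- 0L
    for (k in 1:10000) {
      res <- immigrate(inds, su5$params, su5$traits, 1L)
      arrivals <- arrivals + res$arrived
      if (res$arrived == 1L)
        expect_true(res$inds$quota >= 0.5 && res$inds$quota <= 1.0)
    }
    se <- sqrt(0.05 * 0.95 / 10000)
    expect_lt(abs(arrivals / 10000 - 0.05), 3 * se)
  })
})

test_that("consumption conserves mass-quota exactly and saturates", {
  res <- consume(quota = 0.5, content = 1000, kappa = 0.001)
  expect_equal(res$delta, 0.5)
  expect_equal(res$quota, 1.0)
  expect_equal(res$content, 500)
  # satiation: a full cell consumes nothing
  res2 <- consume(1.0, 1000, 0.001)
  expect_equal(res2$delta, 0)
  expect_equal(res2$content, 1000)
  # the species rate caps uptake by particle fraction
  res3 <- consume(0.5, 1000, 0.001, rate = 0.1)
  expect_equal(res3$delta, 0.1)
  expect_equal(res3$content, 900)
  # conservation across random draws: kappa * Dcontent = delta
  withr::with_seed(12, {
    q <- runif(100); ct <- runif(100, 1, 10000); r <- runif(100, 0.1, 1)
    res4 <- consume(q, ct, 0.001, r)
    expect_equal(0.001 * (ct - res4$content), res4$delta)
    expect_true(all(res4$quota <= 1 + 1e-12))
  })
})

test_that("fission halves post-cost quota and scales cost with g and Q", {
  fs <- fission_split(quota = 1, growth_rate = 1, c_g = 0.1)
  expect_equal(fs$half, (1 - 0.1) / 2)
  expect_equal(fs$cost, 0.1)
  fs2 <- fission_split(0.6, 0.5, 0.1)
  expect_equal(fs2$cost, 0.1 * 0.5 * 0.6)
  expect_equal(2 * fs2$half + fs2$cost, 0.6)  # quota conserved
})

test_that("maintenance deducts the species cost, reduced while dormant", {
  ms <- maintenance_step(0.5, TRUE, 0.01, 100)
  expect_equal(ms$quota, 0.49)
  ms2 <- maintenance_step(0.5, FALSE, 0.01, 100)
  expect_equal(ms2$paid, 0.0001)
  # dormant deduction never exceeds the active one
  withr::with_seed(13, {
    m <- runif(50, 0.001, 0.01); f <- runif(50, 10, 100); q <- runif(50)
    expect_true(all(maintenance_step(q, FALSE, m, f)$paid <=
                    maintenance_step(q, TRUE, m, f)$paid))
  })
  # deduction caps at the available quota (no negative quotas)
  expect_equal(maintenance_step(0.003, TRUE, 0.01, 10)$quota, 0)
})

test_that("death is strict quota-below-maintenance, active or dormant", {
  expect_false(check_death(0.0005, 0.001))   # dead
  expect_true(check_death(0.001, 0.001))     # boundary survives
  expect_true(check_death(0.5, 0.01))
})

test_that("dormancy entry is a deterministic depletion threshold; exit is stochastic", {
  # theta_d = 50, m = 0.01: quota 0.4 <= 0.5 goes dormant
  expect_false(dormancy_transition(TRUE, 0.4, 0.01, 0.005, 50))
  expect_true(dormancy_transition(TRUE, 0.6, 0.01, 0.005, 50))
  # rho = 0 never resuscitates
  withr::with_seed(14, {
    expect_false(any(replicate(200,
      dormancy_transition(FALSE, 0.3, 0.01, 0, 50))))
  })
  withr::with_seed(15, {
    wakes <- sum(replicate(10000,
      dormancy_transition(FALSE, 0.9, 0.001, 0.005, 50)))
    se <- sqrt(0.005 * 0.995 / 10000)
    expect_lt(abs(wakes / 10000 - 0.005), 3 * se)
  })
})
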