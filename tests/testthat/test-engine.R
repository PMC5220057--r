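test_that("encounters require contact and a consumable type", {
  traits <- list(table = NULL, consumable = matrix(TRUE, 1, 11),
                 product = NULL, S = 1L)
  # a full cell (radius 0.625 um) against a particle of radius 2000 um
  parts <- build_particles(1L, 1000, x = 2000, y = 0, z = 0)
  expect_equal(diameter_from_content(1000) / 2, 2000)
  inds <- build_individuals(1L, 1.0, x = 0, y = 0, z = 0)
  enc <- detect_encounters(inds, parts, traits)
  expect_equal(nrow(enc), 1L)       # 2000 <= 2000 + 0.625
  inds2 <- build_individuals(1L, 1.0, x = 4100, y = 0, z = 0)
  expect_equal(nrow(detect_encounters(inds2, parts, traits)), 0L)
  # an inedible type at the same spot is not an encounter
  traits$consumable[1, 1] <- FALSE
  expect_equal(nrow(detect_encounters(inds, parts, traits)), 0L)
})

test_that("encounter detection equals the all-pairs oracle on random states", {
  withr::with_seed(31, {
    L <- 43200
    n <- 100; m <- 100; S <- 8
    cons <- matrix(runif(S * 11) < 0.5, S, 11)
    traits <- list(table = NULL, consumable = cons, product = NULL, S = S)
    inds <- build_individuals(sample(S, n, TRUE), runif(n, 0.2, 1),
                              runif(n, 0, L), runif(n, 0, L), runif(n, 0, L))
    parts <- build_particles(sample(11, m, TRUE), runif(m, 1000, 10000),
                             runif(m, 0, L), runif(m, 0, L), runif(m, 0, L))
    enc <- detect_encounters(inds, parts, traits)
    want <- oracle_nearest(inds$x, inds$y, inds$z,
                           diameter_from_quota(inds$quota) / 2,
                           inds$species, parts, cons)
    hit <- !is.na(want$touch)
    expect_equal(enc$ind, inds$id[hit])
    expect_equal(enc$part, want$touch[hit])
  })
})

test_that("dispersal energetics: passive free, chemotaxis twice run-and-tumble", {
  expect_equal(apply_dispersal_cost(0.8, 10000, "passive", 0.05), 0)
  rt <- apply_dispersal_cost(0.8, 10000, "run_tumble", 0.05)
  ch <- apply_dispersal_cost(0.8, 10000, "chemotaxis", 0.05)
  expect_equal(ch, 2 * rt)
  expect_equal(rt, 1 * 0.05 * (10000 / 43200) * 0.8)
  expect_equal(apply_dispersal_cost(0.8, 0, "chemotaxis", 0.05), 0)
  expect_error(apply_dispersal_cost(0.8, 1, "teleport", 0.05), "unknown")
})

test_that("an empty, closed system is inert except for the clock", {
  su <- tiny_setup(seed = 6,
                   overrides = list(supply_rate = 0, immigration_rate = 0))
  st <- make_state(su$params, su$traits, su$regime, seed = 30)
  st$inds <- new_individuals()          # empty the community
  st$cum$q_init <- 0
  st2 <- step_model(st)
  expect_equal(st2$step_index, 1L)
  expect_equal(individual_count(st2$inds), 0L)
  expect_equal(particle_count(st2$parts), 0L)
  expect_equal(st2$tally, list(births = 0L, deaths = 0L, encounters = 0L,
                               immigrations = 0L))
})

test_that("trajectories are reproducible under a seed", {
  su <- tiny_setup(seed = 8)
  r1 <- run_model(su$params, su$traits, su$regime, seed = 77,
                  burnin_cap = 0, production_steps = 200, cadence = 10)
  r2 <- run_model(su$params, su$traits, su$regime, seed = 77,
                  burnin_cap = 0, production_steps = 200, cadence = 10)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$state$inds, r2$state$inds)
  expect_identical(r1$state$parts, r2$state$parts)
})

test_that("quota and mass ledgers balance exactly over a 500-step run", {
  for (sd in c(101, 202)) {
    su <- tiny_setup(seed = sd,
                     reg = regime_from_index(1L + (sd %% 72L)))
    st <- make_state(su$params, su$traits, su$regime, seed = sd)
    for (k in 1:500) st <- step_model(st)
    aud <- audit_state(st)
    scale_c <- max(1, st$cum$supplied + st$cum$spawned)
    scale_q <- max(1, st$cum$q_init + st$cum$q_immig + st$cum$q_consumed)
    expect_lt(aud$content_error / scale_c, 1e-9)
    expect_lt(aud$quota_error / scale_q, 1e-9)
  }
})

test_that("a closed system never gains energy", {
  su <- tiny_setup(seed = 9,
                   overrides = list(supply_rate = 0, immigration_rate = 0))
  st <- make_state(su$params, su$traits, su$regime, seed = 31)
  # give the community something to eat first, then close the system
  st$parts <- build_particles(1L, c(5000, 8000),
                              x = c(100, 30000), y = c(100, 30000),
                              z = c(100, 30000))
  st$next_part_id <- 3L
  kappa <- su$params$mass_to_quota
  energy <- sum(st$inds$quota) + kappa * sum(st$parts$content)
  for (k in 1:300) {
    st <- step_model(st)
    e2 <- sum(st$inds$quota) + kappa * sum(st$parts$content)
    expect_lte(e2, energy + 1e-9)
    energy <- e2
  }
})

test_that("process blocks are executed in a fresh uniform order each step", {
  su <- tiny_setup(seed = 10,
                   overrides = list(supply_rate = 0, immigration_rate = 0))
  st <- make_state(su$params, su$traits, su$regime, seed = 32)
  st$inds <- new_individuals()   # keep the steps cheap
  st$cum$q_init <- 0
  firsts <- character(5000)
  withr::with_seed(33, {
    for (k in 1:5000) {
      st <- step_model(st)
      firsts[k] <- st$last_order[1]
    }
  })
  tab <- table(factor(firsts, levels = seedbankIBM:::PROCESS_BLOCKS))
  expect_equal(length(tab), 9L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})
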