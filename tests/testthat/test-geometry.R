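L <- 43200

test_that("reflection mirrors coordinates back into the domain", {
  expect_equal(reflect(43300, L), 43100)
  expect_equal(reflect(-50, L), 50)
  expect_equal(reflect(100, L), 100)
  expect_equal(reflect(2 * L + 10, L), 10)     # repeated folding
  expect_error(reflect(NaN, L), "non-finite")
  withr::with_seed(1, {
    x <- runif(1000, -3 * L, 4 * L)
    y <- reflect(x, L)
    expect_true(all(y >= 0 & y <= L))
  })
})

test_that("well-mixed relocation is uniform and memoryless", {
  withr::with_seed(42, {
    pos <- relocate_well_mixed(10000, L)
    expect_true(all(pos >= 0 & pos <= L))
    # per-axis uniformity, chi-squared over 20 bins at alpha = 0.01
    for (ax in 1:3) {
      cnt <- table(cut(pos[, ax], seq(0, L, length.out = 21)))
      expect_gt(chisq.test(cnt)$p.value, 0.01)
    }
    # consecutive relocations are uncorrelated across entities
    pos2 <- relocate_well_mixed(10000, L)
    expect_lt(abs(cor(pos[, 1], pos2[, 1], method = "spearman")), 0.05)
  })
})

test_that("Brownian displacement is zero-mean, bounded, and degenerate at sigma 0", {
  pos <- matrix(rep(L / 2, 30), ncol = 3)
  expect_identical(brownian_step(pos, 0, L), pos)
  expect_error(brownian_step(pos, -1, L), ">= 0")
  withr::with_seed(11, {
    p1 <- matrix(rep(L / 2, 3 * 10000), ncol = 3)
    p2 <- brownian_step(p1, 10, L)
    expect_true(all(p2 >= 0 & p2 <= L))
    # mean displacement within 3 standard errors of zero
    d <- p2 - p1
    se <- 10 / sqrt(nrow(d))
    expect_true(all(abs(colMeans(d)) < 3 * se))
    # large sigma forces reflections yet stays in-domain
    p3 <- brownian_step(p1, 2 * L, L)
    expect_true(all(p3 >= 0 & p3 <= L))
  })
})

test_that("run-and-tumble advances by the step length and respects walls", {
  pos <- matrix(c(L / 2, L / 2, L / 2), ncol = 3)
  h <- matrix(c(1, 0, 0), ncol = 3)
  # degenerate zero step
  mv0 <- run_tumble_step(pos, h, 0, L)
  expect_identical(mv0$pos, pos)
  expect_identical(mv0$heading, h)
  # interior move: displacement magnitude equals step length
  mv <- run_tumble_step(pos, h, 500, L)
  expect_equal(sqrt(sum((mv$pos - pos)^2)), 500)
  expect_identical(mv$heading, h)  # heading persists without wall contact
  # long trajectories with many bounces never leave the domain
  withr::with_seed(5, {
    n <- 50
    p <- matrix(runif(3 * n, 0, L), ncol = 3)
    hd <- matrix(rnorm(3 * n), ncol = 3)
    hd <- hd / sqrt(rowSums(hd^2))
    steps <- runif(n, 0.01, 1) * L
    for (k in 1:100) {
      mv <- run_tumble_step(p, hd, steps, L)
      p <- mv$pos; hd <- mv$heading
      expect_true(all(p >= 0 & p <= L))
      expect_equal(rowSums(hd^2), rep(1, n), tolerance = 1e-8)
    }
  })
})

test_that("chemotaxis closes on its target and falls back to run-and-tumble", {
  pos <- matrix(c(1000, 1000, 1000), ncol = 3)
  h <- matrix(c(0, 1, 0), ncol = 3)
  tgt <- matrix(c(2000, 1000, 1000), ncol = 3)  # 1000 um away on x
  # gap = 1000 - rc - rp; travelling 400 shrinks centre distance by 400
  mv <- chemotaxis_step(pos, h, 400, cell_radius = 0.5,
                        target_pos = tgt, target_radius = 10, L = L)
  expect_equal(sqrt(sum((tgt - mv$pos)^2)), 600)
  expect_equal(mv$dist, 400)
  # never overshoots into the target: travel stops at contact
  mv2 <- chemotaxis_step(pos, h, 5000, cell_radius = 0.5,
                         target_pos = tgt, target_radius = 10, L = L)
  expect_equal(sqrt(sum((tgt - mv2$pos)^2)), 10.5)
  # no consumable particle anywhere: identical to run-and-tumble
  # under the same rng state
  set.seed(99)
  fb <- chemotaxis_step(pos, h, 700, cell_radius = 0.5,
                        target_pos = matrix(NA_real_, 1, 3),
                        target_radius = NA_real_, L = L)
  set.seed(99)
  rt <- run_tumble_step(pos, h, 700, L)
  expect_identical(fb$pos, rt$pos)
  expect_identical(fb$heading, rt$heading)
})

test_that("nearest consumable particle filters by diet and breaks ties low", {
  expect_true(is.na(nearest_consumable(c(0, 0, 0), 1, new_particles(),
                                       matrix(TRUE, 1, 11))))
  cons <- matrix(FALSE, 1, 11); cons[1, 2] <- TRUE
  parts <- build_particles(rtype = c(1L, 2L), content = c(1000, 1000),
                           x = c(10, 500), y = c(0, 0), z = c(0, 0))
  # the nearer particle is of an inedible type; returns the consumable one
  expect_equal(nearest_consumable(c(0, 0, 0), 1, parts, cons), 2L)
  # exact tie: lowest particle id wins
  parts2 <- build_particles(rtype = 1L, content = c(1000, 1000),
                            x = c(100, 300), y = c(0, 0), z = c(0, 0))
  expect_equal(nearest_consumable(c(200, 0, 0), 1, parts2,
                                  matrix(TRUE, 1, 11)), 1L)
})

test_that("the spatial-grid kernel matches the brute-force oracle", {
  withr::with_seed(21, {
    n <- 80; m <- 200; S <- 6
    cons <- matrix(runif(S * 11) < 0.4, S, 11)
    inds <- build_individuals(sample(S, n, TRUE), runif(n, 0.3, 1),
                              runif(n, 0, L), runif(n, 0, L), runif(n, 0, L))
    parts <- build_particles(sample(11, m, TRUE),
                             10^runif(m, 0, 4),
                             runif(m, 0, L), runif(m, 0, L), runif(m, 0, L))
    traits <- list(table = NULL, consumable = cons, product = NULL, S = S)
    got <- seedbankIBM:::nearest_particles(inds, parts, traits, L = L)
    want <- oracle_nearest(inds$x, inds$y, inds$z,
                           diameter_from_quota(inds$quota) / 2,
                           inds$species, parts, cons)
    expect_identical(parts$id[got$near_idx], want$near)
    expect_identical(parts$id[got$touch_idx], want$touch)
  })
})
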