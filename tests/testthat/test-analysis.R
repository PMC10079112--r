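rec_of <- function(pre, peak) list(effector_pre = pre, effector_peak = peak)

test_that("inducibility is the induced share of the peak response", {
  expect_equal(inducibility(rec_of(0, 0.8)), 1)
  expect_equal(inducibility(rec_of(0.6, 0.6)), 0)
  expect_equal(inducibility(rec_of(0.2, 0.8)), 0.75)
  expect_equal(inducibility(rec_of(0, 0)), 0)   # no response mounted
  set.seed(71)
  for (k in 1:50) {
    peak <- runif(1)
    pre <- runif(1, 0, peak)
    v <- inducibility(rec_of(pre, peak))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("response densities are peak-normalized and locate the mass", {
  d <- response_density(rep(1, 40))
  expect_equal(max(d$y), 1)
  expect_equal(density_peak(d), 1)

  # symmetric bimodal sample: two equal peaks, reflected at the borders
  d2 <- response_density(rep(c(0.1, 0.9), each = 100), bandwidth = 0.03)
  y_at <- function(d, x) d$y[which.min(abs(d$x - x))]
  expect_equal(y_at(d2, 0.1), y_at(d2, 0.9), tolerance = 1e-10)
  expect_equal(max(d2$y), 1)
  expect_lt(y_at(d2, 0.5), 0.05)

  expect_error(response_density(numeric(0)), "no data")
})

test_that("the KDE recovers known mixture components", {
  set.seed(72)
  x <- c(pmin(pmax(rnorm(250, 0.25, 0.04), 0), 1),
         pmin(pmax(rnorm(250, 0.75, 0.04), 0), 1))
  d <- response_density(x)
  step <- d$x[2] - d$x[1]
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  expect_true(any(abs(peaks - 0.25) <= step))
  expect_true(any(abs(peaks - 0.75) <= step))
})

test_that("density correlation behaves on constructed cases", {
  set.seed(73)
  a <- response_density(runif(100))
  expect_equal(density_correlation(a, a), 1)

  # a density symmetric about 0.5 equals its own reversal
  x <- runif(200)
  sym <- response_density(c(x, 1 - x), bandwidth = 0.05)
  rev_sym <- sym
  rev_sym$y <- rev(rev_sym$y)
  expect_equal(density_correlation(sym, rev_sym), 1, tolerance = 1e-10)

  lo <- response_density(rep(0.02, 50), bandwidth = 0.05)
  hi <- response_density(rep(0.98, 50), bandwidth = 0.05)
  expect_lt(density_correlation(lo, hi), 0)

  expect_error(density_correlation(a, response_density(runif(10),
                                                       n_grid = 11)),
               "grid")
})

test_that("2D densities pool runs additively and integrate to run count", {
  one <- tibble::tibble(inducibility = 0.3, effector_peak = 0.7)
  d <- magnitude_inducibility_density(one, bandwidth = c(0.05, 0.05))
  top <- which(d$z == 1, arr.ind = TRUE)
  expect_equal(d$x[top[1]], 0.3, tolerance = 0.03)
  expect_equal(d$y[top[2]], 0.7, tolerance = 0.03)

  two <- tibble::tibble(
    inducibility = c(rep(0.1, 30), rep(0.9, 30)),
    effector_peak = c(rep(0.2, 30), rep(0.8, 30)),
    run = rep(1:2, each = 30))
  d2 <- magnitude_inducibility_density(two, bandwidth = c(0.04, 0.04))
  at <- function(d, x, y)
    d$z[which.min(abs(d$x - x)), which.min(abs(d$y - y))]
  expect_gt(at(d2, 0.1, 0.2), 0.5)
  expect_gt(at(d2, 0.9, 0.8), 0.5)
  expect_lt(at(d2, 0.5, 0.5), 0.05)
  cell <- (d2$x[2] - d2$x[1]) * (d2$y[2] - d2$y[1])
  expect_equal(sum(d2$z_raw) * cell, 2, tolerance = 0.05)
})

test_that("knockout divergence isolates a protein's contribution", {
  roles4 <- c("detector", "signaling", "signaling", "effector")
  # relay chain D -> S2 -> E with an isolated extra protein S3
  W <- matrix(0, 4, 4)
  W[1, 2] <- 1
  W[2, 4] <- 1
  net <- immune_network(1:4, roles4, W)
  dyn0 <- dynamics_params(use_coef = 0)

  # knocking out the isolated protein changes nothing
  expect_equal(knockout_divergence(net, 3L, dyn0), 0)
  # knocking out the sole relay silences the induced response
  expect_gt(knockout_divergence(net, 2L, dyn0), 0)
  expect_error(knockout_divergence(net, 4L), "signaling")

  # identical trajectories diverge by exactly zero
  tr <- pleiosim:::infection_effector_trace(net, dyn0, fitness_params())
  expect_length(tr, 20)                       # no early termination
  expect_equal(mean(abs(tr - tr)), 0)
})

test_that("knockout contrasts run an equal-variance t-test with Bonferroni", {
  same <- c(0.1, 0.1, 0.1)
  res <- knockout_contrast(same, same)
  expect_equal(res$p_raw, 1)
  expect_false(res$significant)

  set.seed(74)
  a <- rnorm(50, 0, 0.1)
  b <- rnorm(50, 1, 0.1)
  res <- knockout_contrast(a, b, n_comparisons = 12)
  expect_lt(res$p_bonferroni, 0.05)
  expect_true(res$significant)
  # against the base implementation at one comparison
  ref <- t.test(a, b, var.equal = TRUE)$p.value
  res1 <- knockout_contrast(a, b, n_comparisons = 1)
  expect_equal(res1$p_raw, ref)
  expect_equal(res1$p_bonferroni, ref)
})

test_that("distinct paths count vertex-disjoint routes", {
  roles <- function(n) c("detector", rep("signaling", n - 2), "effector")
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- 0.5
  chain[2, 3] <- -0.5                          # signs are ignored
  expect_equal(distinct_paths(immune_network(1:3, roles(3), chain)), 1)

  two <- matrix(0, 4, 4)
  two[1, 2] <- 1; two[2, 4] <- 1
  two[1, 3] <- 1; two[3, 4] <- 1
  expect_equal(distinct_paths(immune_network(1:4, roles(4), two)), 2)

  # shared relay: both routes pass through node 2
  shared <- matrix(0, 5, 5)
  shared[1, 2] <- 1; shared[2, 3] <- 1; shared[2, 4] <- 1
  shared[3, 5] <- 1; shared[4, 5] <- 1
  expect_equal(distinct_paths(immune_network(1:5, roles(5), shared)), 1)

  expect_equal(distinct_paths(immune_network(
    1:3, roles(3), matrix(0, 3, 3))), 0)
})

test_that("distinct paths agree with exhaustive search on random graphs", {
  set.seed(75)
  for (k in 1:150) {
    n <- sample(4:8, 1)
    net <- random_small_net(n, p_edge = runif(1, 0.2, 0.7))
    expect_identical(distinct_paths(net), brute_force_distinct_paths(net))
  }
})

test_that("the modal network is found by exact-form counting", {
  set.seed(76)
  a <- init_random_network()
  b <- init_random_network()
  pop <- list(a, a, b)
  res <- most_common_network(pop, host_ids = c(3L, 7L, 1L))
  expect_equal(res$count, 2)
  expect_identical(res$network$W, a$W)
  expect_identical(res$host_ids, c(3L, 7L))

  # all distinct: count 1, lowest id wins
  res <- most_common_network(list(a, b), host_ids = c(9L, 2L))
  expect_equal(res$count, 1)
  expect_identical(res$network$W, b$W)

  # one altered weight separates otherwise identical networks
  a2 <- a
  nz <- which(a2$W != 0, arr.ind = TRUE)
  a2$W[nz[1, 1], nz[1, 2]] <- 0.123456789
  res <- most_common_network(list(a, a2, a2), host_ids = 1:3)
  expect_equal(res$count, 2)
  expect_identical(res$network$W, a2$W)
})

test_that("lineage splits need both strategies within one lineage", {
  recs <- function(lin, ind) tibble::tibble(lineage_id = lin,
                                            inducibility = ind)
  expect_false(lineage_split(recs(c(1, 1, 1), c(0.1, 0.2, 0.05))))
  expect_true(lineage_split(recs(c(1, 1), c(0.1, 0.9))))
  # two pure lineages: divergence is between, not within
  expect_false(lineage_split(recs(c(1, 1, 2, 2), c(0.9, 0.8, 0.1, 0.2))))
  expect_false(lineage_split(recs(1, NA_real_)))
})

test_that("run-level helpers expose profiles and knockout tables", {
  run <- run_coevolution(simulation_config(
    n_hosts = 15, n_generations = 3, seed = 8, infection_chance = 0.9,
    pleiotropy_mode = "fixed-down"))
  prof <- response_profiles(run)
  expect_true(all(prof$inducibility >= 0 & prof$inducibility <= 1))
  expect_equal(nrow(prof), sum(!is.na(run$records_final$inducibility)))

  kt <- knockout_table(run)
  expect_true(any(kt$pleiotropic))
  expect_true(all(kt$divergence >= 0))
})
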