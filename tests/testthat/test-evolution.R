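# force exactly one mutation regardless of the per-offspring rate
force_mutation <- function(net, params = evolution_params()) {
  pleiosim:::apply_host_mutation(net, params)
}

test_that("pleiotropy modes install the advertised constraints", {
  set.seed(51)
  net <- init_random_network()

  expect_null(apply_pleiotropy(net, "none")$pleio)

  down <- apply_pleiotropy(net, "fixed-down")
  p <- match(down$pleio$node, down$ids)
  e <- match(effector_id(down), down$ids)
  expect_equal(sum(down$locked), 1)
  expect_true(down$locked[p, e])
  expect_equal(down$W[p, e], -1)

  up <- apply_pleiotropy(net, "fixed-up")
  p <- match(up$pleio$node, up$ids)
  expect_equal(up$W[p, e], 1)
  expect_true(up$locked[p, e])

  slow <- apply_pleiotropy(net, "slow")
  expect_equal(slow$pleio$mode, "slow")
  expect_equal(sum(slow$locked), 0)

  rnd <- apply_pleiotropy(net, "fixed-random")
  p <- match(rnd$pleio$node, rnd$ids)
  incident <- net$W != 0
  keep <- matrix(FALSE, 5, 5)
  keep[p, ] <- TRUE
  keep[, p] <- TRUE
  expect_identical(rnd$locked, incident & keep)
})

test_that("zero mutation rate copies the parent exactly", {
  set.seed(52)
  net <- init_random_network()
  off <- mutate_host(net, evolution_params(host_mutation_rate = 0))
  expect_identical(off$W, net$W)
  p <- parasite(2L, 0.4)
  expect_equal(mutate_parasite(p, 2:4,
                               evolution_params(parasite_mutation_rate = 0))[
                                 c("target", "manipulation")],
               p[c("target", "manipulation")])
})

test_that("locked pleiotropic edges survive any mutation stream", {
  set.seed(53)
  for (mode in c("fixed-down", "fixed-random")) {
    net <- apply_pleiotropy(init_random_network(), mode)
    locked_cells <- which(net$locked, arr.ind = TRUE)
    locked_edges <- data.frame(
      src = net$ids[locked_cells[, 1]], dst = net$ids[locked_cells[, 2]],
      w = net$W[locked_cells])
    cur <- net
    ok_locks <- TRUE
    ok_structure <- TRUE
    for (k in 1:2000) {
      cur <- force_mutation(cur)$net
      for (r in seq_len(nrow(locked_edges))) {
        i <- match(locked_edges$src[r], cur$ids)
        j <- match(locked_edges$dst[r], cur$ids)
        ok_locks <- ok_locks && !is.na(i) && !is.na(j) &&
          identical(cur$W[i, j], locked_edges$w[r])
      }
      d <- which(cur$roles == "detector")
      e <- which(cur$roles == "effector")
      ok_structure <- ok_structure && length(d) == 1 && length(e) == 1 &&
        net$pleio$node %in% cur$ids && cur$W[d, e] == 0
    }
    expect_true(ok_locks)      # presence and weight preserved throughout
    expect_true(ok_structure)  # roles intact, forbidden edge never created
  }
})

test_that("duplication copies the full edge neighborhood", {
  # signaling node 2: in-degree 2, out-degree 1, no self-edge
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.5
  W[3, 2] <- -0.2
  W[2, 4] <- 0.9
  net <- immune_network(1:4, c("detector", "signaling", "signaling",
                               "effector"), W)
  params <- evolution_params(host_mutation_weights = c(
    add_edge = 0, del_edge = 0, alter_weight = 0, del_protein = 0,
    dup_protein = 1))
  set.seed(54)
  off <- force_mutation(net, params)$net
  # the duplicated node may be 2 or 3; force node 2 by repeating
  while (off$W[5, 4] == 0) off <- force_mutation(net, params)$net
  expect_length(off$ids, 5)
  expect_equal(sum(off$W != 0), sum(net$W != 0) + 3)
  expect_equal(off$W[1, 5], 0.5)
  expect_equal(off$W[3, 5], -0.2)
  expect_equal(off$W[5, 4], 0.9)
  expect_equal(off$roles[5], "signaling")

  # a self-edge duplicates as a self-edge on the copy, not a cross-edge
  W2 <- W
  W2[2, 2] <- 0.3
  net2 <- immune_network(1:4, net$roles, W2)
  off2 <- force_mutation(net2, params)$net
  while (off2$W[5, 4] == 0) off2 <- force_mutation(net2, params)$net
  expect_equal(off2$W[5, 5], 0.3)
  expect_equal(off2$W[2, 5], 0)
  expect_equal(off2$W[5, 2], 0)
})

test_that("a duplicated pleiotropic protein's paralog is unconstrained", {
  set.seed(55)
  net <- apply_pleiotropy(init_random_network(), "fixed-down")
  params <- evolution_params(host_mutation_weights = c(
    add_edge = 0, del_edge = 0, alter_weight = 0, del_protein = 0,
    dup_protein = 1))
  p <- match(net$pleio$node, net$ids)
  off <- force_mutation(net, params)$net
  while (length(off$ids) != 6 || off$W[6, 5] == 0 ||
         !identical(off$W[6, 5], net$W[p, 5]))
    off <- force_mutation(net, params)$net      # until the pleio node dups
  expect_false(any(off$locked[6, ]))
  expect_false(any(off$locked[, 6]))
  expect_equal(off$pleio$node, net$pleio$node)  # original stays pleiotropic
})

test_that("parasite mutations retarget or reweight in fair proportion", {
  set.seed(56)
  params <- evolution_params(parasite_mutation_rate = 1)
  p <- parasite(2L, 0.123)
  expect_equal(mutate_parasite(p, 2L, params)$target, 2L)  # single choice

  n <- 5000
  retargeted <- 0
  reweighted <- 0
  for (k in seq_len(n)) {
    off <- mutate_parasite(parasite(99L, 0.123), 1:10, params)
    if (off$target != 99L) retargeted <- retargeted + 1
    if (off$manipulation != 0.123) reweighted <- reweighted + 1
  }
  # the old target 99 is outside the pool, so every retarget draw changes it
  expect_lt(abs(retargeted / n - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(reweighted / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("culling prioritizes infection deaths and honors the cap", {
  set.seed(57)
  n <- 100
  params <- evolution_params()                   # cap 0.3
  # 40% succumbed: exactly 30 die, the excess 10 restored at random
  died <- rep(c(TRUE, FALSE), c(40, 60))
  res <- cull_population(runif(n), died, params)
  expect_length(res$deaths, 30)
  expect_true(all(res$deaths <= 40))             # only infected died
  expect_length(res$survivors, 70)

  # deaths never exceed the cap for random inputs
  for (k in 1:20) {
    n <- sample(10:200, 1)
    died <- runif(n) < runif(1)
    res <- cull_population(runif(n), died, params)
    expect_lte(length(res$deaths), ceiling(0.3 * n))
    expect_setequal(c(res$survivors, res$deaths), seq_len(n))
  }
})

test_that("reproduction restores the population from any survivor set", {
  set.seed(58)
  net <- init_random_network()
  params <- evolution_params(host_mutation_rate = 0)

  one <- reproduce_hosts(list(net), 1, 50, params)
  expect_length(one$nets, 50)
  expect_true(all(one$parent_idx == 1))
  expect_true(all(vapply(one$nets, function(x)
    identical(x$W, net$W), logical(1))))

  for (k in c(2, 7, 30)) {
    surv <- replicate(k, init_random_network(), simplify = FALSE)
    out <- reproduce_hosts(surv, runif(k), 50, params)
    expect_length(out$nets, 50)
  }
  expect_error(reproduce_hosts(list(), numeric(0), 10, params),
               class = "pleiosim_extinct")
})

test_that("parasite offspring quotas follow the load bins", {
  quota <- function(load) 1L + (load > 0.33) + (load > 0.66)
  expect_identical(quota(0), 1L)
  expect_identical(quota(0.33), 1L)
  expect_identical(quota(0.5), 2L)
  expect_identical(quota(0.66), 2L)
  expect_identical(quota(0.9), 3L)

  set.seed(59)
  params <- evolution_params(parasite_mutation_rate = 0)
  mk <- function(load, target) {
    p <- parasite(target, 0.1)
    p$cumulative_load <- load
    p$host_signaling_ids <- 2:4
    p
  }
  # one high-load and one low-load parent, target_size 4: the high-load
  # parent contributes its quota of 3 before the low-load parent cycles in
  out <- reproduce_parasites(list(mk(0.1, 7L), mk(0.9, 8L)), 4, params)
  expect_equal(vapply(out, function(p) p$target, integer(1)),
               c(8L, 8L, 8L, 7L))

  # all loads zero: everyone contributes one per cycle until replenished
  out <- reproduce_parasites(list(mk(0, 1L), mk(0, 2L)), 5, params)
  expect_length(out, 5)
  expect_error(reproduce_parasites(list(), 5, params),
               class = "pleiosim_extinct")
})
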