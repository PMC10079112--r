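small_config <- function(...) {
  defaults <- list(n_hosts = 20, n_generations = 5, seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

test_that("a generation without infection uses the two-term fitness", {
  set.seed(61)
  cfg <- small_config(infection_chance = 0)
  hosts <- pleiosim:::init_host_population(cfg)
  pre <- vapply(hosts, function(h)
    healthy_equilibrium(h, cfg$dynamics)$effector_pre, numeric(1))
  gen <- run_generation(hosts, list(), cfg)
  expect_equal(gen$summary$n_infected, 0)
  expect_equal(gen$summary$n_uninfected, 20)
  expect_equal(gen$summary$mean_fitness, mean(exp(-2 * pre)))
  expect_length(gen$hosts, 20)
  expect_length(gen$parasites, 0)
})

test_that("full infection yields one parasite per host", {
  set.seed(62)
  cfg <- small_config(infection_chance = 1, n_hosts = 10)
  hosts <- pleiosim:::init_host_population(cfg)
  parasites <- pleiosim:::init_parasite_population(cfg)
  expect_length(parasites, 10)
  gen <- run_generation(hosts, parasites, cfg)
  expect_equal(gen$summary$n_infected, 10)
  expect_equal(gen$summary$n_cleared + gen$summary$n_managed +
                 gen$summary$n_dead, 10)
  expect_length(gen$parasites, 10)
  expect_length(gen$hosts, 10)
})

test_that("coevolution archives have the advertised shape", {
  run <- run_coevolution(simulation_config(n_hosts = 10, n_generations = 1,
                                           seed = 5))
  expect_s3_class(run, "coevolution_run")
  expect_equal(nrow(run$summary), 1)
  expect_length(run$hosts_final, 10)
  expect_equal(nrow(run$records_final), 10)
  expect_equal(nrow(run$ancestry), 10)

  run5 <- run_coevolution(small_config())
  expect_equal(nrow(run5$summary), 5)
  expect_equal(run5$summary$n_pleiotropic + run5$summary$n_non_pleiotropic,
               rep(20, 5))
  expect_equal(nrow(run5$ancestry), 5 * 20)
  expect_s3_class(tidy(run5), "tbl_df")
  expect_equal(nrow(glance(run5)), 1)
})

test_that("runs are deterministic in the seed and vary across seeds", {
  cfg <- small_config(infection_chance = 0.5)
  a <- run_coevolution(cfg)
  b <- run_coevolution(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$records_final, b$records_final)
  expect_identical(
    vapply(a$hosts_final, pleiosim:::network_key, character(1)),
    vapply(b$hosts_final, pleiosim:::network_key, character(1)))

  c <- run_coevolution(small_config(seed = 43))
  expect_false(identical(a$summary, c$summary))
})

test_that("population size is constant and composition counts add up", {
  run <- run_coevolution(small_config(pleiotropy_mode = "fixed-up",
                                      infection_chance = 0.9))
  expect_true(all(run$summary$n_hosts == 20))
  expect_true(all(run$summary$n_pleiotropic == 20))
  expect_true(all(run$summary$n_cleared + run$summary$n_managed +
                    run$summary$n_dead + run$summary$n_uninfected == 20))
})

test_that("competition merges, tracks composition, and is reproducible", {
  cfg <- simulation_config(n_hosts = 16, n_generations = 5, seed = 9,
                           infection_chance = 0.5,
                           pleiotropy_mode = "fixed-down")
  res <- run_competition(cfg, pre_evolution_generations = 2,
                         max_generations = 4)
  expect_s3_class(res, "competition_run")
  expect_true(res$winner %in% c("pleiotropic", "non_pleiotropic", "draw"))
  comp <- dplyr::filter(res$summary, phase == "competition")
  expect_equal(comp$n_hosts[1], 16)              # 8 + 8 merged
  expect_true(all(comp$n_pleiotropic + comp$n_non_pleiotropic == 16))
  iso <- dplyr::filter(res$summary, phase != "competition")
  expect_equal(nrow(iso), 4)                     # 2 generations x 2 sides

  res2 <- run_competition(cfg, pre_evolution_generations = 2,
                          max_generations = 4)
  expect_identical(res$summary, res2$summary)
  expect_identical(res$winner, res2$winner)

  # unevolved competition collapses straight into the merged arena
  res0 <- run_competition(cfg, pre_evolution_generations = 0,
                          max_generations = 3)
  expect_false(any(res0$summary$phase != "competition"))
})

test_that("archives round-trip through disk", {
  run <- run_coevolution(small_config(pleiotropy_mode = "slow",
                                      infection_chance = 0.5))
  dir <- withr::local_tempdir()
  write_run_archive(run, dir)
  expect_true(all(file.exists(file.path(
    dir, c("summary.tsv", "ancestry.tsv", "records_final.tsv",
           "hosts_final.json", "parasites_final.json",
           "config_echo.yaml")))))
  back <- read_run_archive(dir)
  expect_equal(as.data.frame(back$summary), as.data.frame(run$summary))
  expect_identical(
    vapply(back$hosts_final, pleiosim:::network_key, character(1)),
    vapply(run$hosts_final, pleiosim:::network_key, character(1)))
  expect_identical(back$host_ids, run$host_ids)
  expect_equal(back$config$infection_chance, run$config$infection_chance)
  expect_equal(length(back$parasites_final), length(run$parasites_final))
  # the archive alone feeds the analysis metrics
  expect_s3_class(response_density(stats::na.omit(
    back$records_final$inducibility)), "response_density")
  expect_type(lineage_split(back$records_final), "logical")
  expect_type(connectivity(most_common_network(back$hosts_final)$network),
              "double")
})

test_that("sweeps return one glance row per run", {
  sw <- run_sweep(modes = c("none", "fixed-down"), infection_chances = 0.5,
                  n_replicates = 2, seed = 1, n_hosts = 10,
                  n_generations = 3)
  expect_equal(nrow(sw), 4)
  expect_true(all(c("mode", "infection_chance", "replicate",
                    "mean_inducibility", "mean_connectivity")
                  %in% names(sw)))
})
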