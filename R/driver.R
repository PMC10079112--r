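# ---- population construction ----------------------------------------------

init_host_population <- function(config) {
  lapply(seq_len(config$n_hosts), function(i) {
    net <- init_random_network(config$n_signaling, lineage_id = i)
    apply_pleiotropy(net, config$pleiotropy_mode)
  })
}

init_parasite_population <- function(config) {
  n_inf <- round(config$infection_chance * config$n_hosts)
  sig0 <- seq.int(2L, 1L + config$n_signaling)   # initial signaling ids
  lapply(seq_len(n_inf), function(i) {
    p <- parasite(resample(sig0, 1), runif(1, -1, 1))
    p$host_signaling_ids <- sig0
    p
  })
}

# ---- one generation --------------------------------------------------------

# Full cycle on an evaluated population: healthy equilibria (cached per
# genotype), random infection pairing, infection episodes, fitness,
# culling, and reproduction.  Returns both the next generation and the
# evaluated population's records.
generation_step <- function(nets, host_ids, parasites, config, gen,
                            next_id) {
  dyn <- config$dynamics
  fit <- config$fitness
  evo <- config$evolution
  n <- length(nets)

  # healthy equilibrium once per distinct genotype
  gids <- vapply(nets, function(x) x$gid, integer(1))
  eq_of <- match(gids, gids)        # index of first host with same genotype
  eq_state <- vector("list", n)
  eff_pre <- numeric(n)
  for (i in seq_len(n)) {
    if (eq_of[i] == i) {
      net <- nets[[i]]
      e_idx <- which(net$roles == "effector")
      eq <- .cpp_equilibrium(net$W,
                             rep(dyn$initial_active, length(net$ids)),
                             dyn$use_coef, e_idx, dyn$equilibrium_tol,
                             dyn$max_equilibrium_steps)
      eq_state[[i]] <- eq$state
      eff_pre[i] <- eq$effector
    } else {
      eq_state[[i]] <- eq_state[[eq_of[i]]]
      eff_pre[i] <- eff_pre[eq_of[i]]
    }
  }

  # infection assignment: a uniform random host<->parasite bijection
  n_inf <- round(config$infection_chance * n)
  infected <- if (n_inf > 0) resample(seq_len(n), n_inf) else integer(0)
  if (n_inf > 0) {
    if (length(parasites) < n_inf) {
      parasites <- c(parasites,
                     parasites[sample.int(length(parasites),
                                          n_inf - length(parasites),
                                          replace = TRUE)])
    } else if (length(parasites) > n_inf) {
      parasites <- parasites[resample(seq_along(parasites), n_inf)]
    }
    pairing <- sample.int(n_inf)    # parasite index per infected host
  }

  outcome <- rep("uninfected", n)
  area <- numeric(n)
  eff_post <- eff_pre
  eff_peak <- eff_pre
  par_load <- numeric(length(parasites))
  par_died <- logical(length(parasites))

  for (k in seq_len(n_inf)) {
    i <- infected[k]
    net <- nets[[i]]
    pk <- pairing[k]
    par <- parasites[[pk]]
    sig <- signaling_ids(net)
    if (is.na(par$target) || !par$target %in% sig) {
      if (par$manipulation != 0) par$target <- resample(sig, 1)
    }
    par$host_signaling_ids <- sig
    d_idx <- which(net$roles == "detector")
    e_idx <- which(net$roles == "effector")
    t_idx <- if (par$manipulation != 0) match(par$target, net$ids)
             else NA_integer_
    A <- augment_matrix(net$W, d_idx, e_idx, t_idx, par$manipulation)
    res <- .cpp_infection(A, c(eq_state[[i]], dyn$parasite_initial_active),
                          dyn$use_coef, e_idx, length(net$ids) + 1L,
                          fit$clearance_threshold,
                          fit$death_area_threshold,
                          fit$max_infection_steps, TRUE)
    outcome[i] <- outcome_labels[res$outcome]
    area[i] <- res$area
    eff_post[i] <- res$eff_trace[length(res$eff_trace)]
    eff_peak[i] <- max(eff_pre[i], res$eff_trace)
    par$cumulative_load <- res$area
    par_load[pk] <- res$area
    par_died[pk] <- outcome[i] %in% c("cleared", "host_death")
    parasites[[pk]] <- par
  }

  sizes <- vapply(nets, function(x) length(x$ids), integer(1))
  fitness <- exp(-(eff_pre + fit$virulence * area + eff_post +
                     protein_cost(sizes, fit)))
  inducib <- ifelse(eff_peak > 0, (eff_peak - eff_pre) / eff_peak, 0)
  inducib <- pmin(pmax(inducib, 0), 1)
  is_pleio <- vapply(nets, function(x) !is.null(x$pleio), logical(1))

  # death and reproduction; hosts that succumbed to infection are barred
  # from reproducing even when the death cap restored them to the
  # population (fallback to all survivors if nobody else is left)
  cull <- cull_population(fitness, outcome == "host_death", evo)
  breeders <- cull$survivors[outcome[cull$survivors] != "host_death"]
  if (length(breeders) == 0) breeders <- cull$survivors
  rep_h <- reproduce_hosts(nets[breeders], fitness[breeders], n, evo)
  child_ids <- next_id + seq_len(n) - 1L

  parasites_next <- list()
  if (length(parasites) > 0) {
    cull_p <- cull_population(par_load, par_died, evo)
    parasites_next <- reproduce_parasites(parasites[cull_p$survivors],
                                          n_inf, evo)
  }

  conn <- vapply(nets, connectivity, numeric(1))
  summary <- list(
    generation = gen,
    n_hosts = n,
    n_infected = n_inf,
    n_cleared = sum(outcome == "cleared"),
    n_managed = sum(outcome == "managed"),
    n_dead = sum(outcome == "host_death"),
    n_uninfected = sum(outcome == "uninfected"),
    mean_fitness = mean(fitness),
    median_fitness = stats::median(fitness),
    mean_parasite_load = if (n_inf > 0) mean(par_load) else NA_real_,
    mean_inducibility = if (n_inf > 0) mean(inducib[infected]) else NA_real_,
    mean_effector_pre = mean(eff_pre),
    mean_network_size = mean(sizes),
    mean_connectivity = mean(conn),
    n_pleiotropic = sum(is_pleio),
    n_non_pleiotropic = sum(!is_pleio))

  records <- tibble::tibble(
    generation = gen, host_id = host_ids,
    lineage_id = vapply(nets, function(x) x$lineage_id, integer(1)),
    pleiotropic = is_pleio, outcome = outcome,
    effector_pre = eff_pre, effector_post = eff_post,
    effector_peak = eff_peak, area = area, fitness = fitness,
    inducibility = ifelse(outcome == "uninfected", NA_real_, inducib))

  ancestry <- list(
    generation = rep(gen, n), child_id = child_ids,
    parent_id = host_ids[breeders][rep_h$parent_idx],
    lineage_id = vapply(rep_h$nets, function(x) x$lineage_id, integer(1)),
    mutation_type = rep_h$mutation_type)

  list(nets = rep_h$nets, host_ids = child_ids,
       parasites = parasites_next, next_id = next_id + n,
       summary = summary, records = records, ancestry = ancestry,
       eval_nets = nets, eval_ids = host_ids, eval_parasites = parasites)
}

#' Run one full generation
#'
#' Executes, in order: healthy equilibria for every host, random selection
#' of `round(infection_chance * n)` hosts paired one-to-one with the
#' parasites, infection episodes, fitness, fitness-weighted culling of
#' both populations (infection deaths first), and reproduction back to
#' constant population sizes (the parasite population size equals the
#' number of infections).
#'
#' @param hosts List of [immune_network()]s.
#' @param parasites List of [parasite()]s (resized to the infection count
#'   if it disagrees).
#' @param config A [simulation_config()].
#' @return A list with the next-generation `hosts` and `parasites` and a
#'   one-row `summary` tibble.  Seeding is the caller's business; the
#'   orchestrators seed once from `config$seed`.
#' @export
run_generation <- function(hosts, parasites, config) {
  step <- generation_step(hosts, seq_along(hosts), parasites, config,
                          gen = 1L, next_id = length(hosts) + 1L)
  list(hosts = step$nets, parasites = step$parasites,
       summary = tibble::as_tibble(step$summary))
}

# ---- coevolution -----------------------------------------------------------

#' Run a host-parasite coevolution simulation
#'
#' Seeds the RNG from `config$seed`, initializes `n_hosts` random networks
#' (with the configured pleiotropic constraint) and a matching parasite
#' population, and iterates [run_generation()] logic for `n_generations`.
#' The returned archive holds the per-generation summaries, the ancestry
#' log of every reproduction event, and the *final evaluated* population
#' (the hosts of the last generation together with their infection
#' records) -- everything the analysis metrics need, with no
#' re-simulation.
#'
#' @param config A [simulation_config()].
#' @return An object of class `coevolution_run` with elements `config`,
#'   `summary`, `ancestry`, `records_final`, `hosts_final`, `host_ids`,
#'   `parasites_final`.
#' @export
run_coevolution <- function(config) {
  set.seed(config$seed)
  nets <- init_host_population(config)
  parasites <- init_parasite_population(config)
  host_ids <- seq_len(config$n_hosts)
  next_id <- config$n_hosts + 1L

  summaries <- vector("list", config$n_generations)
  ancestry <- vector("list", config$n_generations)
  step <- NULL
  for (gen in seq_len(config$n_generations)) {
    step <- generation_step(nets, host_ids, parasites, config, gen, next_id)
    summaries[[gen]] <- step$summary
    ancestry[[gen]] <- step$ancestry
    nets <- step$nets
    host_ids <- step$host_ids
    parasites <- step$parasites
    next_id <- step$next_id
  }

  structure(list(
    config = config,
    summary = dplyr::bind_rows(lapply(summaries, tibble::as_tibble)),
    ancestry = bind_ancestry(ancestry),
    records_final = step$records,
    hosts_final = step$eval_nets,
    host_ids = step$eval_ids,
    parasites_final = step$eval_parasites),
    class = "coevolution_run")
}

bind_ancestry <- function(chunks) {
  tibble::tibble(
    generation = unlist(lapply(chunks, `[[`, "generation")),
    child_id = unlist(lapply(chunks, `[[`, "child_id")),
    parent_id = unlist(lapply(chunks, `[[`, "parent_id")),
    lineage_id = unlist(lapply(chunks, `[[`, "lineage_id")),
    mutation_type = unlist(lapply(chunks, `[[`, "mutation_type")))
}

#' @export
print.coevolution_run <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    paste0("<coevolution_run> %d hosts, %d generations, infection chance ",
           "%.2f, mode '%s'\n"),
    x$config$n_hosts, x$config$n_generations, x$config$infection_chance,
    x$config$pleiotropy_mode))
  cat(sprintf(
    "  final: mean fitness %.3f, mean inducibility %s, connectivity %.3f\n",
    last$mean_fitness,
    ifelse(is.na(last$mean_inducibility), "NA",
           sprintf("%.3f", last$mean_inducibility)),
    last$mean_connectivity))
  invisible(x)
}

# ---- competition -----------------------------------------------------------

#' Run a competitive simulation
#'
#' A pleiotropic population and a non-pleiotropic population (each half of
#' `config$n_hosts`, with their own parasites) evolve in isolation for
#' `pre_evolution_generations` (0 = unevolved competition), then hosts and
#' parasites are merged into a single arena where offspring inherit their
#' parent's pleiotropic status and both types compete for the same
#' reproductive slots under one fitness ranking.  The run ends when one
#' type is extinct, or in a draw after `max_generations` merged
#' generations.
#'
#' @param config A [simulation_config()]; `pleiotropy_mode` names the
#'   pleiotropic competitor.
#' @param pre_evolution_generations Isolated generations before the merge
#'   (study conditions: 0 or 250).
#' @param max_generations Merged-generation cap before declaring a draw
#'   (default 1000).
#' @return An object of class `competition_run` with `winner` (one of
#'   `"pleiotropic"`, `"non_pleiotropic"`, `"draw"`),
#'   `generations_elapsed` (merged generations), per-generation `summary`
#'   (with phase and composition counts), and the final populations.
#' @export
run_competition <- function(config, pre_evolution_generations = 0L,
                            max_generations = 1000L) {
  stopifnot(config$pleiotropy_mode != "none")
  set.seed(config$seed)
  n_each <- config$n_hosts %/% 2L

  make_side <- function(mode, lineage_offset, id_offset) {
    nets <- lapply(seq_len(n_each), function(i) {
      net <- init_random_network(config$n_signaling,
                                 lineage_id = lineage_offset + i)
      apply_pleiotropy(net, mode)
    })
    side_cfg <- config
    side_cfg$n_hosts <- n_each
    list(nets = nets, ids = id_offset + seq_len(n_each),
         parasites = init_parasite_population(side_cfg), cfg = side_cfg)
  }

  a <- make_side(config$pleiotropy_mode, 0L, 0L)
  b <- make_side("none", n_each, n_each)
  next_id <- 2L * n_each + 1L
  summaries <- list()

  for (gen in seq_len(pre_evolution_generations)) {
    sa <- generation_step(a$nets, a$ids, a$parasites, a$cfg, gen, next_id)
    a$nets <- sa$nets; a$ids <- sa$host_ids; a$parasites <- sa$parasites
    next_id <- sa$next_id
    sb <- generation_step(b$nets, b$ids, b$parasites, b$cfg, gen, next_id)
    b$nets <- sb$nets; b$ids <- sb$host_ids; b$parasites <- sb$parasites
    next_id <- sb$next_id
    row_a <- tibble::as_tibble(sa$summary)
    row_b <- tibble::as_tibble(sb$summary)
    row_a$phase <- "isolated_pleiotropic"
    row_b$phase <- "isolated_non_pleiotropic"
    summaries[[length(summaries) + 1L]] <- row_a
    summaries[[length(summaries) + 1L]] <- row_b
  }

  nets <- c(a$nets, b$nets)
  ids <- c(a$ids, b$ids)
  parasites <- c(a$parasites, b$parasites)
  winner <- "draw"
  gens_elapsed <- max_generations
  step <- NULL
  for (gen in seq_len(max_generations)) {
    step <- generation_step(nets, ids, parasites, config,
                            pre_evolution_generations + gen, next_id)
    nets <- step$nets; ids <- step$host_ids; parasites <- step$parasites
    next_id <- step$next_id
    row <- tibble::as_tibble(step$summary)
    row$phase <- "competition"
    summaries[[length(summaries) + 1L]] <- row
    n_pleio <- sum(vapply(nets, function(x) !is.null(x$pleio), logical(1)))
    if (n_pleio == 0L) {
      winner <- "non_pleiotropic"; gens_elapsed <- gen; break
    }
    if (n_pleio == length(nets)) {
      winner <- "pleiotropic"; gens_elapsed <- gen; break
    }
  }

  structure(list(
    config = config,
    pre_evolution_generations = as.integer(pre_evolution_generations),
    winner = winner, generations_elapsed = as.integer(gens_elapsed),
    summary = dplyr::bind_rows(summaries),
    records_final = if (!is.null(step)) step$records else NULL,
    hosts_final = nets, host_ids = ids, parasites_final = parasites),
    class = "competition_run")
}

#' @export
print.competition_run <- function(x, ...) {
  cat(sprintf(
    "<competition_run> mode '%s', winner: %s after %d merged generations\n",
    x$config$pleiotropy_mode, x$winner, x$generations_elapsed))
  invisible(x)
}

# ---- replicate sweeps ------------------------------------------------------

#' Run replicate coevolution simulations over a condition grid
#'
#' Executes `n_replicates` independent [run_coevolution()] runs for every
#' combination of pleiotropy mode and infection chance, each with its own
#' seed derived from `seed`, and returns one [glance()] row per run.
#'
#' @param modes Pleiotropy modes to sweep.
#' @param infection_chances Infection chances to sweep.
#' @param n_replicates Replicates per cell.
#' @param seed Base seed; replicate seeds are `seed + 1000 * k` for run
#'   counter `k`.
#' @param keep_runs If `TRUE`, the full run archives are attached as a
#'   list attribute `runs`.
#' @param ... Passed on to [simulation_config()] (e.g. `n_hosts`,
#'   `n_generations`).
#' @return A tibble with one row per run: the condition cell, the seed,
#'   and the run's [glance()] metrics.
#' @export
run_sweep <- function(modes = c("none", "fixed-random", "fixed-up",
                                "fixed-down", "slow"),
                      infection_chances = c(0.1, 0.5, 0.9),
                      n_replicates = 5, seed = 1L, keep_runs = FALSE,
                      ...) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      infection_chance = infection_chances,
                      mode = modes, stringsAsFactors = FALSE)
  runs <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- simulation_config(infection_chance = grid$infection_chance[k],
                             pleiotropy_mode = grid$mode[k],
                             seed = seed + 1000L * k, ...)
    run <- run_coevolution(cfg)
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(mode = grid$mode[k],
                     infection_chance = grid$infection_chance[k],
                     replicate = grid$replicate[k], seed = cfg$seed),
      glance(run))
    if (keep_runs) runs[[k]] <- run
  }
  out <- dplyr::bind_rows(rows)
  if (keep_runs) attr(out, "runs") <- runs
  out
}
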