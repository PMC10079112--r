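# ---- run archives on disk --------------------------------------------------

config_to_list <- function(config) {
  x <- rapply(unclass(config), unclass, how = "replace")
  # named vectors must become maps or yaml drops the names
  x$evolution$host_mutation_weights <-
    as.list(x$evolution$host_mutation_weights)
  x$evolution$parasite_mutation_weights <-
    as.list(x$evolution$parasite_mutation_weights)
  x
}

config_from_list <- function(x) {
  simulation_config(
    infection_chance = x$infection_chance,
    pleiotropy_mode = x$pleiotropy_mode,
    n_hosts = x$n_hosts, n_generations = x$n_generations,
    seed = x$seed, n_signaling = x$n_signaling,
    dynamics = do.call(dynamics_params, x$dynamics),
    fitness = do.call(fitness_params, x$fitness),
    evolution = do.call(
      evolution_params,
      within(x$evolution, {
        host_mutation_weights <- unlist(host_mutation_weights)
        parasite_mutation_weights <- unlist(parasite_mutation_weights)
      })))
}

parasite_to_list <- function(p) {
  list(target = p$target, manipulation = p$manipulation,
       cumulative_load = p$cumulative_load,
       host_signaling_ids = p$host_signaling_ids)
}

parasite_from_list <- function(x) {
  p <- parasite(x$target %||% NA_integer_, x$manipulation)
  p$cumulative_load <- x$cumulative_load %||% NA_real_
  p$host_signaling_ids <- as.integer(unlist(x$host_signaling_ids))
  p
}

#' Write a run archive to a directory
#'
#' Emits plain-text artifacts sufficient to re-run every analysis without
#' re-simulation: `summary.tsv` (one row per generation), `ancestry.tsv`
#' (one row per reproduction event), `records_final.tsv` (per-host
#' records of the final evaluated generation), `hosts_final.json` and
#' `parasites_final.json` (full-precision serialized populations), and
#' `config_echo.yaml`.  Competition runs additionally write `result.json`
#' with the winner and elapsed generations.
#'
#' @param run A `coevolution_run` or `competition_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_archive <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$summary, file.path(dir, "summary.tsv"))
  readr::write_tsv(run$records_final, file.path(dir, "records_final.tsv"))
  if (!is.null(run$ancestry))
    readr::write_tsv(run$ancestry, file.path(dir, "ancestry.tsv"))
  hosts <- lapply(seq_along(run$hosts_final), function(i) {
    c(list(host_id = run$host_ids[i]),
      network_to_list(run$hosts_final[[i]]))
  })
  jsonlite::write_json(hosts, file.path(dir, "hosts_final.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  jsonlite::write_json(lapply(run$parasites_final, parasite_to_list),
                       file.path(dir, "parasites_final.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  yaml::write_yaml(config_to_list(run$config),
                   file.path(dir, "config_echo.yaml"))
  if (inherits(run, "competition_run")) {
    jsonlite::write_json(
      list(winner = run$winner,
           generations_elapsed = run$generations_elapsed,
           pre_evolution_generations = run$pre_evolution_generations),
      file.path(dir, "result.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a run archive back from a directory
#'
#' @param dir A directory written by [write_run_archive()].
#' @return A `coevolution_run` (or `competition_run` when `result.json`
#'   is present).
#' @export
read_run_archive <- function(dir) {
  summary <- readr::read_tsv(file.path(dir, "summary.tsv"),
                             show_col_types = FALSE)
  records <- readr::read_tsv(file.path(dir, "records_final.tsv"),
                             show_col_types = FALSE)
  anc_path <- file.path(dir, "ancestry.tsv")
  ancestry <- if (file.exists(anc_path))
    readr::read_tsv(anc_path, show_col_types = FALSE) else NULL
  hosts_raw <- jsonlite::fromJSON(file.path(dir, "hosts_final.json"),
                                  simplifyVector = FALSE)
  hosts <- lapply(hosts_raw, network_from_list)
  host_ids <- vapply(hosts_raw, function(h) as.integer(h$host_id),
                     integer(1))
  parasites <- lapply(
    jsonlite::fromJSON(file.path(dir, "parasites_final.json"),
                       simplifyVector = FALSE),
    parasite_from_list)
  config <- config_from_list(yaml::read_yaml(
    file.path(dir, "config_echo.yaml")))
  out <- list(config = config, summary = summary, ancestry = ancestry,
              records_final = records, hosts_final = hosts,
              host_ids = host_ids, parasites_final = parasites)
  res_path <- file.path(dir, "result.json")
  if (file.exists(res_path)) {
    res <- jsonlite::fromJSON(res_path)
    out$winner <- res$winner
    out$generations_elapsed <- res$generations_elapsed
    out$pre_evolution_generations <- res$pre_evolution_generations
    class(out) <- "competition_run"
  } else {
    class(out) <- "coevolution_run"
  }
  out
}

# ---- broom-style accessors -------------------------------------------------

#' Tidy a simulation run
#'
#' @param x A `coevolution_run` or `competition_run`.
#' @param ... Unused.
#' @return The per-generation summary tibble.
#' @export
tidy.coevolution_run <- function(x, ...) x$summary

#' @rdname tidy.coevolution_run
#' @export
tidy.competition_run <- function(x, ...) x$summary

#' One-row summary of a simulation run
#'
#' @param x A `coevolution_run`.
#' @param ... Unused.
#' @return A tibble with the run's headline final-generation metrics:
#'   mean fitness, mean and peak-density inducibility among infected
#'   hosts, mean connectivity and network size, clearance/death counts,
#'   and whether any lineage split across the inducibility threshold.
#' @export
glance.coevolution_run <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  ind <- x$records_final$inducibility
  ind <- ind[!is.na(ind)]
  peak <- if (length(ind) > 0) density_peak(response_density(ind))
          else NA_real_
  tibble::tibble(
    n_generations = nrow(x$summary),
    n_hosts = last$n_hosts,
    mean_fitness = last$mean_fitness,
    mean_inducibility = last$mean_inducibility,
    peak_inducibility = peak,
    mean_connectivity = last$mean_connectivity,
    mean_network_size = last$mean_network_size,
    frac_cleared = last$n_cleared / max(last$n_infected, 1L),
    frac_dead = last$n_dead / max(last$n_infected, 1L),
    lineage_split = lineage_split(x$records_final))
}

#' @rdname glance.coevolution_run
#' @export
glance.competition_run <- function(x, ...) {
  tibble::tibble(
    winner = x$winner,
    generations_elapsed = x$generations_elapsed,
    pre_evolution_generations = x$pre_evolution_generations,
    n_pleiotropic_final = sum(vapply(x$hosts_final,
                                     function(h) !is.null(h$pleio),
                                     logical(1))),
    n_hosts = length(x$hosts_final))
}
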