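#' Within-host dynamics parameters
#'
#' @param use_coef Per-step activity cost paid by every protein for each of
#'   its outgoing regulatory edges (self-edges count; during infection the
#'   effector's edge onto the parasite counts too).  Nonnegative;
#'   default 0.01.
#' @param equilibrium_tol Healthy-phase convergence tolerance on the
#'   effector level between consecutive steps (default 1e-3).
#' @param max_equilibrium_steps Cap on healthy-phase iterations
#'   (default 200); guarantees termination, non-convergence is flagged.
#' @param initial_active Initial active fraction of every protein
#'   (default 0.5).
#' @param parasite_initial_active Parasite active fraction at infection
#'   onset (default 0.5).
#' @return A list of class `dynamics_params`.
#' @export
dynamics_params <- function(use_coef = 0.01, equilibrium_tol = 1e-3,
                            max_equilibrium_steps = 200L,
                            initial_active = 0.5,
                            parasite_initial_active = 0.5) {
  stopifnot(use_coef >= 0, equilibrium_tol >= 0,
            max_equilibrium_steps >= 1,
            initial_active >= 0, initial_active <= 1,
            parasite_initial_active >= 0, parasite_initial_active <= 1)
  structure(list(use_coef = use_coef, equilibrium_tol = equilibrium_tol,
                 max_equilibrium_steps = as.integer(max_equilibrium_steps),
                 initial_active = initial_active,
                 parasite_initial_active = parasite_initial_active),
            class = "dynamics_params")
}

#' Infection and fitness parameters
#'
#' @param virulence Damage coefficient `V` multiplying the normalized
#'   parasite area in the host fitness exponent (default 1).
#' @param clearance_threshold Parasite abundance below which the infection
#'   counts as cleared (default 1e-2).
#' @param death_area_threshold Normalized parasite area above which the
#'   host succumbs and is barred from reproducing (default 0.9).
#' @param max_infection_steps Length of the infection window, the host's
#'   reproductive lifespan (default 20 steps).
#' @param size_cost_threshold Network size (protein count) above which a
#'   fitness penalty accrues (default 10).
#' @param size_cost_slope Penalty per protein above the threshold
#'   (default 1.1).
#' @return A list of class `fitness_params`.
#' @export
fitness_params <- function(virulence = 1, clearance_threshold = 1e-2,
                           death_area_threshold = 0.9,
                           max_infection_steps = 20L,
                           size_cost_threshold = 10L,
                           size_cost_slope = 1.1) {
  stopifnot(virulence >= 0, clearance_threshold >= 0,
            death_area_threshold >= 0, max_infection_steps >= 1,
            size_cost_threshold >= 0, size_cost_slope >= 0)
  structure(list(virulence = virulence,
                 clearance_threshold = clearance_threshold,
                 death_area_threshold = death_area_threshold,
                 max_infection_steps = as.integer(max_infection_steps),
                 size_cost_threshold = as.integer(size_cost_threshold),
                 size_cost_slope = size_cost_slope),
            class = "fitness_params")
}

#' Mutation, death and reproduction parameters
#'
#' @param host_mutation_rate Probability that a host offspring is a mutated
#'   (rather than exact) copy of its parent (default 5e-3).
#' @param parasite_mutation_rate Same for parasite offspring (default 1e-2).
#' @param host_mutation_weights Named relative probabilities of the five
#'   host mutation types `add_edge`, `del_edge`, `alter_weight`,
#'   `del_protein`, `dup_protein` (defaults .25/.25/.3/.1/.1).
#' @param parasite_mutation_weights Named relative probabilities of
#'   `retarget` and `reweight` (defaults .5/.5).
#' @param death_cap Maximum fraction of either population that may die in
#'   one generation (default 0.3).
#' @param slow_factor Divisor applied to the mutation rate of edges
#'   incident to the pleiotropic protein under the `"slow"` constraint
#'   (default 100).
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(host_mutation_rate = 5e-3,
                             parasite_mutation_rate = 1e-2,
                             host_mutation_weights = c(
                               add_edge = 0.25, del_edge = 0.25,
                               alter_weight = 0.3, del_protein = 0.1,
                               dup_protein = 0.1),
                             parasite_mutation_weights = c(
                               retarget = 0.5, reweight = 0.5),
                             death_cap = 0.3, slow_factor = 100) {
  stopifnot(host_mutation_rate >= 0, host_mutation_rate <= 1,
            parasite_mutation_rate >= 0, parasite_mutation_rate <= 1,
            abs(sum(host_mutation_weights) - 1) < 1e-8,
            abs(sum(parasite_mutation_weights) - 1) < 1e-8,
            death_cap >= 0, death_cap <= 1, slow_factor >= 1)
  stopifnot(setequal(names(host_mutation_weights),
                     c("add_edge", "del_edge", "alter_weight",
                       "del_protein", "dup_protein")),
            setequal(names(parasite_mutation_weights),
                     c("retarget", "reweight")))
  structure(list(host_mutation_rate = host_mutation_rate,
                 parasite_mutation_rate = parasite_mutation_rate,
                 host_mutation_weights = host_mutation_weights,
                 parasite_mutation_weights = parasite_mutation_weights,
                 death_cap = death_cap, slow_factor = slow_factor),
            class = "evolution_params")
}

#' Configuration of a coevolution or competition run
#'
#' @param infection_chance Fraction of hosts infected each generation
#'   (study conditions use 0.1, 0.5 or 0.9; any value in `[0, 1]` is
#'   accepted).
#' @param pleiotropy_mode One of `"none"`, `"fixed-random"`, `"fixed-up"`,
#'   `"fixed-down"`, `"slow"`.
#' @param n_hosts Host population size, constant across generations
#'   (default 500; competitive runs split it half-and-half).
#' @param n_generations Number of generations (default 500).
#' @param seed Master seed; every random draw of the run flows from it.
#' @param n_signaling Signaling proteins in each initial network
#'   (default 3).
#' @param dynamics A [dynamics_params()] object.
#' @param fitness A [fitness_params()] object.
#' @param evolution An [evolution_params()] object.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(infection_chance = 0.5,
                              pleiotropy_mode = "none",
                              n_hosts = 500L, n_generations = 500L,
                              seed = 1L, n_signaling = 3L,
                              dynamics = dynamics_params(),
                              fitness = fitness_params(),
                              evolution = evolution_params()) {
  stopifnot(infection_chance >= 0, infection_chance <= 1, n_hosts > 0,
            n_generations >= 1)
  pleiotropy_mode <- match.arg(
    pleiotropy_mode,
    c("none", "fixed-random", "fixed-up", "fixed-down", "slow"))
  structure(list(infection_chance = infection_chance,
                 pleiotropy_mode = pleiotropy_mode,
                 n_hosts = as.integer(n_hosts),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed),
                 n_signaling = as.integer(n_signaling),
                 dynamics = dynamics, fitness = fitness,
                 evolution = evolution),
            class = "simulation_config")
}
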