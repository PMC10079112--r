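#' Parasites
#'
#' A parasite is defined by the signaling protein it targets and a signed
#' manipulation weight in `[-1, 1]` applied to that target during
#' infection.  A manipulation of exactly 0 means the parasite cannot
#' interfere with host signaling (the target edge is absent), in which case
#' `target` may be `NA`.
#'
#' @param target Id of the targeted signaling protein (never the detector
#'   or effector), or `NA` when `manipulation` is 0.
#' @param manipulation Signed regulatory weight on the target.
#' @return An object of class `parasite`.
#' @export
parasite <- function(target, manipulation) {
  stopifnot(abs(manipulation) <= 1)
  if (is.na(target) && manipulation != 0)
    stop("a manipulating parasite needs a target")
  structure(list(target = as.integer(target),
                 manipulation = manipulation,
                 cumulative_load = NA_real_,
                 host_signaling_ids = NULL),
            class = "parasite")
}

# augmented weight matrix: host block plus one parasite row/column with
# parasite->detector +1, parasite->parasite +0.8, parasite->target the
# manipulation weight, and effector->parasite -1
augment_matrix <- function(W, d_idx, e_idx, t_idx, manipulation) {
  n <- nrow(W)
  A <- matrix(0, n + 1, n + 1)
  A[seq_len(n), seq_len(n)] <- W
  q <- n + 1
  A[q, d_idx] <- 1
  A[q, q] <- 0.8
  if (manipulation != 0) A[q, t_idx] <- manipulation
  A[e_idx, q] <- -1
  A
}

#' Attach a parasite to a host network
#'
#' The parasite joins the dynamics as one extra node with three outgoing
#' connections -- `+1` to the detector (recognition), `+0.8` to itself
#' (replication), and its manipulation weight to the targeted signaling
#' protein -- while the host effector gains a `-1` connection onto the
#' parasite (killing).  The host network itself is not modified.
#'
#' @param net An [immune_network()].
#' @param parasite A [parasite()]; its target must be a signaling protein
#'   of `net` (or `NA` for a non-manipulating parasite).
#' @return A list of class `infection_graph` with the augmented weight
#'   matrix `W`, the host network, and the effector/parasite row indices.
#' @export
attach_parasite <- function(net, parasite) {
  t_idx <- NA_integer_
  if (parasite$manipulation != 0) {
    if (!parasite$target %in% signaling_ids(net))
      stop("parasite target must be a signaling protein of the host")
    t_idx <- node_index(net, parasite$target)
  }
  W <- augment_matrix(net$W, node_index(net, detector_id(net)),
                      node_index(net, effector_id(net)), t_idx,
                      parasite$manipulation)
  structure(list(W = W, net = net, parasite = parasite,
                 eff_idx = node_index(net, effector_id(net)),
                 par_idx = length(net$ids) + 1L),
            class = "infection_graph")
}

outcome_labels <- c("cleared", "managed", "host_death")

new_infection_record <- function(eff_trace, par_trace, outcome, area,
                                 effector_pre) {
  structure(list(
    effector_trace = eff_trace, parasite_trace = par_trace,
    outcome = outcome, area = area,
    effector_pre = effector_pre,
    effector_post = eff_trace[length(eff_trace)],
    effector_peak = max(effector_pre, eff_trace)),
    class = "infection_record")
}

#' Record of an uninfected host's "episode"
#'
#' For hosts that escape infection in a generation the fitness terms reduce
#' to the healthy equilibrium effector level counted both pre and post,
#' with zero parasite area.
#'
#' @param effector_pre Healthy-equilibrium effector level.
#' @return An `infection_record` with `outcome = "uninfected"`.
#' @export
uninfected_record <- function(effector_pre) {
  structure(list(effector_trace = numeric(0), parasite_trace = numeric(0),
                 outcome = "uninfected", area = 0,
                 effector_pre = effector_pre, effector_post = effector_pre,
                 effector_peak = effector_pre),
            class = "infection_record")
}

#' Run one infection episode
#'
#' Starting from the host's healthy equilibrium with the parasite at
#' `parasite_initial_active`, the augmented dynamics are iterated and
#' checked after every step, in order: (a) `max_infection_steps` elapsed
#' (the host's reproductive lifespan) -> `"managed"`; (b) parasite
#' abundance below `clearance_threshold` -> `"cleared"`; (c) running
#' normalized parasite area above `death_area_threshold` -> `"host_death"`.
#' The area is the summed parasite trace divided by `max_infection_steps`
#' regardless of when the episode ends, so fast clearance yields a small
#' area.
#'
#' @param net An [immune_network()].
#' @param parasite A [parasite()].
#' @param params A [dynamics_params()] object.
#' @param fitness A [fitness_params()] object (thresholds and step cap).
#' @param start_state The host's healthy-equilibrium [network_state()];
#'   computed via [healthy_equilibrium()] when omitted.
#' @return An `infection_record`: effector/parasite traces, `outcome`,
#'   normalized `area`, and the pre/post/peak effector levels.
#' @export
run_infection <- function(net, parasite, params = dynamics_params(),
                          fitness = fitness_params(), start_state = NULL) {
  if (is.null(start_state))
    start_state <- healthy_equilibrium(net, params)$state
  aug <- attach_parasite(net, parasite)
  p0 <- c(unname(start_state$active), params$parasite_initial_active)
  res <- .cpp_infection(aug$W, p0, params$use_coef, aug$eff_idx,
                        aug$par_idx, fitness$clearance_threshold,
                        fitness$death_area_threshold,
                        fitness$max_infection_steps, TRUE)
  eff_pre <- unname(start_state$active[node_index(net, effector_id(net))])
  new_infection_record(res$eff_trace, res$par_trace,
                       outcome_labels[res$outcome], res$area, eff_pre)
}

#' Network-size component of the host fitness penalty
#'
#' Zero up to `size_cost_threshold` proteins, then
#' `size_cost_slope * (size - size_cost_threshold)`.
#'
#' @param size Protein count.
#' @param params A [fitness_params()] object.
#' @return Nonnegative penalty.
#' @examples
#' protein_cost(12)  # 1.1 * (12 - 10) = 2.2
#' @export
protein_cost <- function(size, params = fitness_params()) {
  ifelse(size <= params$size_cost_threshold, 0,
         params$size_cost_slope * (size - params$size_cost_threshold))
}

#' Host fitness
#'
#' `W = exp(-(effector_pre + V * area + effector_post + protein_cost))`:
#' constitutive investment, parasite damage, residual (post-infection)
#' investment, and genome-size cost each reduce fitness multiplicatively.
#' Hosts whose episode ended in `"host_death"` keep their fitness value for
#' ranking but are flagged non-reproductive by the evolution engine.
#'
#' @param rec An `infection_record` (use [uninfected_record()] for hosts
#'   that escaped infection).
#' @param net The host [immune_network()] (for the size cost).
#' @param params A [fitness_params()] object.
#' @return Fitness in `(0, 1]`.
#' @export
host_fitness <- function(rec, net, params = fitness_params()) {
  exp(-(rec$effector_pre + params$virulence * rec$area +
          rec$effector_post + protein_cost(network_size(net), params)))
}

#' Parasite fitness
#'
#' The normalized area under the parasite's abundance curve from its most
#' recent infection: a proxy for total transmission potential.
#'
#' @param rec An `infection_record`.
#' @return Area in `[0, 1]`.
#' @export
parasite_fitness <- function(rec) rec$area
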