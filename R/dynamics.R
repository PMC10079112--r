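#' Per-protein network state
#'
#' Each protein exists as an active and an inactive fraction summing to 1;
#' only the active fraction acts on other proteins.  During infection the
#' parasite is carried as one extra abundance.
#'
#' @param active Named (by node id) numeric vector of active fractions in
#'   `[0, 1]`.
#' @param parasite_active Parasite active fraction, or `NULL` outside
#'   infection.
#' @return An object of class `network_state`.
#' @export
network_state <- function(active, parasite_active = NULL) {
  stopifnot(all(active >= 0 & active <= 1))
  if (!is.null(parasite_active))
    stopifnot(parasite_active >= 0, parasite_active <= 1)
  structure(list(active = active, parasite_active = parasite_active),
            class = "network_state")
}

initial_state <- function(net, params) {
  network_state(setNames(rep(params$initial_active, length(net$ids)),
                         net$ids))
}

#' Advance the within-host dynamics by one time step
#'
#' For every protein `i` the active fraction changes by the regulatory
#' balance `(1 - P*_i) * sum_j k_ij P*_j  -  P*_i * sum_j I_ij P*_j` minus
#' a flat use cost `use_coef * outdegree(i)`, and is then clamped to
#' `[0, 1]`.  All proteins update synchronously.  With a parasite attached
#' the parasite abundance follows the same rule on the augmented graph.
#'
#' @param net An [immune_network()].
#' @param state A [network_state()].
#' @param params A [dynamics_params()] object.
#' @param parasite Optional [parasite()]; when given, `state` must carry
#'   `parasite_active`.
#' @return The [network_state()] at the next step.
#' @export
step_dynamics <- function(net, state, params = dynamics_params(),
                          parasite = NULL) {
  if (is.null(parasite)) {
    if (length(state$active) != length(net$ids))
      stop("state does not match network (dangling endpoint?)")
    p1 <- .cpp_step(net$W, unname(state$active), params$use_coef)
    return(network_state(setNames(p1, net$ids)))
  }
  aug <- attach_parasite(net, parasite)
  if (is.null(state$parasite_active))
    stop("infected step needs a parasite_active fraction")
  p <- c(unname(state$active), state$parasite_active)
  p1 <- .cpp_step(aug$W, p, params$use_coef)
  n <- length(net$ids)
  network_state(setNames(p1[seq_len(n)], net$ids), p1[n + 1])
}

#' Run the healthy phase to effector equilibrium
#'
#' Iterates [step_dynamics()] from a uniform initial state until the
#' effector level changes by less than `equilibrium_tol` between
#' consecutive steps, or `max_equilibrium_steps` is reached.  The returned
#' effector level is the host's constitutive immune investment.
#'
#' @param net An [immune_network()].
#' @param params A [dynamics_params()] object.
#' @return A list with `state` (a [network_state()]), `effector_pre` (the
#'   equilibrium effector level), `steps`, and `converged`.
#' @examples
#' net <- immune_network(1:3, c("detector", "signaling", "effector"),
#'                       matrix(0, 3, 3))
#' healthy_equilibrium(net)$effector_pre  # 0.5: nothing regulates anything
#' @export
healthy_equilibrium <- function(net, params = dynamics_params()) {
  eq <- .cpp_equilibrium(net$W, rep(params$initial_active, length(net$ids)),
                         params$use_coef, node_index(net, effector_id(net)),
                         params$equilibrium_tol,
                         params$max_equilibrium_steps)
  list(state = network_state(setNames(eq$state, net$ids)),
       effector_pre = eq$effector, steps = eq$steps,
       converged = eq$converged)
}
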