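`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the length-1 surprise
resample <- function(x, k) x[sample.int(length(x), k)]

# fraction of the pool with strictly lower value; ties share a percentile,
# so a host at the 75th percentile has 75% of the pool strictly below it
strict_percentile <- function(x) (rank(x, ties.method = "min") - 1) / length(x)

extinct_signal <- function(what) {
  stop(errorCondition(paste0(what, " population extinct"),
                      class = "pleiosim_extinct"))
}

#' Install a pleiotropic constraint on a fresh network
#'
#' One of the initial signaling proteins (chosen uniformly) becomes the
#' pleiotropic protein, standing in for a gene that also serves another
#' trait such as development:
#' * `"fixed-random"` -- every edge incident to it at initialization is
#'   locked (immutable) for the rest of evolutionary time;
#' * `"fixed-up"` / `"fixed-down"` -- it gains a locked connection of +1 /
#'   -1 onto the effector, a side effect of its other role;
#' * `"slow"` -- nothing is locked, but mutations touching its edges run at
#'   a `slow_factor`-fold reduced rate;
#' * `"none"` -- the network is returned unchanged.
#'
#' @param net A freshly initialized [immune_network()].
#' @param mode Constraint mode.
#' @return The constrained [immune_network()].
#' @export
apply_pleiotropy <- function(net, mode = c("none", "fixed-random",
                                           "fixed-up", "fixed-down",
                                           "slow")) {
  mode <- match.arg(mode)
  if (mode == "none") return(net)
  sig <- signaling_ids(net)
  node <- resample(sig, 1)
  p <- node_index(net, node)
  e <- node_index(net, effector_id(net))
  if (mode == "fixed-random") {
    inc <- matrix(FALSE, length(net$ids), length(net$ids))
    inc[p, ] <- TRUE
    inc[, p] <- TRUE
    net$locked <- net$locked | (inc & net$W != 0)
  } else if (mode == "fixed-up") {
    net$W[p, e] <- 1
    net$locked[p, e] <- TRUE
  } else if (mode == "fixed-down") {
    net$W[p, e] <- -1
    net$locked[p, e] <- TRUE
  }
  net$pleio <- list(node = node, mode = mode)
  net$gid <- new_gid()
  validate_network(net)
}

# ---- host mutation ---------------------------------------------------------

#' Mutate a host network
#'
#' With probability `host_mutation_rate` the offspring carries exactly one
#' mutation, drawn by `host_mutation_weights`: add an edge (random ordered
#' pair, uniform weight, redrawn while the pair is occupied or is the
#' forbidden detector-to-effector pair), delete an edge, redraw one edge's
#' weight, delete a signaling protein (with its incident edges; never the
#' detector, effector, pleiotropic protein, or the last signaling protein),
#' or duplicate a signaling protein (the copy inherits all incoming and
#' outgoing edges, a self-edge becoming a self-edge on the copy; a
#' duplicated pleiotropic protein's copy is an ordinary unconstrained
#' signaling protein).  Locked edges are never deleted or re-weighted.
#' Under the `"slow"` constraint a drawn edge mutation touching the
#' pleiotropic protein is only carried out with probability
#' `1 / slow_factor`.  When the drawn mutation type has no legal move the
#' type is redrawn.
#'
#' @param net An [immune_network()].
#' @param params An [evolution_params()] object.
#' @return The offspring [immune_network()].
#' @export
mutate_host <- function(net, params = evolution_params()) {
  mutate_host_info(net, params)$net
}

mutate_host_info <- function(net, params) {
  if (params$host_mutation_rate <= 0 ||
      runif(1) >= params$host_mutation_rate)
    return(list(net = net, type = "none"))
  apply_host_mutation(net, params)
}

# a "slow" pleiotropic protein accepts edge mutations with prob 1/factor
slow_gate <- function(net, params, idx) {
  if (is.null(net$pleio) || net$pleio$mode != "slow") return(TRUE)
  p <- node_index(net, net$pleio$node)
  if (!p %in% idx) return(TRUE)
  runif(1) < 1 / params$slow_factor
}

apply_host_mutation <- function(net, params) {
  w <- params$host_mutation_weights
  types <- names(w)
  for (attempt in 1:100) {
    type <- sample(types, 1, prob = w)
    res <- switch(type,
                  add_edge = mut_add_edge(net, params),
                  del_edge = mut_del_edge(net, params),
                  alter_weight = mut_alter_weight(net, params),
                  del_protein = mut_del_protein(net, params),
                  dup_protein = mut_dup_protein(net, params))
    if (!is.null(res)) return(res)
  }
  list(net = net, type = "none")
}

mut_add_edge <- function(net, params) {
  n <- length(net$ids)
  d <- which(net$roles == "detector")
  e <- which(net$roles == "effector")
  for (try in 1:200) {
    i <- sample.int(n, 1)
    j <- sample.int(n, 1)
    if ((i == d && j == e) || net$W[i, j] != 0) next
    if (!slow_gate(net, params, c(i, j)))
      return(list(net = net, type = "slow_suppressed"))
    net$W[i, j] <- runif(1, -1, 1)
    net$gid <- new_gid()
    return(list(net = net, type = "add_edge"))
  }
  NULL
}

mut_del_edge <- function(net, params) {
  cand <- which(net$W != 0 & !net$locked, arr.ind = TRUE)
  if (nrow(cand) == 0) return(NULL)
  k <- sample.int(nrow(cand), 1)
  if (!slow_gate(net, params, cand[k, ]))
    return(list(net = net, type = "slow_suppressed"))
  net$W[cand[k, 1], cand[k, 2]] <- 0
  net$gid <- new_gid()
  list(net = net, type = "del_edge")
}

mut_alter_weight <- function(net, params) {
  cand <- which(net$W != 0 & !net$locked, arr.ind = TRUE)
  if (nrow(cand) == 0) return(NULL)
  k <- sample.int(nrow(cand), 1)
  if (!slow_gate(net, params, cand[k, ]))
    return(list(net = net, type = "slow_suppressed"))
  net$W[cand[k, 1], cand[k, 2]] <- runif(1, -1, 1)
  net$gid <- new_gid()
  list(net = net, type = "alter_weight")
}

mut_del_protein <- function(net, params) {
  sig <- signaling_ids(net)
  if (length(sig) <= 1) return(NULL)  # parasites need a target
  if (!is.null(net$pleio)) sig <- setdiff(sig, net$pleio$node)
  # a node carrying a locked edge cannot go: locked edges are immortal
  if (any(net$locked)) {
    has_lock <- rowSums(net$locked) + colSums(net$locked) > 0
    sig <- setdiff(sig, net$ids[has_lock])
  }
  if (length(sig) == 0) return(NULL)
  victim <- resample(sig, 1)
  k <- node_index(net, victim)
  net$ids <- net$ids[-k]
  net$roles <- net$roles[-k]
  net$W <- net$W[-k, -k, drop = FALSE]
  net$locked <- net$locked[-k, -k, drop = FALSE]
  net$gid <- new_gid()
  list(net = net, type = "del_protein")
}

mut_dup_protein <- function(net, params) {
  sig <- signaling_ids(net)
  if (length(sig) == 0) return(NULL)
  orig <- resample(sig, 1)
  o <- node_index(net, orig)
  n <- length(net$ids)
  W2 <- matrix(0, n + 1, n + 1)
  W2[seq_len(n), seq_len(n)] <- net$W
  W2[seq_len(n), n + 1] <- net$W[, o]          # incoming copies
  W2[n + 1, seq_len(n)] <- net$W[o, ]          # outgoing copies
  W2[o, n + 1] <- 0                            # a self-edge stays a
  W2[n + 1, o] <- 0                            # self-edge on the copy
  W2[n + 1, n + 1] <- net$W[o, o]
  L2 <- matrix(FALSE, n + 1, n + 1)
  L2[seq_len(n), seq_len(n)] <- net$locked     # the paralog is unconstrained
  net$ids <- c(net$ids, max(net$ids) + 1L)
  net$roles <- c(net$roles, "signaling")
  net$W <- W2
  net$locked <- L2
  net$gid <- new_gid()
  list(net = net, type = "dup_protein")
}

# ---- parasite mutation -----------------------------------------------------

#' Mutate a parasite
#'
#' With probability `parasite_mutation_rate` the offspring either retargets
#' to a uniformly drawn signaling protein or redraws its manipulation
#' weight uniformly on `[-1, 1]` (each with the configured relative
#' probability, default 1/2 each).
#'
#' @param p A [parasite()].
#' @param net_signaling_ids Signaling-protein ids available as targets
#'   (typically those of the parent's most recent host; a target that does
#'   not exist in the next host is redrawn at pairing time).
#' @param params An [evolution_params()] object.
#' @return The offspring [parasite()].
#' @export
mutate_parasite <- function(p, net_signaling_ids,
                            params = evolution_params()) {
  off <- parasite(p$target, p$manipulation)
  off$host_signaling_ids <- p$host_signaling_ids
  if (params$parasite_mutation_rate <= 0 ||
      runif(1) >= params$parasite_mutation_rate)
    return(off)
  w <- params$parasite_mutation_weights
  type <- sample(names(w), 1, prob = w)
  if (type == "retarget") {
    if (length(net_signaling_ids) > 0)
      off$target <- resample(as.integer(net_signaling_ids), 1)
  } else {
    off$manipulation <- runif(1, -1, 1)
  }
  off
}

# ---- death and reproduction ------------------------------------------------

#' Fitness-weighted culling
#'
#' Individuals that succumbed to infection die first; if they alone exceed
#' the death cap (`death_cap` of the population, rounded down), the excess
#' are restored at random.  Otherwise the remaining pool is visited in
#' random order and each member dies with probability one minus its
#' strict fitness percentile (a 75th-percentile host dies with probability
#' 0.25), until everyone has been evaluated once or the cap is reached.
#'
#' @param fitness Numeric fitness (hosts) or cumulative load (parasites).
#' @param died Logical: succumbed to / cleared from infection, prioritized
#'   in the death process.
#' @param params An [evolution_params()] object.
#' @return A list with integer `survivors` and `deaths` indices.
#' @export
cull_population <- function(fitness, died, params = evolution_params()) {
  n <- length(fitness)
  cap <- floor(params$death_cap * n)
  deaths <- which(died)
  if (length(deaths) > cap)
    deaths <- resample(deaths, cap)              # excess restored at random
  alive <- setdiff(seq_len(n), deaths)
  if (length(deaths) < cap && length(alive) > 0) {
    pct <- strict_percentile(fitness[alive])
    for (k in sample.int(length(alive))) {
      if (length(deaths) >= cap) break
      if (runif(1) < 1 - pct[k]) deaths <- c(deaths, alive[k])
    }
  }
  list(survivors = setdiff(seq_len(n), deaths), deaths = sort(deaths))
}

#' Fitness-weighted host reproduction
#'
#' Survivors are drawn uniformly and accepted to reproduce with
#' probability equal to their strict fitness percentile (the mirror image
#' of the death rule); each acceptance appends one [mutate_host()]
#' offspring, until the population is back to `target_size`.  Offspring
#' inherit their parent's pleiotropy record and lineage id.  If every
#' survivor sits at percentile zero (all fitness equal, including a lone
#' survivor) every draw is accepted, so replenishment always terminates.
#'
#' @param survivors List of surviving [immune_network()]s.
#' @param fitness Their fitness values.
#' @param target_size Population size to restore.
#' @param params An [evolution_params()] object.
#' @return A list with `nets` (offspring networks), `parent_idx` (index
#'   into `survivors`), and `mutation_type` per offspring.
#' @export
reproduce_hosts <- function(survivors, fitness, target_size,
                            params = evolution_params()) {
  n <- length(survivors)
  if (n == 0) extinct_signal("host")
  pct <- strict_percentile(fitness)
  if (all(pct == 0)) pct[] <- 1
  nets <- vector("list", target_size)
  parent <- integer(target_size)
  mtype <- character(target_size)
  filled <- 0L
  while (filled < target_size) {
    m <- max(16L, 2L * (target_size - filled))
    idx <- sample.int(n, m, replace = TRUE)
    keep <- runif(m) < pct[idx]
    for (i in idx[keep]) {
      if (filled >= target_size) break
      filled <- filled + 1L
      info <- mutate_host_info(survivors[[i]], params)
      nets[[filled]] <- info$net
      parent[filled] <- i
      mtype[filled] <- info$type
    }
  }
  list(nets = nets, parent_idx = parent, mutation_type = mtype)
}

#' Load-based parasite reproduction
#'
#' Each surviving parasite earns an offspring quota from the normalized
#' area of its last infection: loads in `[0, .33]` give 1 offspring,
#' `(.33, .66]` give 2, and `(.66, 1]` give 3.  Parents are visited from
#' highest load downward, each contributing its quota of
#' [mutate_parasite()] offspring, cycling until the population is
#' replenished to `target_size`.
#'
#' @param parasites List of surviving [parasite()]s with
#'   `cumulative_load` set.
#' @param target_size Population size to restore.
#' @param params An [evolution_params()] object.
#' @return A list of offspring [parasite()]s.
#' @export
reproduce_parasites <- function(parasites, target_size,
                                params = evolution_params()) {
  if (target_size == 0) return(list())
  if (length(parasites) == 0) extinct_signal("parasite")
  loads <- vapply(parasites, function(p) p$cumulative_load, numeric(1))
  quota <- 1L + (loads > 0.33) + (loads > 0.66)
  ord <- order(-loads)
  out <- vector("list", target_size)
  filled <- 0L
  while (filled < target_size) {
    for (i in ord) {
      for (j in seq_len(quota[i])) {
        if (filled >= target_size) break
        filled <- filled + 1L
        out[[filled]] <- mutate_parasite(
          parasites[[i]], parasites[[i]]$host_signaling_ids %||% integer(0),
          params)
      }
      if (filled >= target_size) break
    }
  }
  out
}
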