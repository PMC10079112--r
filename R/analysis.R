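# ---- inducibility ----------------------------------------------------------

#' Inducibility of an immune response
#'
#' The fraction of a host's maximal effector response that was activated
#' by the infection: `(effector_peak - effector_pre) / effector_peak`,
#' clamped to `[0, 1]`.  0 means a fully constitutive response, 1 a fully
#' induced one.  A host that never mounts any response
#' (`effector_peak = 0`) scores 0: nothing was induced.
#'
#' @param rec An `infection_record`, or anything with `effector_pre` and
#'   `effector_peak` fields.
#' @return A scalar in `[0, 1]`.
#' @export
inducibility <- function(rec) {
  if (rec$effector_peak <= 0) return(0)
  min(max((rec$effector_peak - rec$effector_pre) / rec$effector_peak, 0), 1)
}

# ---- kernel density estimates ---------------------------------------------

gauss_kernel_sum <- function(grid, x, bw) {
  # boundary-reflected Gaussian KDE on [0, 1]: mass that would spill
  # past either edge is folded back in, so the estimate integrates to 1
  # on the unit interval
  f <- numeric(length(grid))
  for (xx in c(list(x), list(-x), list(2 - x))) {
    z <- outer(grid, xx, function(g, v) stats::dnorm(g - v, sd = bw))
    f <- f + rowSums(z)
  }
  f / length(x)
}

silverman_bw <- function(x, fallback = 0.05) {
  if (length(x) < 2 || stats::sd(x) == 0) return(fallback)
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) fallback else bw
}

#' Immune response probability density
#'
#' Gaussian kernel density estimate of a set of inducibility values on a
#' fixed grid over `[0, 1]`, reflected at both boundaries and
#' peak-normalized to 1 to ease comparison between populations.
#' Conventionally computed from all infected hosts of a run's final
#' generation.
#'
#' @param values Inducibility values in `[0, 1]`.
#' @param bandwidth Kernel bandwidth; Silverman's rule by default (with a
#'   small fallback when the sample is degenerate).
#' @param n_grid Number of grid points (default 201).
#' @return An object of class `response_density` with fields `x` (grid),
#'   `y` (peak-normalized density), `y_raw` (density integrating to 1),
#'   `bandwidth`, `n`.
#' @export
response_density <- function(values, bandwidth = NULL, n_grid = 201L) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("cannot estimate a density from no data")
  stopifnot(all(values >= 0 & values <= 1))
  bw <- bandwidth %||% silverman_bw(values)
  grid <- seq(0, 1, length.out = n_grid)
  y_raw <- gauss_kernel_sum(grid, values, bw)
  structure(list(x = grid, y = y_raw / max(y_raw), y_raw = y_raw,
                 bandwidth = bw, n = length(values)),
            class = "response_density")
}

#' @export
print.response_density <- function(x, ...) {
  cat(sprintf("<response_density> n = %d, bandwidth = %.4f, peak at %.3f\n",
              x$n, x$bandwidth, x$x[which.max(x$y)]))
  invisible(x)
}

#' Location of a density's highest peak
#' @param d A [response_density()].
#' @return The grid point with maximal density.
#' @export
density_peak <- function(d) d$x[which.max(d$y)]

#' Pearson correlation between two response densities
#'
#' Computed across the shared evaluation grid.  Correlations with absolute
#' value at or below 0.2 flag a substantive difference between the two
#' populations' immune dynamics.  If either density is constant across the
#' grid the correlation is undefined and `NaN` is returned with a warning.
#'
#' @param a,b [response_density()] objects on the same grid.
#' @return Pearson r, or `NaN` for a degenerate density.
#' @export
density_correlation <- function(a, b) {
  if (length(a$x) != length(b$x) || any(a$x != b$x))
    stop("densities must share an evaluation grid")
  if (stats::sd(a$y) == 0 || stats::sd(b$y) == 0) {
    warning("zero-variance density; correlation undefined")
    return(NaN)
  }
  cor(a$y, b$y)
}

#' Joint density of response magnitude and inducibility
#'
#' Two-dimensional boundary-reflected Gaussian KDE over `[0, 1]^2` of
#' (inducibility, peak effector abundance) pairs.  With a `run` column the
#' density is estimated per run (each integrating to 1) and the estimates
#' are added, so the raw surface integrates to the number of runs pooled;
#' `z` is the peak-normalized sum.
#'
#' @param profiles A data frame with columns `inducibility` and
#'   `effector_peak`, optionally `run`.
#' @param bandwidth Length-2 bandwidth (x, y); Silverman's rule per axis
#'   by default, pooled across runs.
#' @param n_grid Grid points per axis (default 51).
#' @return An object of class `response_density_2d` with `x`, `y` grids,
#'   peak-normalized matrix `z` and raw matrix `z_raw` (rows index `x`).
#' @export
magnitude_inducibility_density <- function(profiles, bandwidth = NULL,
                                           n_grid = 51L) {
  stopifnot(nrow(profiles) > 0,
            all(c("inducibility", "effector_peak") %in% names(profiles)))
  runs <- if ("run" %in% names(profiles)) profiles$run
          else rep(1L, nrow(profiles))
  bw <- bandwidth %||% c(silverman_bw(profiles$inducibility),
                         silverman_bw(profiles$effector_peak))
  gx <- seq(0, 1, length.out = n_grid)
  gy <- seq(0, 1, length.out = n_grid)
  z <- matrix(0, n_grid, n_grid)
  for (r in unique(runs)) {
    sel <- runs == r
    fx <- vapply(profiles$inducibility[sel], function(v)
      stats::dnorm(gx - v, sd = bw[1]) + stats::dnorm(gx + v, sd = bw[1]) +
        stats::dnorm(gx - (2 - v), sd = bw[1]), numeric(n_grid))
    fy <- vapply(profiles$effector_peak[sel], function(v)
      stats::dnorm(gy - v, sd = bw[2]) + stats::dnorm(gy + v, sd = bw[2]) +
        stats::dnorm(gy - (2 - v), sd = bw[2]), numeric(n_grid))
    z <- z + (fx %*% t(fy)) / sum(sel)     # product kernel, mean over hosts
  }
  structure(list(x = gx, y = gy, z = z / max(z), z_raw = z,
                 bandwidth = bw, n_runs = length(unique(runs))),
            class = "response_density_2d")
}

# ---- knockout robustness ---------------------------------------------------

remove_protein <- function(net, id) {
  k <- node_index(net, id)
  net$ids <- net$ids[-k]
  net$roles <- net$roles[-k]
  net$W <- net$W[-k, -k, drop = FALSE]
  net$locked <- net$locked[-k, -k, drop = FALSE]
  if (!is.null(net$pleio) && net$pleio$node == id) net$pleio <- NULL
  net$gid <- new_gid()
  net
}

infection_effector_trace <- function(net, params, fitness) {
  eq <- healthy_equilibrium(net, params)
  aug <- attach_parasite(net, parasite(NA, 0))
  res <- .cpp_infection(aug$W,
                        c(unname(eq$state$active),
                          params$parasite_initial_active),
                        params$use_coef, aug$eff_idx, aug$par_idx,
                        fitness$clearance_threshold,
                        fitness$death_area_threshold,
                        fitness$max_infection_steps, FALSE)
  res$eff_trace
}

#' Effector divergence after a signaling-protein knockout
#'
#' The intact network and the network with `protein` (and its incident
#' edges) removed are each infected, from their own healthy equilibria, by
#' a parasite that cannot manipulate host signaling, for the full
#' infection window with no early termination.  Returned is the mean over
#' time steps of the absolute difference in active effector levels -- a
#' measure of how much the evolved response relies on that protein.
#'
#' @param net An [immune_network()].
#' @param protein Id of a signaling protein of `net`.
#' @param params A [dynamics_params()] object.
#' @param fitness A [fitness_params()] object (window length).
#' @return Mean absolute effector difference over the window.
#' @export
knockout_divergence <- function(net, protein, params = dynamics_params(),
                                fitness = fitness_params()) {
  if (!protein %in% signaling_ids(net))
    stop("knockout target must be a signaling protein")
  intact <- infection_effector_trace(net, params, fitness)
  ko <- infection_effector_trace(remove_protein(net, protein), params,
                                 fitness)
  mean(abs(intact - ko))
}

#' Contrast pleiotropic vs other knockout divergences
#'
#' Equal-variance two-sample two-tailed t-test between the divergences
#' observed when knocking out the pleiotropic protein and those from other
#' (or randomly chosen) signaling proteins, with a Bonferroni-corrected
#' p-value over `n_comparisons` tests.  Degenerate samples (both sides
#' constant) are flagged: equal means give `t = 0, p = 1`, differing means
#' `p = 0`.
#'
#' @param pleiotropic_divs,other_divs Numeric vectors (length >= 2).
#' @param n_comparisons Number of tests in the Bonferroni family.
#' @return A one-row tibble: `t`, `p_raw`, `p_bonferroni`, `significant`
#'   (at 0.05 after correction), `flagged`.
#' @export
knockout_contrast <- function(pleiotropic_divs, other_divs,
                              n_comparisons = 1L) {
  stopifnot(length(pleiotropic_divs) >= 2, length(other_divs) >= 2)
  degenerate <- stats::sd(pleiotropic_divs) == 0 &&
    stats::sd(other_divs) == 0
  if (degenerate) {
    same <- mean(pleiotropic_divs) == mean(other_divs)
    t_stat <- if (same) 0 else Inf
    p_raw <- if (same) 1 else 0
  } else {
    tt <- t.test(pleiotropic_divs, other_divs, var.equal = TRUE)
    t_stat <- unname(tt$statistic)
    p_raw <- tt$p.value
  }
  p_bonf <- min(1, p_raw * n_comparisons)
  tibble::tibble(t = t_stat, p_raw = p_raw, p_bonferroni = p_bonf,
                 significant = p_bonf < 0.05, flagged = degenerate)
}

# ---- structural metrics ----------------------------------------------------

#' Vertex-disjoint detector-to-effector paths
#'
#' The maximum number of directed detector-to-effector paths sharing no
#' signaling protein with one another, ignoring edge signs and weights --
#' a redundancy measure of the signaling architecture.  Computed as a unit
#' vertex-capacity maximum flow on the node-split graph.
#'
#' @param net An [immune_network()].
#' @return A nonnegative integer.
#' @examples
#' W <- matrix(0, 4, 4)
#' W[1, 2] <- 1; W[2, 4] <- 1; W[1, 3] <- 1; W[3, 4] <- 1
#' net <- immune_network(1:4, c("detector", "signaling", "signaling",
#'                              "effector"), W)
#' distinct_paths(net)  # 2 parallel relays
#' @export
distinct_paths <- function(net) {
  n <- length(net$ids)
  sig <- which(net$roles == "signaling")
  d <- which(net$roles == "detector")
  e <- which(net$roles == "effector")
  if (length(sig) == 0) return(0L)
  # node-split: signaling k -> vertices k_in, k_out joined by a capacity-1
  # arc; detector/effector stay single with effectively infinite capacity
  v_in <- integer(n); v_out <- integer(n)
  nv <- 0L
  for (k in seq_len(n)) {
    if (k %in% sig) {
      v_in[k] <- nv + 1L; v_out[k] <- nv + 2L; nv <- nv + 2L
    } else {
      v_in[k] <- v_out[k] <- nv + 1L; nv <- nv + 1L
    }
  }
  big <- length(sig) + 1
  from <- integer(0); to <- integer(0); cap <- numeric(0)
  for (k in sig) {
    from <- c(from, v_in[k]); to <- c(to, v_out[k]); cap <- c(cap, 1)
  }
  ed <- which(net$W != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(ed))) {
    s <- ed[r, 1]; t <- ed[r, 2]
    if (s == t) next
    from <- c(from, v_out[s]); to <- c(to, v_in[t]); cap <- c(cap, big)
  }
  g <- igraph::make_empty_graph(n = nv, directed = TRUE)
  if (length(from) > 0) g <- igraph::add_edges(g, rbind(from, to))
  fl <- igraph::max_flow(g, source = v_out[d], target = v_in[e],
                         capacity = cap)
  as.integer(round(fl$value))
}

#' Most common network in a population
#'
#' Networks are compared by exact canonical form: node ids (stable,
#' lineage-inherited labels) with their roles, plus the ordered edge list
#' with weights at full float precision.  Ties are broken by the lowest
#' host id carrying the network.
#'
#' @param population List of [immune_network()]s.
#' @param host_ids Optional host ids parallel to `population` (defaults to
#'   list position).
#' @return A list with `network`, `count`, and the carrying `host_ids`.
#' @export
most_common_network <- function(population, host_ids = NULL) {
  stopifnot(length(population) > 0)
  host_ids <- host_ids %||% seq_along(population)
  keys <- vapply(population, network_key, character(1))
  counts <- table(keys)
  top <- names(counts)[counts == max(counts)]
  # tie-break: the modal network whose lowest carrier id is smallest
  lowest <- vapply(top, function(k) min(host_ids[keys == k]), numeric(1))
  key <- top[which.min(lowest)]
  idx <- which(keys == key)
  list(network = population[[idx[which.min(host_ids[idx])]]],
       count = as.integer(max(counts)),
       host_ids = host_ids[idx])
}

#' Did any lineage split into constitutive and inducible hosts?
#'
#' `TRUE` when at least one generation-0 lineage is represented in the
#' final generation by both a host at or above the inducibility threshold
#' and one below it -- evidence that descendants of a single ancestor
#' settled on different immune strategies.
#'
#' @param records A data frame with `lineage_id` and `inducibility`
#'   columns (e.g. the `records_final` table of a run; uninfected hosts
#'   with `NA` inducibility are ignored).
#' @param inducibility_threshold Split threshold (default 0.5).
#' @return Logical.
#' @export
lineage_split <- function(records, inducibility_threshold = 0.5) {
  recs <- records[!is.na(records$inducibility), , drop = FALSE]
  if (nrow(recs) == 0) return(FALSE)
  split_by <- tapply(recs$inducibility, recs$lineage_id, function(v)
    any(v >= inducibility_threshold) && any(v < inducibility_threshold))
  any(unlist(split_by))
}

# ---- run-level convenience -------------------------------------------------

#' Response profiles of a run's final generation
#'
#' One row per infected host of the final evaluated generation:
#' inducibility and peak effector abundance, ready for
#' [response_density()] and [magnitude_inducibility_density()].
#'
#' @param run A `coevolution_run` or `competition_run`.
#' @return A tibble with `host_id`, `lineage_id`, `pleiotropic`,
#'   `inducibility`, `effector_peak`.
#' @export
response_profiles <- function(run) {
  run$records_final |>
    dplyr::filter(!is.na(.data$inducibility)) |>
    dplyr::select("host_id", "lineage_id", "pleiotropic", "inducibility",
                  "effector_peak")
}

#' Knockout divergence table for a run's modal network
#'
#' Extracts the most common final-generation network and computes
#' [knockout_divergence()] for every signaling protein, labelling the
#' pleiotropic one.  For non-pleiotropic networks the contrast convention
#' is to draw nodes at random instead; this table supplies the raw
#' divergences either way.
#'
#' @param run A `coevolution_run`.
#' @return A tibble with `protein`, `pleiotropic`, `divergence`.
#' @export
knockout_table <- function(run) {
  net <- most_common_network(run$hosts_final, run$host_ids)$network
  sig <- signaling_ids(net)
  pnode <- if (is.null(net$pleio)) NA_integer_ else net$pleio$node
  tibble::tibble(
    protein = sig,
    pleiotropic = !is.na(pnode) & sig == pnode,
    divergence = vapply(sig, function(s)
      knockout_divergence(net, s, run$config$dynamics, run$config$fitness),
      numeric(1)))
}
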