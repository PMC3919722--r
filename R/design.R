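#' Loss matrices
#'
#' Points lost as a function of final location (AtHome, InTransit, InShelter)
#' and disaster outcome (Hit, Miss). Every admissible matrix has zero loss
#' for (AtHome, Miss), strictly increasing Miss losses for InTransit then
#' InShelter, and on a Hit the ordering reverses: InShelter loses least,
#' AtHome most.
#'
#' @param miss losses for (AtHome, InTransit, InShelter) on a Miss.
#' @param hit losses for (AtHome, InTransit, InShelter) on a Hit.
#' @return A 3x2 matrix of class `loss_matrix` with dimnames
#'   `(AtHome, InTransit, InShelter) x (Hit, Miss)`.
#' @export
loss_matrix <- function(miss = c(0, 20, 30), hit = c(100, 60, 30)) {
  m <- cbind(Hit = hit, Miss = miss)
  rownames(m) <- c("AtHome", "InTransit", "InShelter")
  if (m["AtHome", "Miss"] != 0) stop("(AtHome, Miss) loss must be 0")
  if (!(m["AtHome", "Miss"] < m["InTransit", "Miss"] &&
        m["InTransit", "Miss"] < m["InShelter", "Miss"]))
    stop("Miss losses must increase: AtHome < InTransit < InShelter")
  if (!(m["InShelter", "Hit"] < m["InTransit", "Hit"] &&
        m["InTransit", "Hit"] < m["AtHome", "Hit"]))
    stop("Hit losses must increase: InShelter < InTransit < AtHome")
  if (any(m < 0)) stop("losses must be >= 0")
  structure(m, class = c("loss_matrix", "matrix"))
}

#' @rdname loss_matrix
#' @details `default_loss_matrices()` returns three matrices scaling a base
#'   incentive structure by 1, 1.5, and 0.5 to emulate varying disaster
#'   severity. These are package fixtures; the laboratory values were never
#'   published.
#' @export
default_loss_matrices <- function() {
  lapply(c(1, 1.5, 0.5), function(s)
    loss_matrix(miss = s * c(0, 20, 30), hit = s * c(100, 60, 30)))
}

#' Assemble a nested experimental design
#'
#' Crosses the design factors -- shelter capacity, threat trajectory (which
#' carries the time-pressure regime), loss matrix, and network -- by cycling
#' each at a different period and truncating to `n_runs`, so every capacity
#' level appears, both regimes appear, and trajectories repeat across runs
#' with different settings, as in the laboratory design.
#'
#' @param n_runs number of runs (the experiment used 47).
#' @param trajectories list of [simulate_threat()] trajectories (the pool).
#' @param capacities shelter capacities in beds.
#' @param loss_matrices list of [loss_matrix()] objects.
#' @param networks list of [network_spec()] objects.
#' @param n_agents participants per run.
#' @param seed integer seed for the per-run node assignments.
#' @return A list of `run_config` objects, each with fields `run_id`,
#'   `trajectory`, `capacity`, `loss`, `network`, `node_assignment`.
#' @export
make_design <- function(n_runs = 47L,
                        trajectories = trajectory_pool(),
                        capacities = c(50L, 40L, 30L, 20L, 10L),
                        loss_matrices = default_loss_matrices(),
                        networks = default_network_specs(),
                        n_agents = 50L, seed = 1L) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("`n_runs` must be >= 1")
  if (!length(trajectories) || !length(capacities) ||
      !length(loss_matrices) || !length(networks))
    stop("every design factor needs at least one level")
  if (any(capacities > n_agents)) stop("capacity cannot exceed the group size")
  set.seed(seed)
  lapply(seq_len(n_runs), function(i) {
    cyc <- function(pool, period) pool[[((i - 1L) %/% period) %% length(pool) + 1L]]
    structure(list(
      run_id = i,
      trajectory = cyc(trajectories, length(capacities)),
      capacity = capacities[(i - 1L) %% length(capacities) + 1L],
      loss = cyc(loss_matrices, length(capacities)),
      network = cyc(networks, 1L),
      n_agents = n_agents,
      node_assignment = sample.int(n_agents)
    ), class = "run_config")
  })
}

#' Construct a single run configuration
#'
#' Pairs a trajectory with a shelter capacity, loss matrix, network, and
#' node assignment; [make_design()] builds whole designs by cycling factor
#' levels, this constructor builds one run by hand.
#'
#' @param trajectory a `threat_trajectory`.
#' @param capacity shelter beds (<= `n_agents`).
#' @param loss a [loss_matrix()].
#' @param network a [network_spec()] or `NULL`.
#' @param n_agents participants in the run.
#' @param run_id identifier.
#' @param node_assignment permutation of participants onto network nodes.
#' @return A `run_config`.
#' @export
run_config <- function(trajectory, capacity = 50L, loss = loss_matrix(),
                       network = NULL, n_agents = 50L, run_id = 1L,
                       node_assignment = seq_len(n_agents)) {
  stopifnot(inherits(trajectory, "threat_trajectory"))
  if (capacity > n_agents) stop("capacity cannot exceed the group size")
  if (length(node_assignment) != n_agents ||
      !setequal(node_assignment, seq_len(n_agents)))
    stop("`node_assignment` must be a permutation of the participants")
  structure(list(run_id = run_id, trajectory = trajectory,
                 capacity = as.integer(capacity), loss = loss,
                 network = network, n_agents = as.integer(n_agents),
                 node_assignment = node_assignment),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run %d: %s trajectory (id %s), %d beds, %d agents\n",
              x$run_id, x$trajectory$regime,
              if (is.null(x$trajectory$id)) "-" else x$trajectory$id,
              x$capacity, x$n_agents))
  invisible(x)
}
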