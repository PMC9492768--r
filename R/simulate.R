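#' Synchronous Boolean simulation and attractors
#'
#' The network state is a 0/1 vector over the nodes in alphabetical order
#' (frozen when the network is built). Under synchronous update every node is
#' recomputed simultaneously from the previous state; trajectories in the
#' finite state space must eventually revisit a state, and the revisited
#' segment is the attractor — a fixed point (length 1) or a limit cycle.
#'
#' An `attractor` holds the ordered cycle states, a rotation-invariant
#' `canonical_key` (the lexicographically minimal rotation of the cycle's
#' bit-strings, joined by "|"), and `mean_state`, the per-node average over
#' cycle states used when comparing perturbed attractors.
#'
#' @name boolean-simulation
#' @keywords internal
NULL

.canonical_attractor <- function(states_matrix, nodes) {
  m <- states_matrix
  colnames(m) <- nodes
  L <- nrow(m)
  keys <- apply(m, 1, paste, collapse = "")
  rotations <- vapply(seq_len(L), function(i) {
    paste(keys[c(i:L, seq_len(i - 1))[seq_len(L)]], collapse = "|")
  }, character(1))
  rot <- which(rotations == min(rotations))[1]
  ord <- c(rot:L, seq_len(rot - 1))[seq_len(L)]
  m <- m[ord, , drop = FALSE]
  structure(
    list(states = m,
         canonical_key = paste(keys[ord], collapse = "|"),
         mean_state = colMeans(m)),
    class = "attractor"
  )
}

#' @export
print.attractor <- function(x, ...) {
  cat("<attractor> cycle length ", nrow(x$states), ": ", x$canonical_key,
      "\n", sep = "")
  invisible(x)
}

#' One synchronous update step
#'
#' @param state Named 0/1 vector over the network nodes (alphabetical order).
#' @param rules Named list of `boolean_rule`, one per node.
#' @param clamps Optional named vector of 0/1 values; clamped nodes are
#'   forced after the update.
#' @return The next state (named 0/1 integer vector).
#' @export
step_state <- function(state, rules, clamps = NULL) {
  nodes <- sort(names(rules))
  s <- as.integer(state[nodes])
  compiled <- .compile_rules(rules, nodes)
  nxt <- vapply(seq_along(nodes), function(i) {
    r <- compiled$regs[[i]] + 1L
    idx <- 1L + sum(s[r] * 2L^(seq_along(r) - 1L))
    compiled$tts[[i]][idx]
  }, integer(1))
  names(nxt) <- nodes
  if (!is.null(clamps)) nxt[names(clamps)] <- as.integer(clamps)
  nxt
}

.clamp_vector <- function(nodes, clamps) {
  cl <- rep(-1L, length(nodes))
  if (!is.null(clamps)) {
    stopifnot(all(names(clamps) %in% nodes))
    cl[match(names(clamps), nodes)] <- as.integer(clamps)
  }
  cl
}

#' Find the attractor reachable from a start state
#'
#' Iterates the synchronous update with visited-state hashing; the first
#' revisited state closes the cycle. With deterministic update a revisit is
#' guaranteed; `max_steps` (default 100) is kept as a budget guard, and if it
#' is exhausted the final state is returned as a flagged singleton.
#'
#' @inheritParams step_state
#' @param max_steps Simulation budget (default 100).
#' @return An `attractor` (with attribute `converged`).
#' @export
find_attractor <- function(state, rules, clamps = NULL, max_steps = 100) {
  nodes <- sort(names(rules))
  compiled <- .compile_rules(rules, nodes)
  res <- cpp_attractor(as.integer(state[nodes]), compiled$regs, compiled$tts,
                       .clamp_vector(nodes, clamps), max_steps)
  att <- .canonical_attractor(res$states, nodes)
  attr(att, "converged") <- res$converged
  att
}

#' Exhaustively enumerate all attractors of a rule set (test oracle)
#'
#' Sweeps all 2^n start states; only feasible for networks of at most 20
#' nodes.
#'
#' @param rules Named list of `boolean_rule`.
#' @param max_steps Simulation budget per trajectory.
#' @return A tibble with columns `attractor` (list of `attractor`),
#'   `canonical_key`, `cycle_length`, `basin_size`.
#' @export
enumerate_all_attractors <- function(rules, max_steps = 2^length(rules) + 1) {
  nodes <- sort(names(rules))
  if (length(nodes) > 20) {
    stop("refusing exhaustive enumeration beyond 20 nodes", call. = FALSE)
  }
  compiled <- .compile_rules(rules, nodes)
  res <- cpp_enumerate_attractors(compiled$regs, compiled$tts, max_steps)
  atts <- lapply(res$states, .canonical_attractor, nodes = nodes)
  tibble::tibble(
    attractor = atts,
    canonical_key = vapply(atts, `[[`, character(1), "canonical_key"),
    cycle_length = vapply(atts, function(a) nrow(a$states), integer(1)),
    basin_size = res$basin
  ) |> dplyr::arrange(.data$canonical_key)
}

#' Knock-in / knock-out attractors for one node
#'
#' Runs two clamped simulations from the cell's state: the node pinned to 1
#' (knock-in) and to 0 (knock-out). The clamp applies to the start state too.
#'
#' @param state Named 0/1 start state (a cell's binary profile over the
#'   network genes).
#' @param rules Named list of `boolean_rule`.
#' @param node Node to perturb.
#' @param max_steps Simulation budget.
#' @return List with elements `ki` and `ko`, both `attractor`s.
#' @export
perturbation_attractors <- function(state, rules, node, max_steps = 100) {
  list(
    ki = find_attractor(state, rules, clamps = setNames(1L, node),
                        max_steps = max_steps),
    ko = find_attractor(state, rules, clamps = setNames(0L, node),
                        max_steps = max_steps)
  )
}

#' Write attractors as JSON or a mean-activity TSV
#'
#' @param attractors List of `attractor` objects (or the tibble from
#'   [enumerate_all_attractors()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attractors_json <- function(attractors, path) {
  if (is.data.frame(attractors)) attractors <- attractors$attractor
  payload <- lapply(attractors, function(a) {
    list(
      canonical_key = a$canonical_key,
      cycle = apply(a$states, 1, paste, collapse = ""),
      mean_state = as.list(a$mean_state)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_attractors_json
#' @export
write_attractor_profiles_tsv <- function(attractors, path) {
  if (is.data.frame(attractors)) attractors <- attractors$attractor
  prof <- purrr::map_dfr(attractors, function(a) {
    tibble::tibble(attractor = a$canonical_key,
                   gene = names(a$mean_state),
                   mean_activity = unname(a$mean_state))
  })
  readr::write_tsv(tidyr::pivot_wider(prof, names_from = "attractor",
                                      values_from = "mean_activity"), path)
  invisible(path)
}
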