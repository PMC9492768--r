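#' Sample rule sets from the equivalent rule sets
#'
#' Draws `n` rule sets; each draw picks one ERS member uniformly and
#' independently per node. Duplicates are expected when the ERS is small.
#'
#' @param fit A `rule_fit`.
#' @param n Number of rule sets (default 10).
#' @param seed Integer seed.
#' @return List of `n` named rule lists.
#' @export
sample_rulesets <- function(fit, n = 10, seed = 1) {
  withr::local_seed(seed)
  nodes <- sort(names(fit$rulespaces))
  lapply(seq_len(n), function(i) {
    setNames(lapply(nodes, function(nd) {
      rs <- fit$rulespaces[[nd]]
      rs$candidates[[rs$ers[sample.int(length(rs$ers), 1)]]]
    }), nodes)
  })
}

#' Harvest reachable attractors from observed cell states
#'
#' Simulates every cell's binary state to its attractor under each sampled
#' rule set (and, by default, under the simplest-rules set too), then
#' deduplicates by the rotation-invariant canonical key. Starting from all
#' observed states covers the reachable portion of the state space.
#'
#' @param fit A `rule_fit`.
#' @param binary A `binary_matrix` covering the network nodes.
#' @param n_rulesets Number of ERS samples (default 10).
#' @param include_simplest Also simulate under the simplest-rule set.
#' @param seed Integer seed for the ERS sampling.
#' @param max_steps Simulation budget.
#' @return A tibble: `canonical_key`, `attractor` (list-column),
#'   `cycle_length`, `n_rulesets` (how many rule sets reached it),
#'   `provenance` (list of rule-set labels).
#' @export
harvest_attractors <- function(fit, binary, n_rulesets = 10,
                               include_simplest = TRUE, seed = 1,
                               max_steps = 100) {
  nodes <- sort(names(fit$rules))
  E <- binary$states[, nodes, drop = FALSE]
  storage.mode(E) <- "integer"
  rulesets <- sample_rulesets(fit, n = n_rulesets, seed = seed)
  if (length(rulesets)) names(rulesets) <- paste0("sample",
                                                  seq_along(rulesets))
  if (include_simplest) {
    rulesets <- c(list(simplest = fit$simplest_rules %||% fit$rules),
                  rulesets)
  }

  found <- list()
  for (lab in names(rulesets)) {
    compiled <- .compile_rules(rulesets[[lab]], nodes)
    atts <- cpp_attractors(E, compiled$regs, compiled$tts,
                           rep(-1L, length(nodes)), max_steps)
    for (m in unique(atts)) {
      a <- .canonical_attractor(m, nodes)
      k <- a$canonical_key
      if (is.null(found[[k]])) {
        found[[k]] <- list(attractor = a, provenance = lab)
      } else {
        found[[k]]$provenance <- union(found[[k]]$provenance, lab)
      }
    }
  }
  tibble::tibble(
    canonical_key = names(found),
    attractor = lapply(found, `[[`, "attractor"),
    cycle_length = vapply(found, function(f) nrow(f$attractor$states),
                          integer(1)),
    n_rulesets = vapply(found, function(f) length(f$provenance), integer(1)),
    provenance = lapply(found, `[[`, "provenance")
  ) |> dplyr::arrange(.data$canonical_key)
}

#' Assign cells to attractors by Hamming distance
#'
#' Each cell's distance to an attractor is the minimum, over the attractor's
#' cycle states, of the per-gene mismatch count (restricted to the network
#' genes); the cell is assigned to the closest attractor, ties going to the
#' smallest canonical key.
#'
#' @param binary A `binary_matrix` (with `subject`/`group` metadata if the
#'   association tests will be run).
#' @param attractors Tibble from [harvest_attractors()] (or a list of
#'   `attractor`s).
#' @return An `attractor_assignment` tibble: `cell_id`, `attractor`
#'   (canonical key), `distance`, plus `subject`/`group` when present.
#' @export
assign_cells <- function(binary, attractors) {
  if (is.data.frame(attractors)) attractors <- attractors$attractor
  stopifnot(length(attractors) >= 1)
  keys <- vapply(attractors, `[[`, character(1), "canonical_key")
  ord <- order(keys)
  attractors <- attractors[ord]
  keys <- keys[ord]
  nodes <- colnames(attractors[[1]]$states)
  E <- binary$states[, nodes, drop = FALSE]

  dist_to <- vapply(attractors, function(a) {
    # cells x cycle-states mismatch counts, min over cycle states
    d <- vapply(seq_len(nrow(a$states)), function(i) {
      rowSums(E != matrix(a$states[i, ], nrow(E), length(nodes), byrow = TRUE))
    }, numeric(nrow(E)))
    if (nrow(E) == 1) min(d) else apply(matrix(d, nrow = nrow(E)), 1, min)
  }, numeric(nrow(E)))
  dist_to <- matrix(dist_to, nrow = nrow(E))

  best <- apply(dist_to, 1, which.min) # ties: first = smallest canonical key
  out <- tibble::tibble(
    cell_id = rownames(E),
    attractor = keys[best],
    distance = dist_to[cbind(seq_len(nrow(E)), best)]
  )
  for (col in intersect(c("subject", "group"), names(binary$metadata))) {
    out[[col]] <- binary$metadata[[col]]
  }
  class(out) <- c("attractor_assignment", class(out))
  out
}

#' Summarize an assignment: cells and fractions per attractor
#'
#' @param assignment An `attractor_assignment`.
#' @return Tibble: `attractor`, `n_cells`, `fraction`.
#' @export
assignment_summary <- function(assignment) {
  assignment |>
    dplyr::count(.data$attractor, name = "n_cells") |>
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::arrange(dplyr::desc(.data$n_cells))
}

#' Chi-square association between attractors and subjects/groups
#'
#' Attractors with fewer than `min_count` assigned cells are pooled into an
#' `"other"` category before testing (Pearson chi-square, no continuity
#' correction). Degenerate tables (a single attractor level, or a metadata
#' column with one level) are skipped with a notice.
#'
#' @param assignment An `attractor_assignment` with `subject` and/or `group`.
#' @param min_count Pooling threshold (default 5 cells).
#' @return Tibble: `test` ("subject"/"group"), `statistic`, `df`, `p`,
#'   `n_levels`.
#' @export
association_tests <- function(assignment, min_count = 5) {
  counts <- table(assignment$attractor)
  lab <- ifelse(counts[assignment$attractor] >= min_count,
                assignment$attractor, "other")
  purrr::map_dfr(intersect(c("subject", "group"), names(assignment)),
                 function(col) {
    tab <- table(lab, assignment[[col]])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      message("association test vs ", col, " skipped: degenerate table")
      return(tibble::tibble(test = col, statistic = NA_real_, df = NA_real_,
                            p = NA_real_, n_levels = nrow(tab)))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(test = col, statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p = ct$p.value,
                   n_levels = nrow(tab))
  })
}

#' Write attractor-analysis outputs
#'
#' @param assignment An `attractor_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(assignment, path) {
  readr::write_tsv(tibble::as_tibble(assignment), path)
  invisible(path)
}
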