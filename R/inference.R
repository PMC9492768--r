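#' Total fitting error of a rule set against binarized cells
#'
#' For each cell the network is simulated synchronously from the cell's own
#' binary state until an attractor is reached; the cell's error is the
#' minimum, over the attractor's cycle states, of the per-node mismatch count
#' against the observed state. The total is the sum over cells — the
#' objective the genetic algorithm minimizes.
#'
#' @param rules Named list of `boolean_rule`, one per network node.
#' @param binary A `binary_matrix` whose genes cover the network nodes.
#' @param max_steps Simulation budget per cell (default 100).
#' @return Total error (numeric scalar).
#' @export
rule_fit_error <- function(rules, binary, max_steps = 100) {
  nodes <- sort(names(rules))
  E <- binary$states[, nodes, drop = FALSE]
  compiled <- .compile_rules(rules, nodes)
  cpp_eval_ruleset(E, compiled$regs, compiled$tts, max_steps)$total
}

.eval_indices <- function(indices, candidates, nodes, E, max_steps) {
  regs <- vector("list", length(nodes))
  tts <- vector("list", length(nodes))
  idx <- setNames(seq_along(nodes), nodes)
  for (i in seq_along(nodes)) {
    r <- candidates[[nodes[i]]][[indices[i]]]
    regs[[i]] <- unname(idx[r$genes]) - 1L
    tts[[i]] <- r$tt
  }
  cpp_eval_ruleset(E, regs, tts, max_steps)
}

#' Genetic-algorithm global search over rule-set space
#'
#' Individuals are vectors of candidate indices (one per node); fitness is
#' the total fitting error of [rule_fit_error()]. Tournament selection,
#' one-point crossover, per-position mutation to a random candidate, and one
#' elite individual guarantee a monotone best-fitness trace. Runs are fully
#' reproducible given `seed`.
#'
#' @param candidates Named list (per node) of candidate `boolean_rule` lists,
#'   from [enumerate_candidates()].
#' @param binary A `binary_matrix` covering the nodes.
#' @param pop_size,n_gen,cx_prob,mut_prob,tournament,patience GA
#'   hyperparameters: population 50, 100 generations with early stop after
#'   25 stagnant generations, crossover probability 0.7, per-position
#'   mutation 0.1, tournament size 3. The population/generation budget is
#'   sized so that noise-free benchmark scenarios reach the exhaustive
#'   global optimum (see the methods vignette).
#' @param max_steps Simulation budget per cell.
#' @param seed Integer seed (required for reproducibility).
#' @return List with `rules` (named list of `boolean_rule`), `indices`,
#'   `error` (final total error), and `trace` (best error per generation).
#' @export
ga_search <- function(candidates, binary, pop_size = 50, n_gen = 100,
                      cx_prob = 0.7, mut_prob = 0.1, tournament = 3,
                      patience = 25, max_steps = 100, seed = 1) {
  nodes <- sort(names(candidates))
  n_cand <- vapply(candidates, length, integer(1))[nodes]
  stopifnot(all(n_cand >= 1))
  E <- binary$states[, nodes, drop = FALSE]
  storage.mode(E) <- "integer"

  fit_cache <- new.env(parent = emptyenv())
  fitness <- function(ind) {
    key <- paste(ind, collapse = ",")
    v <- fit_cache[[key]]
    if (is.null(v)) {
      v <- .eval_indices(ind, candidates, nodes, E, max_steps)$total
      fit_cache[[key]] <- v
    }
    v
  }

  withr::local_seed(seed)
  pop <- lapply(seq_len(pop_size), function(i) {
    vapply(n_cand, function(m) sample.int(m, 1), integer(1))
  })
  fits <- vapply(pop, fitness, numeric(1))
  best_i <- which.min(fits)
  best <- pop[[best_i]]
  best_fit <- fits[best_i]
  trace <- best_fit
  stagnant <- 0

  for (gen in seq_len(n_gen)) {
    sel <- function() {
      contenders <- sample.int(pop_size, tournament, replace = TRUE)
      pop[[contenders[which.min(fits[contenders])]]]
    }
    newpop <- vector("list", pop_size)
    newpop[[1]] <- best # elitism
    i <- 2
    while (i <= pop_size) {
      p1 <- sel(); p2 <- sel()
      if (runif(1) < cx_prob && length(nodes) > 1) {
        cut <- sample.int(length(nodes) - 1, 1)
        child <- c(p1[seq_len(cut)], p2[(cut + 1):length(nodes)])
      } else {
        child <- p1
      }
      mut <- runif(length(nodes)) < mut_prob
      if (any(mut)) {
        child[mut] <- vapply(n_cand[mut], function(m) sample.int(m, 1),
                             integer(1))
      }
      newpop[[i]] <- child
      i <- i + 1
    }
    pop <- newpop
    fits <- vapply(pop, fitness, numeric(1))
    gen_best <- which.min(fits)
    if (fits[gen_best] < best_fit) {
      best_fit <- fits[gen_best]
      best <- pop[[gen_best]]
      stagnant <- 0
    } else {
      stagnant <- stagnant + 1
    }
    trace <- c(trace, best_fit)
    if (stagnant >= patience || best_fit == 0) break
  }

  rules <- setNames(
    lapply(seq_along(nodes), function(i) candidates[[nodes[i]]][[best[i]]]),
    nodes
  )
  list(rules = rules, indices = setNames(best, nodes), error = best_fit,
       trace = trace)
}

#' Node-wise local search producing the equivalent rule set (ERS)
#'
#' With all other nodes' rules held fixed, every candidate rule of the focal
#' node is scored by the node-restricted fitting error (the sum over cells of
#' the minimal mismatch of that node alone against the reached attractor).
#' All candidates attaining the minimum form the node's ERS; the incumbent is
#' updated to the simplest ERS member before the next node is processed.
#' Nodes are visited in descending out-degree order (ties alphabetical) so
#' upstream regulators settle first.
#'
#' @param net A [signed_network()].
#' @param candidates Per-node candidate lists.
#' @param incumbent Rule set to refine (from [ga_search()]).
#' @param binary A `binary_matrix`.
#' @param max_steps Simulation budget.
#' @return List with `rulespaces` (named list; per node: `target`,
#'   `candidates`, `max_size`, `ers` (indices into candidates), `min_error`,
#'   `optimized`), `rules` (the refined minimum-error rule set), and
#'   `simplest_rules` (per node, the simplest ERS member — the set used for
#'   attractor and perturbation simulation).
#' @export
local_search <- function(net, candidates, incumbent, binary,
                         max_steps = 100) {
  nodes <- sort(names(candidates))
  E <- binary$states[, nodes, drop = FALSE]
  storage.mode(E) <- "integer"
  outdeg <- table(factor(net$edges$from, levels = nodes))
  order_nodes <- nodes[order(-as.integer(outdeg[nodes]), nodes)]

  rules <- incumbent
  rulespaces <- vector("list", length(nodes))
  names(rulespaces) <- nodes

  for (node in order_nodes) {
    cand <- candidates[[node]]
    pos <- match(node, nodes)
    errs <- vapply(seq_along(cand), function(j) {
      trial <- rules
      trial[[node]] <- cand[[j]]
      compiled <- .compile_rules(trial, nodes)
      cpp_eval_ruleset(E, compiled$regs, compiled$tts,
                       max_steps)$node_err[pos]
    }, numeric(1))
    min_err <- min(errs)
    ers <- which(errs == min_err)
    # canonical ERS order: expression-string lexicographic
    ers <- ers[order(vapply(cand[ers], `[[`, character(1), "expr"))]
    # keep the incumbent rule when it ties (swapping a tied rule can still
    # perturb the other nodes' fit); otherwise take the simplest minimizer
    inc_tt <- paste(rules[[node]]$tt, collapse = "")
    ers_tts <- vapply(cand[ers], function(r) paste(r$tt, collapse = ""),
                      character(1))
    if (!inc_tt %in% ers_tts) rules[[node]] <- simplest_rule(cand[ers])
    rulespaces[[node]] <- list(
      target = node,
      candidates = cand,
      max_size = length(cand),
      ers = ers,
      min_error = min_err,
      optimized = length(ers) < length(cand)
    )
  }
  simplest <- setNames(lapply(nodes, function(n) {
    rs <- rulespaces[[n]]
    simplest_rule(rs$candidates[rs$ers])
  }), nodes)
  list(rulespaces = rulespaces, rules = rules, simplest_rules = simplest)
}

#' Infer Boolean rules for a network from binarized cells
#'
#' Orchestrates the full rule-determination stage: candidate enumeration per
#' node (after the in-degree cap), the genetic-algorithm global search, and
#' the node-wise local search that yields each node's equivalent rule set
#' (ERS). A node is "optimized" when its ERS is smaller than its candidate
#' space; a pathway is optimized when any node is.
#'
#' @param net A [signed_network()] (already pruned to the dataset).
#' @param binary A `binary_matrix` covering the network nodes.
#' @param k_max In-degree cap (default 3).
#' @param max_steps Simulation budget per cell (default 100).
#' @param seed Integer seed.
#' @param ... GA hyperparameters passed to [ga_search()].
#' @return A `rule_fit` object: list with `network`, `rules` (refined
#'   minimum-error rule set), `simplest_rules` (simplest ERS member per
#'   node), `rulespaces`, `ga` (indices, error, trace), `optimized`, `seed`.
#' @export
#'
#' @examples
#' scn <- synthetic_scenario(n_nodes = 6, n_cells = c(40, 40), seed = 1)
#' fit <- infer_rules(scn$network, scn$binary, seed = 1, n_gen = 10)
#' tidy(fit)
infer_rules <- function(net, binary, k_max = 3, max_steps = 100, seed = 1,
                        ...) {
  assignments <- cap_indegree(net, binary, k_max = k_max)
  candidates <- setNames(
    purrr::pmap(assignments, function(target, regulators, signs) {
      enumerate_candidates(target, regulators, signs)
    }),
    assignments$target
  )
  ga <- ga_search(candidates, binary, max_steps = max_steps, seed = seed, ...)
  ls <- local_search(net, candidates, ga$rules, binary, max_steps = max_steps)
  structure(
    list(
      network = net,
      rules = ls$rules,
      simplest_rules = ls$simplest_rules,
      rulespaces = ls$rulespaces,
      ga = ga[c("indices", "error", "trace")],
      optimized = any(vapply(ls$rulespaces, `[[`, logical(1), "optimized")),
      seed = seed
    ),
    class = "rule_fit"
  )
}

#' @export
print.rule_fit <- function(x, ...) {
  cat("<rule_fit> ", x$network$name, ": ", length(x$rules), " nodes, GA error ",
      x$ga$error, ", ", sum(vapply(x$rulespaces, `[[`, logical(1),
                                   "optimized")),
      " node(s) optimized\n", sep = "")
  invisible(x)
}

#' Tidy a fitted rule set
#'
#' @param x A `rule_fit`.
#' @param ... Unused.
#' @return One row per node: `target`, `rule` (simplest ERS expression),
#'   `n_regulators`, `max_ers`, `observed_ers`, `min_error`, `optimized`,
#'   `uncertainty`.
#' @export
tidy.rule_fit <- function(x, ...) {
  rep_rules <- x$simplest_rules %||% x$rules
  purrr::map_dfr(x$rulespaces, function(rs) {
    tibble::tibble(
      target = rs$target,
      rule = rep_rules[[rs$target]]$expr,
      n_regulators = length(x$rules[[rs$target]]$genes),
      max_ers = rs$max_size,
      observed_ers = length(rs$ers),
      min_error = rs$min_error,
      optimized = rs$optimized,
      uncertainty = uncertainty_factor(rs$max_size, length(rs$ers))
    )
  }) |> dplyr::arrange(.data$target)
}

#' @rdname tidy.rule_fit
#' @export
glance.rule_fit <- function(x, ...) {
  tibble::tibble(
    pathway = x$network$name,
    n_nodes = length(x$rules),
    n_edges = nrow(x$network$edges),
    ga_error = x$ga$error,
    n_optimized = sum(vapply(x$rulespaces, `[[`, logical(1), "optimized")),
    optimized = x$optimized,
    seed = x$seed
  )
}

#' Write the ERS of a fit as JSON
#'
#' @param fit A `rule_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ers_json <- function(fit, path) {
  payload <- list(
    pathway = fit$network$name,
    seed = fit$seed,
    ga_error = fit$ga$error,
    optimized = fit$optimized,
    nodes = lapply(fit$rulespaces, function(rs) {
      list(
        target = rs$target,
        max_size = rs$max_size,
        ers = rs$ers,
        min_error = rs$min_error,
        optimized = rs$optimized,
        candidates = vapply(rs$candidates, `[[`, character(1), "expr"),
        truth_tables = lapply(rs$candidates, `[[`, "tt")
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
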