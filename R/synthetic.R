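#' Random signed network with capped in-degree
#'
#' Draws a directed graph over `n_nodes` gene-like symbols (G01, G02, ...):
#' each ordered pair gets an edge with probability `edge_prob`, each node's
#' in-degree is capped at `max_indegree` by keeping a random subset of
#' parents, and each surviving edge is inhibitory with probability
#' `inhibition_frac`. Draws are repeated (bounded) until the graph is weakly
#' connected.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param edge_prob Per-ordered-pair edge probability.
#' @param inhibition_frac Probability an edge is inhibitory.
#' @param max_indegree In-degree cap by construction (default 3).
#' @param seed Integer seed.
#' @param max_tries Connectivity retries (default 50).
#' @return A [signed_network()].
#' @export
random_network <- function(n_nodes, edge_prob = 0.25, inhibition_frac = 0.2,
                           max_indegree = 3, seed = 1, max_tries = 50) {
  stopifnot(n_nodes >= 2)
  withr::local_seed(seed)
  nodes <- sprintf("G%02d", seq_len(n_nodes))
  for (try in seq_len(max_tries)) {
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[runif(nrow(pairs)) < edge_prob, ]
    if (nrow(pairs)) {
      pairs <- pairs |>
        dplyr::group_by(.data$to) |>
        dplyr::slice_sample(n = max_indegree) |>
        dplyr::ungroup()
      pairs$sign <- ifelse(runif(nrow(pairs)) < inhibition_frac, -1L, 1L)
      g <- igraph::graph_from_data_frame(pairs, directed = TRUE,
                                         vertices = data.frame(name = nodes))
      if (igraph::is_connected(g, mode = "weak")) {
        return(signed_network(pairs, nodes = nodes,
                              name = sprintf("random_%d", n_nodes)))
      }
    }
  }
  stop("could not draw a weakly connected network in ", max_tries,
       " tries; increase edge_prob", call. = FALSE)
}

#' Random ground-truth rule set for a network
#'
#' Each node's rule is drawn uniformly from its read-once candidate space
#' (after the in-degree cap implied by the network, which [random_network()]
#' guarantees).
#'
#' @param net A [signed_network()] with max in-degree 3.
#' @param seed Integer seed.
#' @return Named list of `boolean_rule`.
#' @export
random_rules <- function(net, seed = 1) {
  withr::local_seed(seed)
  setNames(lapply(net$nodes, function(node) {
    parents <- dplyr::filter(net$edges, .data$to == node) |>
      dplyr::arrange(.data$from)
    cand <- enumerate_candidates(node, parents$from,
                                 as.integer(parents$sign))
    cand[[sample.int(length(cand), 1)]]
  }), net$nodes)
}

#' Synthetic two-group single-cell scenario from a known Boolean network
#'
#' Emulates the premise that single cells are samples from the attractor
#' landscape of a dynamic Boolean network. Each cell draws an attractor
#' according to its group's mixture weights, then one cycle state uniformly;
#' each bit is flipped with probability `flip_noise` (dropout/noise).
#' Continuous expression is multiplicative-lognormal on top of the binary
#' state — `value = state * (base + gene_effect + group_shift) * lognormal` —
#' so zeros stay zero, mimicking dropout-heavy scRNA-seq. Cells are split
#' round-robin into 4 pseudo-subjects per group.
#'
#' @param n_nodes Network size (default 8).
#' @param n_cells Cells per group, length-2 vector (default c(100, 100)).
#' @param edge_prob,inhibition_frac Network draw parameters.
#' @param flip_noise Per-bit flip probability in [0, 0.5) (default 0.05).
#' @param mean_shift Named per-gene continuous group-2 offsets (default none).
#' @param base Baseline expression magnitude for an ON gene (default 2).
#' @param sdlog Log-sd of the multiplicative noise (default 0.3).
#' @param attractor_weights Optional list of two weight vectors over the true
#'   attractors (one per group); default uniform for both groups.
#' @param seed Integer seed.
#' @return A `synthetic_scenario`: list with `network`, `true_rules`,
#'   `attractors` (tibble from [enumerate_all_attractors()]), `expression`
#'   (an [expr_matrix()]), `binary` (a `binary_matrix`), `params`. Metadata
#'   records `cluster`, `subject`, `group`, and `true_attractor` per cell.
#' @export
#'
#' @examples
#' scn <- synthetic_scenario(n_nodes = 6, n_cells = c(30, 30), seed = 7)
#' table(scn$binary$metadata$group)
synthetic_scenario <- function(n_nodes = 8, n_cells = c(100, 100),
                               edge_prob = 0.3, inhibition_frac = 0.2,
                               flip_noise = 0.05, mean_shift = NULL,
                               base = 2, sdlog = 0.3,
                               attractor_weights = NULL, seed = 1) {
  stopifnot(length(n_cells) == 2, flip_noise >= 0, flip_noise < 0.5)
  net <- random_network(n_nodes, edge_prob = edge_prob,
                        inhibition_frac = inhibition_frac, seed = seed)
  rules <- random_rules(net, seed = seed + 1L)
  atts <- enumerate_all_attractors(rules)
  n_att <- nrow(atts)
  if (is.null(attractor_weights)) {
    attractor_weights <- list(rep(1 / n_att, n_att), rep(1 / n_att, n_att))
  }
  stopifnot(length(attractor_weights) == 2,
            all(vapply(attractor_weights, length, integer(1)) == n_att))

  withr::local_seed(seed + 2L)
  nodes <- net$nodes
  gene_effect <- setNames(runif(length(nodes), 0, 1), nodes)
  shift <- setNames(rep(0, length(nodes)), nodes)
  if (!is.null(mean_shift)) {
    shift[toupper(names(mean_shift))] <- mean_shift
  }

  groups <- c("group1", "group2")
  rows <- list()
  meta <- list()
  cell_i <- 0
  for (g in 1:2) {
    w <- attractor_weights[[g]] / sum(attractor_weights[[g]])
    for (i in seq_len(n_cells[g])) {
      cell_i <- cell_i + 1
      a_idx <- sample.int(n_att, 1, prob = w)
      cyc <- atts$attractor[[a_idx]]$states
      state <- cyc[sample.int(nrow(cyc), 1), ]
      flips <- runif(length(state)) < flip_noise
      state[flips] <- 1L - state[flips]
      magnitude <- base + gene_effect + (if (g == 2) shift else 0)
      cont <- state * pmax(magnitude, 0) *
        rlnorm(length(state), 0, sdlog)
      rows[[cell_i]] <- list(state = state, cont = cont)
      meta[[cell_i]] <- tibble::tibble(
        cell_id = sprintf("cell%04d", cell_i),
        cluster = "synthetic",
        subject = sprintf("%s_s%d", groups[g], (i - 1) %% 4 + 1),
        group = groups[g],
        true_attractor = atts$canonical_key[a_idx]
      )
    }
  }
  states <- do.call(rbind, lapply(rows, `[[`, "state"))
  cont <- do.call(rbind, lapply(rows, `[[`, "cont"))
  metadata <- dplyr::bind_rows(meta)
  dimnames(states) <- dimnames(cont) <- list(metadata$cell_id, nodes)
  storage.mode(states) <- "integer"

  expr <- expr_matrix(cont, metadata)
  binary <- structure(
    list(states = states, continuous = cont, metadata = metadata),
    class = "binary_matrix", method = "generator"
  )
  structure(
    list(network = net, true_rules = rules, attractors = atts,
         expression = expr, binary = binary,
         params = list(n_nodes = n_nodes, n_cells = n_cells,
                       edge_prob = edge_prob,
                       inhibition_frac = inhibition_frac,
                       flip_noise = flip_noise, mean_shift = as.list(shift),
                       base = base, sdlog = sdlog, seed = seed)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> ", length(x$network$nodes), " nodes, ",
      nrow(x$binary$states), " cells, ", nrow(x$attractors),
      " true attractors (seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a scenario to the on-disk formats the pipeline reads
#'
#' Emits `matrix.mtx` + `features.tsv` + `barcodes.tsv`, `metadata.csv`, the
#' network as GraphML, and `scenario.json` with all parameters.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(scenario$expression$values), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(id = colnames(scenario$expression$values),
                   symbol = colnames(scenario$expression$values)),
    file.path(dir, "features.tsv"), col_names = FALSE
  )
  readr::write_tsv(
    tibble::tibble(barcode = rownames(scenario$expression$values)),
    file.path(dir, "barcodes.tsv"), col_names = FALSE
  )
  readr::write_csv(scenario$binary$metadata, file.path(dir, "metadata.csv"))
  write_graphml(scenario$network, file.path(dir, "network.graphml"))
  jsonlite::write_json(scenario$params, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
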