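#' Rule-determination uncertainty factor
#'
#' `(|max ERS| - |observed ERS| + 1) / |max ERS|`: equals 1 when the local
#' search narrowed a node to a single rule, and `1/|max ERS|` when no
#' reduction was achieved. It down-weights the importance of nodes whose
#' update logic remains ambiguous.
#'
#' @param max_size Size of the node's full candidate space (|max ERS|).
#' @param observed_size Size of the equivalent rule set after optimization.
#' @return Value in (0, 1].
#' @export
#'
#' @examples
#' uncertainty_factor(17, 1)   # 1
#' uncertainty_factor(17, 17)  # 1/17
uncertainty_factor <- function(max_size, observed_size) {
  stopifnot(max_size >= 1, observed_size >= 1, observed_size <= max_size)
  (max_size - observed_size + 1) / max_size
}

#' Perturbation-based node importance scores
#'
#' For every node and every cell, the network is simulated from the cell's
#' binary state twice — with the node clamped to 1 (knock-in) and to 0
#' (knock-out). The node's raw importance is the sum over cells of the L1
#' distance between the two attractors' mean-state vectors, multiplied by the
#' node's uncertainty factor; scores are scaled to [0, 1] by the network
#' maximum. Cells sharing a binary state are simulated once.
#'
#' @param fit A `rule_fit` from [infer_rules()], or a list with `rules` and
#'   `rulespaces` (the simplest-ERS-member rules are used for simulation
#'   when present; ERS multiplicity enters through the uncertainty factor).
#' @param binary A `binary_matrix` covering the network nodes.
#' @param max_steps Simulation budget.
#' @return A tibble: `gene`, `raw`, `uncertainty`, `importance` (scaled).
#' @export
importance_scores <- function(fit, binary, max_steps = 100) {
  rules <- fit$simplest_rules %||% fit$rules
  nodes <- sort(names(rules))
  E <- binary$states[, nodes, drop = FALSE]
  storage.mode(E) <- "integer"
  compiled <- .compile_rules(rules, nodes)

  uf <- vapply(nodes, function(n) {
    rs <- fit$rulespaces[[n]]
    if (is.null(rs)) 1 else uncertainty_factor(rs$max_size, length(rs$ers))
  }, numeric(1))

  # dedup cell states; weight by multiplicity
  keys <- apply(E, 1, paste, collapse = "")
  tab <- table(keys)
  uniq <- E[match(names(tab), keys), , drop = FALSE]
  w <- as.numeric(tab)

  raw <- vapply(seq_along(nodes), function(i) {
    cl_ki <- rep(-1L, length(nodes)); cl_ki[i] <- 1L
    cl_ko <- rep(-1L, length(nodes)); cl_ko[i] <- 0L
    ki <- cpp_attractors(uniq, compiled$regs, compiled$tts, cl_ki, max_steps)
    ko <- cpp_attractors(uniq, compiled$regs, compiled$tts, cl_ko, max_steps)
    d <- vapply(seq_along(ki), function(c) {
      sum(abs(colMeans(ki[[c]]) - colMeans(ko[[c]])))
    }, numeric(1))
    sum(w * d)
  }, numeric(1))

  raw <- unname(raw * unname(uf))
  scaled <- if (max(raw) > 0) raw / max(raw) else raw
  tibble::tibble(gene = nodes, raw = raw, uncertainty = unname(uf),
                 importance = scaled)
}

#' Per-gene two-group contrast statistics
#'
#' Computed on the retained continuous expression values: `ra` is the
#' absolute difference in group mean expression (relative abundance), `sigma`
#' the standard deviation across all cells in the cluster, and `log2fc` the
#' signed log2 fold change (group 1 vs group 2, with a pseudocount).
#'
#' @param binary A `binary_matrix` with a `group` metadata column.
#' @param groups Pair of group labels (group 1 vs group 2); defaults to the
#'   sorted unique labels.
#' @param genes Genes to report (default: all).
#' @param pseudocount Added to both group means before the log ratio.
#' @return A tibble: `gene`, `ra`, `sigma`, `log2fc`, plus attributes
#'   recording the groups.
#' @export
contrast_stats <- function(binary, groups = NULL, genes = NULL,
                           pseudocount = 0.01) {
  meta <- binary$metadata
  stopifnot("group" %in% names(meta))
  if (is.null(groups)) groups <- sort(unique(meta$group))
  stopifnot(length(groups) == 2)
  g1 <- meta$group == groups[1]
  g2 <- meta$group == groups[2]
  if (!any(g1) || !any(g2)) stop("both contrast groups must be non-empty",
                                 call. = FALSE)
  v <- binary$continuous
  if (!is.null(genes)) {
    missing <- setdiff(toupper(genes), colnames(v))
    if (length(missing)) stop("genes absent from data: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    v <- v[, toupper(genes), drop = FALSE]
  }
  m1 <- colMeans(v[g1, , drop = FALSE])
  m2 <- colMeans(v[g2, , drop = FALSE])
  out <- tibble::tibble(
    gene = colnames(v),
    ra = unname(abs(m1 - m2)),
    sigma = unname(apply(v, 2, sd)),
    log2fc = unname(log2((m1 + pseudocount) / (m2 + pseudocount)))
  )
  attr(out, "groups") <- groups
  attr(out, "n_cells") <- c(sum(g1), sum(g2))
  out
}

#' Pathway modulation score
#'
#' `M_p = sum over pathway genes of ra * sigma * importance` — the node
#' importance weighted by the between-group expression shift and the
#' expression variability. Pathway genes absent from the statistics table
#' contribute 0.
#'
#' @param stats Output of [contrast_stats()].
#' @param importance Output of [importance_scores()] (columns `gene`,
#'   `importance`).
#' @param genes Pathway gene symbols; defaults to the importance table genes.
#' @return Numeric scalar.
#' @export
modulation_score <- function(stats, importance, genes = NULL) {
  if (is.null(genes)) genes <- importance$gene
  genes <- toupper(genes)
  tab <- dplyr::inner_join(
    dplyr::filter(stats, .data$gene %in% genes),
    importance[, c("gene", "importance")],
    by = "gene"
  )
  sum(tab$ra * tab$sigma * tab$importance)
}

#' Permutation p-value for the pathway modulation score
#'
#' Default scheme: the cell group labels are permuted `B` times and the
#' relative-abundance values recomputed under each permutation (sigma and the
#' importance scores stay fixed), giving a null distribution of modulation
#' scores; `p = (1 + #\{M_perm >= M_obs\}) / (B + 1)`. The alternative
#' `scheme = "resample_ra"` draws the genes' RA values with replacement
#' across genes instead of permuting labels.
#'
#' @inheritParams modulation_score
#' @param binary A `binary_matrix` with group metadata.
#' @param groups Pair of group labels.
#' @param B Number of permutations (default 1000, minimum 100).
#' @param scheme `"permute_labels"` (default) or `"resample_ra"`.
#' @param seed Integer seed.
#' @return List with `m_obs`, `p`, `B`, `scheme`.
#' @export
bootstrap_pvalue <- function(binary, importance, genes = NULL, groups = NULL,
                             B = 1000, scheme = c("permute_labels",
                                                  "resample_ra"),
                             seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(B >= 100)
  stats <- contrast_stats(binary, groups = groups)
  if (is.null(genes)) genes <- importance$gene
  genes <- intersect(toupper(genes), stats$gene)
  m_obs <- modulation_score(stats, importance, genes)

  tab <- dplyr::inner_join(dplyr::filter(stats, .data$gene %in% genes),
                           importance[, c("gene", "importance")], by = "gene")
  withr::local_seed(seed)
  if (scheme == "permute_labels") {
    groups_used <- attr(stats, "groups")
    meta <- binary$metadata
    in_contrast <- meta$group %in% groups_used
    v <- binary$continuous[in_contrast, tab$gene, drop = FALSE]
    lab <- meta$group[in_contrast]
    n1 <- sum(lab == groups_used[1])
    n <- length(lab)
    w <- tab$sigma * tab$importance
    m_perm <- vapply(seq_len(B), function(b) {
      pick <- sample.int(n, n1)
      ra_b <- abs(colMeans(v[pick, , drop = FALSE]) -
                    colMeans(v[-pick, , drop = FALSE]))
      sum(ra_b * w)
    }, numeric(1))
  } else {
    ra_pool <- stats$ra
    w <- tab$sigma * tab$importance
    m_perm <- vapply(seq_len(B), function(b) {
      sum(sample(ra_pool, length(w), replace = TRUE) * w)
    }, numeric(1))
  }
  list(m_obs = m_obs, p = (1 + sum(m_perm >= m_obs)) / (B + 1), B = B,
       scheme = scheme)
}

#' Pathway analysis across fitted networks
#'
#' For each fitted pathway: perturbation importance scores, the modulation
#' score for the configured two-group contrast, a permutation p-value,
#' Bonferroni correction over all pathways tested, and an up/down direction
#' call from the sign of the summed log2 fold changes. The full table is
#' returned; the conventional report keeps optimized pathways with adjusted
#' p below `alpha`.
#'
#' @param fits List of `rule_fit` objects (one per pathway).
#' @param binary A `binary_matrix` with group metadata (the contrast cells).
#' @param groups Pair of group labels.
#' @param B Permutations for the p-value.
#' @param alpha Significance threshold on the adjusted p (default 0.01).
#' @param scheme Permutation scheme, see [bootstrap_pvalue()].
#' @param seed Integer seed.
#' @param max_steps Simulation budget.
#' @return A `pathway_results` tibble: `pathway`, `n_nodes`, `m_p`, `p`,
#'   `p_adj`, `direction`, `optimized`, `significant`, and a list-column
#'   `importance` of per-gene score tables.
#' @export
analyze_pathways <- function(fits, binary, groups = NULL, B = 1000,
                             alpha = 0.01, scheme = "permute_labels",
                             seed = 1, max_steps = 100) {
  if (inherits(fits, "rule_fit")) fits <- list(fits)
  stats <- contrast_stats(binary, groups = groups)
  rows <- purrr::imap_dfr(fits, function(fit, i) {
    imp <- importance_scores(fit, binary, max_steps = max_steps)
    bt <- bootstrap_pvalue(binary, imp, genes = imp$gene, groups = groups,
                           B = B, scheme = scheme,
                           seed = seed + as.integer(i))
    fc <- sum(stats$log2fc[stats$gene %in% imp$gene])
    tibble::tibble(
      pathway = fit$network$name,
      n_nodes = length(fit$rules),
      m_p = bt$m_obs,
      p = bt$p,
      direction = if (fc < 0) "down" else "up",
      sum_log2fc = fc,
      optimized = fit$optimized,
      importance = list(imp)
    )
  })
  rows$p_adj <- pmin(1, rows$p * nrow(rows))
  rows$significant <- rows$optimized & rows$p_adj < alpha
  class(rows) <- c("pathway_results", class(rows))
  attr(rows, "alpha") <- alpha
  attr(rows, "scheme") <- scheme
  rows
}

#' Write pathway-analysis outputs
#'
#' `write_pathway_results_tsv()` writes the pathway-level table;
#' `write_importance_tsv()` one pathway's per-gene scores;
#' `write_annotated_graphml()` the network with importance and log2fc node
#' attributes and signed edges for figure reproduction.
#'
#' @param results A `pathway_results` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_results_tsv <- function(results, path) {
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(results), "pathway", "n_nodes", "m_p",
                  "p", "p_adj", "direction", "optimized", "significant"),
    path
  )
  invisible(path)
}

#' @rdname write_pathway_results_tsv
#' @param importance Per-gene importance tibble.
#' @export
write_importance_tsv <- function(importance, path) {
  readr::write_tsv(importance, path)
  invisible(path)
}

#' @rdname write_pathway_results_tsv
#' @param net A [signed_network()].
#' @param stats Output of [contrast_stats()].
#' @export
write_annotated_graphml <- function(net, importance, stats, path) {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = TRUE, vertices = data.frame(name = net$nodes)
  )
  imp <- importance$importance[match(net$nodes, importance$gene)]
  fc <- stats$log2fc[match(net$nodes, stats$gene)]
  g <- igraph::set_vertex_attr(g, "importance",
                               value = ifelse(is.na(imp), 0, imp))
  g <- igraph::set_vertex_attr(g, "log2fc", value = ifelse(is.na(fc), 0, fc))
  g <- igraph::set_edge_attr(g, "signal",
                             value = ifelse(net$edges$sign > 0, "a", "i"))
  g <- igraph::delete_edge_attr(g, "sign")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
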