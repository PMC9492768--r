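#' Rule-inference certainty versus training-set size
#'
#' Re-runs rule inference on random subsamples of the training cells
#' (fractions of the full cluster; fractions above 1 draw the extra cells
#' from `augment_pool`, emulating augmentation with a neighboring cluster)
#' and records the mean observed ERS size per in-degree class. Shrinking ERS
#' sizes with more cells indicate the data are actually constraining the
#' rule space; the in-degree-3 class is the most demanding case.
#'
#' @param net A [signed_network()].
#' @param binary A `binary_matrix` covering the network nodes.
#' @param fractions Training-set fractions (default c(0.01, 0.5, 1)).
#' @param augment_pool Optional `binary_matrix` supplying cells for
#'   fractions > 1.
#' @param n_seeds Replicates per fraction (default 1; each replicate
#'   resamples cells and re-seeds the GA).
#' @param seed Base seed.
#' @param ... Passed to [infer_rules()].
#' @return Tibble: `fraction`, `replicate`, `n_cells`, `indegree`,
#'   `n_nodes`, `mean_ers`, `mean_uncertainty`.
#' @export
ers_vs_cells <- function(net, binary, fractions = c(0.01, 0.5, 1),
                         augment_pool = NULL, n_seeds = 1, seed = 1, ...) {
  if (any(fractions > 1) && is.null(augment_pool)) {
    stop("fractions > 1 require an augment_pool", call. = FALSE)
  }
  n <- nrow(binary$states)
  purrr::map_dfr(fractions, function(f) {
    purrr::map_dfr(seq_len(n_seeds), function(r) {
      s <- seed + r * 1000L + as.integer(round(f * 100))
      withr::local_seed(s)
      if (f <= 1) {
        keep <- sample.int(n, max(2, round(f * n)))
        states <- binary$states[keep, , drop = FALSE]
        cont <- binary$continuous[keep, , drop = FALSE]
        meta <- binary$metadata[keep, ]
      } else {
        extra_n <- round((f - 1) * n)
        pool_idx <- sample.int(nrow(augment_pool$states), extra_n,
                               replace = extra_n > nrow(augment_pool$states))
        states <- rbind(binary$states,
                        augment_pool$states[pool_idx, , drop = FALSE])
        cont <- rbind(binary$continuous,
                      augment_pool$continuous[pool_idx, , drop = FALSE])
        meta <- dplyr::bind_rows(binary$metadata,
                                 augment_pool$metadata[pool_idx, ])
        meta$cell_id <- make.unique(meta$cell_id)
        rownames(states) <- rownames(cont) <- meta$cell_id
      }
      sub <- structure(list(states = states, continuous = cont,
                            metadata = meta),
                       class = "binary_matrix", method = attr(binary, "method"))
      fit <- infer_rules(net, sub, seed = s, ...)
      td <- tidy(fit)
      td |>
        dplyr::group_by(indegree = .data$n_regulators) |>
        dplyr::summarise(n_nodes = dplyr::n(),
                         mean_ers = mean(.data$observed_ers),
                         mean_uncertainty = mean(.data$uncertainty),
                         .groups = "drop") |>
        dplyr::mutate(fraction = f, replicate = r, n_cells = nrow(states),
                      .before = 1)
    })
  })
}
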