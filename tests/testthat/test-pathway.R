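test_that("uncertainty factor matches its closed forms", {
  expect_equal(uncertainty_factor(17, 1), 1)
  expect_equal(uncertainty_factor(17, 17), 1 / 17)
  expect_equal(uncertainty_factor(4, 2), 0.75)
  expect_error(uncertainty_factor(4, 5))
})

test_that("importance of the two-node chain matches the hand derivation", {
  fit <- list(rules = chain_rules(), rulespaces = NULL)
  b <- make_binary(matrix(c(0L, 0L), 1, 2, dimnames = list("c1",
                                                           c("A", "B"))))
  imp <- importance_scores(fit, b)
  expect_equal(imp$raw[imp$gene == "A"], 2)   # A and B both differ
  expect_equal(imp$raw[imp$gene == "B"], 1)   # only B differs
  expect_equal(imp$importance, c(1, 0.5))
  expect_equal(imp$uncertainty, c(1, 1))
})

test_that("scaled importance lies in [0,1] with max 1, invariant to common rescaling", {
  scn <- synthetic_scenario(n_nodes = 7, n_cells = c(30, 30), seed = 13)
  fit <- infer_rules(scn$network, scn$binary, seed = 2)
  imp <- importance_scores(fit, scn$binary)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_equal(max(imp$importance), 1)
  # a common factor on all uncertainty weights cancels in the scaled scores:
  # raw scores scale linearly, so raw/max(raw) is unchanged
  expect_equal((imp$raw * 0.5) / max(imp$raw * 0.5), imp$importance)
})

test_that("contrast statistics compute RA, sigma, and log2fc per definition", {
  v <- rbind(matrix(2, 10, 2), matrix(1, 10, 2))
  colnames(v) <- c("G1", "G2")
  v[, 2] <- 3 # constant gene across groups
  rownames(v) <- sprintf("c%02d", 1:20)
  meta <- tibble::tibble(cell_id = rownames(v),
                         group = rep(c("g1", "g2"), each = 10))
  b <- make_binary((v > 0) * 1L, metadata = meta, continuous = v)
  st <- contrast_stats(b, groups = c("g1", "g2"))
  expect_equal(st$ra[st$gene == "G1"], 1)
  expect_equal(st$log2fc[st$gene == "G1"], log2(2.01 / 1.01))
  expect_equal(st$ra[st$gene == "G2"], 0)
  expect_equal(st$sigma[st$gene == "G2"], 0)
  # identical groups: RA = 0 everywhere
  meta_same <- meta
  v_same <- rbind(v[1:10, ], v[1:10, ])
  rownames(v_same) <- rownames(v)
  b_same <- make_binary((v_same > 0) * 1L, metadata = meta_same,
                        continuous = v_same)
  expect_true(all(contrast_stats(b_same)$ra == 0))
})

test_that("modulation score is the RA * sigma * importance sum, order-invariant", {
  st <- tibble::tibble(gene = c("G1", "G2"), ra = c(0.5, 0),
                       sigma = c(0.2, 3), log2fc = c(1, 0))
  imp <- tibble::tibble(gene = c("G1", "G2"), importance = c(1, 1))
  expect_equal(modulation_score(st, imp), 0.1)
  expect_equal(modulation_score(st, imp, genes = c("G2", "G1")), 0.1)
  st0 <- dplyr::mutate(st, ra = 0)
  expect_equal(modulation_score(st0, imp), 0)
})

test_that("permutation p-values are seeded, valid, and detect a real shift", {
  scn <- synthetic_scenario(n_nodes = 6, n_cells = c(60, 60),
                            mean_shift = setNames(rep(3, 3),
                                                  c("G01", "G02", "G03")),
                            seed = 31)
  imp <- importance_scores(list(rules = scn$true_rules, rulespaces = NULL),
                           scn$binary)
  p1 <- bootstrap_pvalue(scn$binary, imp, B = 200, seed = 5)
  p2 <- bootstrap_pvalue(scn$binary, imp, B = 200, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_gt(p1$p, 0)
  expect_lte(p1$p, 1)
  expect_lt(p1$p, 0.05) # strong injected shift
  # alternative scheme runs and is seeded
  pr <- bootstrap_pvalue(scn$binary, imp, B = 200, seed = 5,
                         scheme = "resample_ra")
  expect_identical(pr$scheme, "resample_ra")
  expect_gt(pr$p, 0)
})

test_that("pathway table applies Bonferroni, direction, and the optimized filter", {
  scn <- synthetic_scenario(n_nodes = 6, n_cells = c(40, 40),
                            mean_shift = setNames(rep(2, 6),
                                                  sprintf("G%02d", 1:6)),
                            seed = 41)
  fit <- infer_rules(scn$network, scn$binary, seed = 1)
  decoy <- synthetic_scenario(n_nodes = 6, n_cells = c(40, 40), seed = 42)
  fit2 <- infer_rules(decoy$network, decoy$binary, seed = 1)
  fit2$network$name <- "decoy"
  res <- analyze_pathways(list(fit, fit2), scn$binary, B = 200, seed = 7)
  expect_equal(res$p_adj, pmin(1, res$p * 2))
  expect_true(all(res$direction %in% c("up", "down")))
  expect_equal(res$direction, ifelse(res$sum_log2fc < 0, "down", "up"))
  # a pathway that is not optimized can never be flagged significant
  expect_true(all(!res$significant[!res$optimized]))
  # output writers produce the declared files
  tsv <- tempfile(fileext = ".tsv")
  write_pathway_results_tsv(res, tsv)
  expect_true(file.exists(tsv))
  gml <- tempfile(fileext = ".graphml")
  st <- contrast_stats(scn$binary)
  write_annotated_graphml(scn$network, res$importance[[1]], st, gml)
  back <- parse_graphml(gml)
  expect_setequal(back$nodes, scn$network$nodes)
})

test_that("importance is context-dependent, not a pure topology statistic", {
  # same graph, two different rule sets: node ordering by importance differs
  net <- random_network(6, edge_prob = 0.4, seed = 55)
  b <- make_binary(matrix(rbinom(40 * 6, 1, 0.5), 40, 6,
                          dimnames = list(NULL, net$nodes)))
  rho <- c()
  found_different <- FALSE
  prev_order <- NULL
  for (s in c(2, 8, 20, 33)) {
    rules <- random_rules(net, seed = s)
    imp <- importance_scores(list(rules = rules, rulespaces = NULL), b)
    deg <- table(factor(c(net$edges$from, net$edges$to),
                        levels = net$nodes))
    rho <- c(rho, suppressWarnings(
      cor(imp$importance, as.numeric(deg), method = "spearman")))
    ord <- imp$gene[order(-imp$importance)]
    if (!is.null(prev_order) && !identical(ord, prev_order)) {
      found_different <- TRUE
    }
    prev_order <- ord
  }
  expect_true(found_different)
  expect_lt(mean(abs(rho), na.rm = TRUE), 0.9)
})
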