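test_that("ERS sampling is seeded, uniform, and degenerate for singletons", {
  scn <- synthetic_scenario(n_nodes = 6, n_cells = c(40, 40), seed = 3)
  fit <- infer_rules(scn$network, scn$binary, seed = 1)
  s1 <- sample_rulesets(fit, n = 5, seed = 9)
  s2 <- sample_rulesets(fit, n = 5, seed = 9)
  expect_identical(lapply(s1, write_rules_txt), lapply(s2, write_rules_txt))

  # all-singleton ERS: every sample is the same rule set
  fit_singleton <- fit
  for (n in names(fit_singleton$rulespaces)) {
    fit_singleton$rulespaces[[n]]$ers <- fit_singleton$rulespaces[[n]]$ers[1]
  }
  ss <- sample_rulesets(fit_singleton, n = 4, seed = 2)
  expect_length(unique(lapply(ss, write_rules_txt)), 1)

  # uniformity over a 4-member ERS: binomial 3-sigma band around 1/4
  net <- signed_network(data.frame(from = c("A", "B"), to = "Z", sign = 1L))
  cand <- list(
    A = enumerate_candidates("A", character(0), integer(0)),
    B = enumerate_candidates("B", character(0), integer(0)),
    Z = enumerate_candidates("Z", c("A", "B"), c(1L, 1L))
  )
  fake <- list(rulespaces = list(
    A = list(target = "A", candidates = cand$A, ers = 1, max_size = 1),
    B = list(target = "B", candidates = cand$B, ers = 1, max_size = 1),
    Z = list(target = "Z", candidates = cand$Z, ers = 1:4, max_size = 4)
  ))
  n_draw <- 4000
  draws <- sample_rulesets(fake, n = n_draw, seed = 1)
  freq <- table(vapply(draws, function(r) r$Z$expr, character(1))) / n_draw
  band <- 3 * sqrt(0.25 * 0.75 / n_draw)
  expect_true(all(abs(freq - 0.25) < band))
})

test_that("harvested attractors are contained in the exhaustive set per rule set", {
  scn <- synthetic_scenario(n_nodes = 7, n_cells = c(30, 30), seed = 11)
  fit <- infer_rules(scn$network, scn$binary, seed = 1)
  harvested <- harvest_attractors(fit, scn$binary, n_rulesets = 5, seed = 4)
  expect_gt(nrow(harvested), 0)
  # simplest-rule attractors must appear in that rule set's exhaustive sweep
  full <- enumerate_all_attractors(fit$simplest_rules)
  simplest_keys <- harvested$canonical_key[
    vapply(harvested$provenance, function(p) "simplest" %in% p, logical(1))
  ]
  expect_true(all(simplest_keys %in% full$canonical_key))
  # cells all sitting on one fixed point harvest exactly that attractor
  fp <- full$attractor[[which(full$cycle_length == 1)[1]]]
  if (!is.null(fp)) {
    b_fp <- make_binary(matrix(rep(fp$states[1, ], 5), 5, byrow = TRUE,
                               dimnames = list(NULL, scn$network$nodes)))
    h1 <- harvest_attractors(fit, b_fp, n_rulesets = 0,
                             include_simplest = TRUE, seed = 1)
    expect_equal(h1$canonical_key, fp$canonical_key)
  }
})

test_that("cells are assigned to the nearest attractor with canonical tie-breaks", {
  scn <- synthetic_scenario(n_nodes = 6, n_cells = c(20, 20), seed = 17)
  atts <- scn$attractors
  # a cell equal to a fixed point is assigned there at distance 0
  fp_idx <- which(atts$cycle_length == 1)[1]
  fp <- atts$attractor[[fp_idx]]
  b <- make_binary(matrix(fp$states[1, ], 1,
                          dimnames = list("c1", scn$network$nodes)))
  asg <- assign_cells(b, atts)
  expect_equal(asg$attractor, fp$canonical_key)
  expect_equal(asg$distance, 0)

  # tie goes to the smallest canonical key: build two fixed points and a
  # cell equidistant from both
  two <- list(
    structure(list(states = matrix(c(0L, 0L, 0L), 1,
                                   dimnames = list(NULL, c("A", "B", "C"))),
                   canonical_key = "000",
                   mean_state = c(A = 0, B = 0, C = 0)),
              class = "attractor"),
    structure(list(states = matrix(c(0L, 1L, 1L), 1,
                                   dimnames = list(NULL, c("A", "B", "C"))),
                   canonical_key = "011",
                   mean_state = c(A = 0, B = 1, C = 1)),
              class = "attractor")
  )
  cell <- make_binary(matrix(c(0L, 1L, 0L), 1,
                             dimnames = list("c1", c("A", "B", "C"))))
  tie <- assign_cells(cell, rev(two)) # order must not matter
  expect_equal(tie$attractor, "000")
  expect_equal(tie$distance, 1)

  # three-cell worked example with hand-computed distances
  cells3 <- make_binary(matrix(c(0L, 0L, 0L,
                                 1L, 1L, 1L,
                                 0L, 1L, 1L), 3, byrow = TRUE,
                               dimnames = list(paste0("c", 1:3),
                                               c("A", "B", "C"))))
  asg3 <- assign_cells(cells3, two)
  expect_equal(asg3$attractor, c("000", "011", "011"))
  expect_equal(asg3$distance, c(0, 1, 0))
})

test_that("assignment fractions sum to one and recovery beats 90% at 5% flips", {
  correct <- 0L
  total <- 0L
  for (s in 1:20) {
    scn <- synthetic_scenario(n_nodes = 8, n_cells = c(60, 60),
                              flip_noise = 0.05, seed = s)
    asg <- assign_cells(scn$binary, scn$attractors)
    smry <- assignment_summary(asg)
    expect_equal(sum(smry$fraction), 1)
    correct <- correct +
      sum(asg$attractor == scn$binary$metadata$true_attractor)
    total <- total + nrow(asg)
  }
  expect_gte(correct / total, 0.9)
})

test_that("chi-square association uses Pearson without correction and pools rare attractors", {
  # [[10,0],[0,10]] -> X^2 = 20, df = 1
  asg <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:20),
    attractor = rep(c("a1", "a2"), each = 10),
    distance = 0,
    group = rep(c("g1", "g2"), each = 10)
  )
  class(asg) <- c("attractor_assignment", class(asg))
  res <- association_tests(asg)
  expect_equal(res$statistic[res$test == "group"], 20)
  expect_equal(res$df[res$test == "group"], 1)

  # identical row distributions: X^2 = 0, p = 1
  asg0 <- asg
  asg0$attractor <- rep(c("a1", "a2"), 10)
  res0 <- association_tests(asg0)
  expect_equal(res0$statistic[res0$test == "group"], 0)
  expect_equal(res0$p[res0$test == "group"], 1)

  # attractors with fewer than 5 cells pool into "other"
  asg_rare <- asg
  asg_rare$attractor[1:4] <- c("r1", "r2", "r3", "r4")
  res_rare <- association_tests(asg_rare)
  expect_equal(res_rare$n_levels[res_rare$test == "group"], 3) # a1, a2, other

  # degenerate single-level table is skipped with a notice
  asg1 <- asg
  asg1$attractor <- "a1"
  expect_message(res1 <- association_tests(asg1), "degenerate")
  expect_true(is.na(res1$p[res1$test == "group"]))
})
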