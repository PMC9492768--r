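test_that("rule_fit_error reproduces hand-simulated totals", {
  rules <- chain_rules()
  # fixed-point cells score zero
  b0 <- make_binary(matrix(c(1L, 1L), 1, 2, dimnames = list("c1",
                                                            c("A", "B"))))
  expect_equal(rule_fit_error(rules, b0), 0)
  # cell (1,0) flows to fixed point (1,1): error 1
  b1 <- make_binary(matrix(c(1L, 0L), 1, 2, dimnames = list("c1",
                                                            c("A", "B"))))
  expect_equal(rule_fit_error(rules, b1), 1)
  # a cell on a 2-cycle scores the closest cycle state: 0
  mutual <- list(
    A = enumerate_candidates("A", "B", 1L)[[1]],
    B = enumerate_candidates("B", "A", 1L)[[1]]
  )
  b2 <- make_binary(matrix(c(1L, 0L), 1, 2, dimnames = list("c1",
                                                            c("A", "B"))))
  expect_equal(rule_fit_error(mutual, b2), 0)
})

test_that("GA is reproducible, elitist, and solves noise-free toys exactly", {
  for (s in 1:6) {
    scn <- synthetic_scenario(n_nodes = 5, n_cells = c(30, 30),
                              flip_noise = 0, seed = s)
    asg <- cap_indegree(scn$network, scn$binary)
    candidates <- setNames(
      purrr::pmap(asg, function(target, regulators, signs) {
        enumerate_candidates(target, regulators, signs)
      }), asg$target)

    ga1 <- ga_search(candidates, scn$binary, seed = 17)
    ga2 <- ga_search(candidates, scn$binary, seed = 17)
    expect_identical(ga1$indices, ga2$indices)
    expect_identical(ga1$trace, ga2$trace)
    # monotone non-increasing best-fitness trace (elitism contract)
    expect_true(all(diff(ga1$trace) <= 0))
    # exhaustive oracle: GA + local search reaches the global optimum
    opt <- oracle_global_min_error(candidates, scn$binary)
    ls <- local_search(scn$network, candidates, ga1$rules, scn$binary)
    expect_equal(rule_fit_error(ls$rules, scn$binary), opt)
  }
})

test_that("local search recovers an exact AND rule from saturating data", {
  # Z = A and B, with A, B free inputs; data = all fixed points of the true
  # system so every regulator configuration appears in attractor states
  net <- signed_network(
    data.frame(from = c("A", "B"), to = "Z", sign = 1L)
  )
  cand <- list(
    A = enumerate_candidates("A", character(0), integer(0)),
    B = enumerate_candidates("B", character(0), integer(0)),
    Z = enumerate_candidates("Z", c("A", "B"), c(1L, 1L))
  )
  states <- rbind(
    c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 1L)
  )
  colnames(states) <- c("A", "B", "Z")
  b <- make_binary(states[rep(1:4, 5), ])
  incumbent <- list(A = cand$A[[1]], B = cand$B[[1]],
                    Z = cand$Z[[which(vapply(cand$Z, `[[`, character(1),
                                             "expr") == "A or B")]])
  ls <- local_search(net, cand, incumbent, b)
  rs <- ls$rulespaces$Z
  expect_equal(length(rs$ers), 1)
  expect_equal(rs$candidates[[rs$ers]]$expr, "A and B")
  expect_equal(rs$min_error, 0)
  expect_true(rs$optimized)
})

test_that("constant data leaves the full candidate space as the ERS", {
  net <- signed_network(data.frame(from = c("A", "B"), to = "Z", sign = 1L))
  cand <- list(
    A = enumerate_candidates("A", character(0), integer(0)),
    B = enumerate_candidates("B", character(0), integer(0)),
    Z = enumerate_candidates("Z", c("A", "B"), c(1L, 1L))
  )
  # every cell all-ones: Z = 1 is a fixed point under all four candidates
  b <- make_binary(matrix(1L, 10, 3, dimnames = list(NULL, c("A", "B", "Z"))))
  incumbent <- lapply(cand, `[[`, 1)
  ls <- local_search(net, cand, incumbent, b)
  rs <- ls$rulespaces$Z
  expect_equal(length(rs$ers), rs$max_size)
  expect_false(rs$optimized)
  # tie order is expression-string lexicographic
  exprs <- vapply(rs$candidates[rs$ers], `[[`, character(1), "expr")
  expect_false(is.unsorted(exprs))
})

test_that("local-search minimum never exceeds the incumbent's node error", {
  scn <- synthetic_scenario(n_nodes = 7, n_cells = c(40, 40), seed = 21)
  asg <- cap_indegree(scn$network, scn$binary)
  candidates <- setNames(
    purrr::pmap(asg, function(target, regulators, signs) {
      enumerate_candidates(target, regulators, signs)
    }), asg$target)
  ga <- ga_search(candidates, scn$binary, n_gen = 10, seed = 3)
  nodes <- sort(names(candidates))
  E <- scn$binary$states[, nodes]
  compiled <- boolcell:::.compile_rules(ga$rules, nodes)
  inc_err <- boolcell:::cpp_eval_ruleset(E, compiled$regs, compiled$tts,
                                         100)$node_err
  ls <- local_search(scn$network, candidates, ga$rules, scn$binary)
  for (i in seq_along(nodes)) {
    expect_lte(ls$rulespaces[[nodes[i]]]$min_error, inc_err[i])
  }
})

test_that("infer_rules is reproducible and reports optimization flags", {
  scn <- synthetic_scenario(n_nodes = 6, n_cells = c(40, 40), seed = 9)
  f1 <- infer_rules(scn$network, scn$binary, seed = 4)
  f2 <- infer_rules(scn$network, scn$binary, seed = 4)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(write_rules_txt(f1$rules), write_rules_txt(f2$rules))
  td <- tidy(f1)
  expect_true(all(td$observed_ers >= 1))
  expect_true(all(td$observed_ers <= td$max_ers))
  expect_equal(f1$optimized, any(td$optimized))
  g <- glance(f1)
  expect_equal(g$n_nodes, 6)
  expect_equal(g$seed, 4)
})

test_that("rule recovery: true rules sit inside the ERS on noise-free data", {
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    scn <- synthetic_scenario(n_nodes = 8, n_cells = c(100, 100),
                              flip_noise = 0, seed = s)
    fit <- infer_rules(scn$network, scn$binary, seed = s)
    for (node in names(fit$rulespaces)) {
      rs <- fit$rulespaces[[node]]
      true_tt <- scn$true_rules[[node]]$tt
      ers_tts <- lapply(rs$candidates[rs$ers], `[[`, "tt")
      hits <- hits + any(vapply(ers_tts, identical, logical(1), true_tt))
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
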