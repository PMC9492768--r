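# Independent oracles used by the tests. These deliberately avoid the
# package's own enumeration/simulation code paths.

# Decomposition test for read-once AND/OR representability of a truth table
# with sign-constrained literals. `tt` is the output column over all 2^k
# input rows (first variable = least-significant bit); `signs[p]` is +1 if
# variable p may only appear as a plain literal, -1 if only negated.
# A function qualifies iff it is non-constant and recursively splits as
# g AND h or g OR h over a bipartition of its support, bottoming out in
# sign-consistent literals.
oracle_is_readonce <- function(tt, k, signs = rep(1L, k)) {
  X <- vapply(seq_len(k), function(p) {
    as.integer(bitwAnd(bitwShiftR(0:(2^k - 1), p - 1), 1L))
  }, integer(2^k))
  X <- matrix(X, ncol = k)

  check <- function(f, vars) {
    # restrict to the support within vars
    # rows with bit v = 0 and = 1 are aligned over the remaining bits, so a
    # variable is in the support iff flipping it ever changes the output
    support <- vars[vapply(vars, function(v) {
      any(f[X[, v] == 0] != f[X[, v] == 1])
    }, logical(1))]
    if (length(support) == 0) return(FALSE) # constant
    if (length(support) == 1) {
      v <- support
      f0 <- unique(f[X[, v] == 0])
      f1 <- unique(f[X[, v] == 1])
      if (length(f0) != 1 || length(f1) != 1) return(FALSE)
      if (f0 == 0 && f1 == 1) return(signs[v] == 1L) # plain literal
      if (f0 == 1 && f1 == 0) return(signs[v] == -1L) # negated literal
      return(FALSE)
    }
    rest <- support[-1]
    for (mask in 1:(2^length(rest) - 1)) {
      s2 <- rest[as.logical(bitwAnd(bitwShiftR(mask, seq_along(rest) - 1),
                                    1L))]
      s1 <- setdiff(support, s2)
      key1 <- apply(X[, s1, drop = FALSE], 1, paste, collapse = "")
      key2 <- apply(X[, s2, drop = FALSE], 1, paste, collapse = "")
      # f = g AND h: g(a) = any_b f(a,b), h(b) = any_a f(a,b)
      g_and <- ave(f, key1, FUN = max)
      h_and <- ave(f, key2, FUN = max)
      if (all(f == (g_and & h_and)) &&
          check(g_and, s1) && check(h_and, s2)) {
        return(TRUE)
      }
      # f = g OR h: g(a) = all_b f(a,b), h(b) = all_a f(a,b)
      g_or <- ave(f, key1, FUN = min)
      h_or <- ave(f, key2, FUN = min)
      if (all(f == (g_or | h_or)) &&
          check(g_or, s1) && check(h_or, s2)) {
        return(TRUE)
      }
    }
    FALSE
  }
  check(as.integer(tt), seq_len(k))
}

# Count all truth tables over k inputs that the decomposition oracle accepts.
oracle_readonce_count <- function(k, signs = rep(1L, k)) {
  n_tt <- 2^(2^k)
  hits <- 0L
  for (code in 0:(n_tt - 1)) {
    tt <- as.integer(bitwAnd(bitwShiftR(code, 0:(2^k - 1)), 1L))
    if (oracle_is_readonce(tt, k, signs)) hits <- hits + 1L
  }
  hits
}

# Plain-R synchronous simulation to an attractor: an oracle for the compiled
# trajectory code. Returns the cycle as a matrix of states (rows).
oracle_attractor <- function(state, rules, max_steps = 1000) {
  nodes <- sort(names(rules))
  s <- as.integer(state[nodes])
  seen <- list()
  traj <- list()
  for (t in seq_len(max_steps + 1)) {
    key <- paste(s, collapse = "")
    if (!is.null(seen[[key]])) {
      cyc <- do.call(rbind, traj[seen[[key]]:(t - 1)])
      colnames(cyc) <- nodes
      return(cyc)
    }
    seen[[key]] <- t
    traj[[t]] <- s
    s <- vapply(nodes, function(n) {
      r <- rules[[n]]
      vals <- s[match(r$genes, nodes)]
      r$tt[1L + sum(vals * 2L^(seq_along(vals) - 1L))]
    }, integer(1))
  }
  stop("oracle did not find a cycle")
}

# Exhaustive search for the minimum total fitting error over all rule-set
# combinations (oracle for GA + local search optimality at toy scale).
oracle_global_min_error <- function(candidates, binary, max_steps = 100) {
  nodes <- sort(names(candidates))
  sizes <- vapply(candidates[nodes], length, integer(1))
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    rules <- setNames(lapply(seq_along(nodes), function(j) {
      candidates[[nodes[j]]][[grid[i, j]]]
    }), nodes)
    err <- rule_fit_error(rules, binary, max_steps = max_steps)
    if (err < best) best <- err
  }
  best
}
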