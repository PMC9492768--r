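#' Boolean update rules
#'
#' A `boolean_rule` is one node's update function: a truth table over its
#' (at most 3) signed regulators together with a canonical read-once AND/OR
#' expression string. Truth-table bit indexing: regulators are in canonical
#' (alphabetical) order and the first regulator is the least-significant bit,
#' so row `i + 1` of the table is the output for the input assignment whose
#' bits are `i` written in binary.
#'
#' @name boolean_rule
#' @keywords internal
NULL

.new_rule <- function(target, genes, signs, tt, expr, n_and, n_lit) {
  structure(
    list(target = target, genes = genes, signs = as.integer(signs),
         tt = as.integer(tt), expr = expr, n_and = n_and, n_lit = n_lit),
    class = "boolean_rule"
  )
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(x$target, "=", x$expr, "\n")
  invisible(x)
}

# Internal expression node used during enumeration: keeps the truth table
# over the FULL regulator set plus a canonical string form. Same-operator
# children are flattened and operands sorted so "B and A" and "A and B"
# canonicalize identically.
.combine <- function(a, b, op) {
  tt <- if (op == "and") a$tt & b$tt else a$tt | b$tt
  items <- c(
    if (identical(a$op, op)) a$items else list(a),
    if (identical(b$op, op)) b$items else list(b)
  )
  strs <- vapply(items, function(it) {
    if (is.null(it$op) || it$op == "lit") it$expr else paste0("(", it$expr, ")")
  }, character(1))
  ord <- order(strs)
  list(
    tt = as.integer(tt), op = op, items = items[ord],
    expr = paste(strs[ord], collapse = paste0(" ", op, " ")),
    n_and = a$n_and + b$n_and + (op == "and"),
    n_lit = a$n_lit + b$n_lit
  )
}

#' Enumerate candidate Boolean rules for one node
#'
#' Generates every distinct truth table realizable by a read-once AND/OR
#' expression over a non-empty subset of the node's signed regulators (each
#' regulator used at most once; an activator contributes its state, an
#' inhibitor its negation). For in-degrees 1, 2, 3 this yields 1, 4, and 17
#' candidates for all-activator inputs; the non-read-once unate functions
#' (e.g. 3-input majority) are deliberately outside the grammar. A node with
#' no regulators gets the single identity rule (it holds its own state).
#'
#' @param target Target gene symbol.
#' @param regulators Character vector of regulator symbols, canonical
#'   (alphabetical) order.
#' @param signs Integer vector of +1/-1 matching `regulators`.
#' @return List of `boolean_rule`, sorted by (AND-term count, literal count,
#'   expression string); the first element is the "simplest" rule.
#' @export
#'
#' @examples
#' length(enumerate_candidates("C", c("A", "B"), c(1L, 1L)))  # 4
enumerate_candidates <- function(target, regulators, signs) {
  k <- length(regulators)
  if (k > 3) stop("more than 3 regulators; apply cap_indegree first",
                  call. = FALSE)
  if (k == 0) {
    return(list(.new_rule(target, target, 1L, c(0L, 1L), target, 0L, 1L)))
  }
  stopifnot(length(signs) == k, !is.unsorted(regulators),
            !anyDuplicated(regulators))
  # input assignments: row i+1 has bits of i, first regulator = LSB
  X <- vapply(seq_len(k), function(p) {
    as.integer(bitwAnd(bitwShiftR(0:(2^k - 1), p - 1), 1L))
  }, integer(2^k))
  X <- matrix(X, ncol = k)

  literal <- function(p) {
    neg <- signs[p] < 0
    list(
      tt = if (neg) 1L - X[, p] else X[, p],
      op = "lit", items = list(),
      expr = if (neg) paste("not", regulators[p]) else regulators[p],
      n_and = 0L, n_lit = 1L
    )
  }

  memo <- new.env(parent = emptyenv())
  readonce <- function(subset) { # subset: integer positions, sorted
    key <- paste(subset, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (length(subset) == 1) {
      list(literal(subset))
    } else {
      out <- list()
      # unordered binary partitions: first element stays in part 1
      rest <- subset[-1]
      for (mask in 1:(2^length(rest) - 1)) {
        s2 <- rest[as.logical(bitwAnd(bitwShiftR(mask, seq_along(rest) - 1), 1L))]
        s1 <- sort(c(subset[1], setdiff(rest, s2)))
        s2 <- sort(s2)
        for (a in readonce(s1)) for (b in readonce(s2)) {
          out[[length(out) + 1]] <- .combine(a, b, "and")
          out[[length(out) + 1]] <- .combine(a, b, "or")
        }
      }
      out
    }
    memo[[key]] <- res
    res
  }

  exprs <- list()
  for (mask in 1:(2^k - 1)) {
    subset <- which(as.logical(bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L)))
    exprs <- c(exprs, readonce(subset))
  }
  # dedup by truth table, keeping the simplest expression form
  best <- list()
  for (e in exprs) {
    key <- paste(e$tt, collapse = "")
    cur <- best[[key]]
    if (is.null(cur) ||
        e$n_and < cur$n_and ||
        (e$n_and == cur$n_and && e$n_lit < cur$n_lit) ||
        (e$n_and == cur$n_and && e$n_lit == cur$n_lit && e$expr < cur$expr)) {
      best[[key]] <- e
    }
  }
  rules <- lapply(best, function(e) {
    .new_rule(target, regulators, signs, e$tt, e$expr, e$n_and, e$n_lit)
  })
  ord <- order(
    vapply(rules, `[[`, integer(1), "n_and"),
    vapply(rules, `[[`, integer(1), "n_lit"),
    vapply(rules, `[[`, character(1), "expr")
  )
  unname(rules[ord])
}

#' Pick the simplest rule from a candidate list
#'
#' Simplicity = fewest AND operators, then fewest literals, then expression
#' string order. Candidate lists from [enumerate_candidates()] are already in
#' this order.
#' @param rules List of `boolean_rule`.
#' @return One `boolean_rule`.
#' @export
simplest_rule <- function(rules) {
  ord <- order(
    vapply(rules, `[[`, integer(1), "n_and"),
    vapply(rules, `[[`, integer(1), "n_lit"),
    vapply(rules, `[[`, character(1), "expr")
  )
  rules[[ord[1]]]
}

# Convert a named list of boolean_rule (one per node, alphabetical node
# order) into the index/tt lists the C++ simulator consumes.
.compile_rules <- function(rules, nodes) {
  idx <- setNames(seq_along(nodes), nodes)
  list(
    regs = lapply(nodes, function(n) unname(idx[rules[[n]]$genes]) - 1L),
    tts = lapply(nodes, function(n) rules[[n]]$tt)
  )
}

#' Serialize a rule set to readable text
#'
#' One line per node: `TARGET = (A or not B) and C`.
#' @param rules Named list of `boolean_rule`.
#' @param path Optional output file; if `NULL` the lines are returned.
#' @return Character vector of rule lines (invisibly when writing).
#' @export
write_rules_txt <- function(rules, path = NULL) {
  lines <- vapply(rules, function(r) paste(r$target, "=", r$expr),
                  character(1))
  lines <- unname(lines[order(names(rules))])
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
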