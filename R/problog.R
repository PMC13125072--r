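#' Probabilistic-logic programs with possible-world semantics
#'
#' A `prob_program` couples independent probabilistic facts (`0.9::fever.`)
#' with definite clauses over them (`call :- fever, low_spo2.`). Each fact is
#' true or false independently in a "possible world"; a query atom's marginal
#' is the total weight of worlds in which it is derivable by forward chaining.
#' Multiple clauses for one head combine as logical OR across worlds, so two
#' single-fact bodies with probabilities \eqn{p_1, p_2} give the noisy-or
#' marginal \eqn{1 - (1-p_1)(1-p_2)}.
#'
#' Programs must be negation-free and acyclic, facts and clause heads must be
#' disjoint, and every body atom must be declared (as a fact or some clause
#' head). These restrictions make exact inference straightforward and cover
#' every construct the monitoring use case needs.
#'
#' @param facts A data frame with columns `atom` (character) and `prob`
#'   (numeric in \[0, 1\]).
#' @param clauses A list of clauses, each a list with elements `head`
#'   (character scalar) and `body` (character vector, non-empty).
#' @return A `prob_program` object.
#' @examples
#' p <- prob_program(
#'   facts = tibble::tibble(atom = c("fever", "low_spo2"), prob = c(0.9, 1)),
#'   clauses = list(list(head = "call", body = c("fever", "low_spo2")))
#' )
#' query_marginal(p, "call")
#' @export
prob_program <- function(facts, clauses = list()) {
  facts <- tibble::as_tibble(facts)
  if (!all(c("atom", "prob") %in% names(facts))) {
    abort("`facts` needs columns `atom` and `prob`")
  }
  facts$atom <- as.character(facts$atom)
  if (anyDuplicated(facts$atom)) {
    abort(sprintf("duplicate fact atom: %s",
                  facts$atom[duplicated(facts$atom)][1]))
  }
  if (any(facts$prob < 0 | facts$prob > 1 | !is.finite(facts$prob))) {
    abort("fact probabilities must lie in [0, 1]")
  }
  clauses <- purrr::map(clauses, function(cl) {
    if (is.null(cl$head) || is.null(cl$body) || length(cl$body) == 0) {
      abort("each clause needs a `head` and a non-empty `body`")
    }
    list(head = as.character(cl$head), body = as.character(cl$body))
  })
  heads <- unique(purrr::map_chr(clauses, "head"))
  if (any(heads %in% facts$atom)) {
    abort(sprintf("clause head `%s` is also a probabilistic fact",
                  intersect(heads, facts$atom)[1]))
  }
  known <- c(facts$atom, heads)
  for (cl in clauses) {
    missing <- setdiff(cl$body, known)
    if (length(missing)) {
      abort(sprintf("clause for `%s` uses undeclared atom `%s`",
                    cl$head, missing[1]))
    }
  }
  order <- topo_order_heads(heads, clauses)  # errors on cycles
  structure(
    list(facts = facts, clauses = clauses, heads = heads, topo = order),
    class = "prob_program"
  )
}

# Kahn's algorithm over clause heads; head -> head edges only (facts are
# sources by construction). Errors if the dependency graph has a cycle.
topo_order_heads <- function(heads, clauses) {
  if (length(heads) == 0) return(character())
  deps <- purrr::map(heads, function(h) {
    body_atoms <- unlist(purrr::map(
      purrr::keep(clauses, ~ .x$head == h), "body"
    ))
    intersect(unique(body_atoms), heads)
  })
  names(deps) <- heads
  order <- character()
  remaining <- heads
  while (length(remaining)) {
    ready <- remaining[purrr::map_lgl(remaining, ~ length(setdiff(deps[[.x]], order)) == 0)]
    if (length(ready) == 0) {
      abort(sprintf("cyclic program: cycle through {%s}",
                    paste(remaining, collapse = ", ")))
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' @export
print.prob_program <- function(x, ...) {
  cat(sprintf("<prob_program: %d facts, %d clauses>\n",
              nrow(x$facts), length(x$clauses)))
  invisible(x)
}

#' Parse and render the mini program syntax
#'
#' One statement per line: probabilistic facts as `0.9::fever.`, clauses as
#' `call :- fever, low_spo2.`; `%` starts a comment; blank lines ignored.
#' `render_prob_program()` writes a program back to this syntax, and
#' `parse_prob_program(render_prob_program(p))` reproduces `p`.
#'
#' @param text Program text (single string or character vector of lines).
#' @return A [prob_program()].
#' @export
parse_prob_program <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("%.*$", "", lines)
  atom_re <- "[a-zA-Z_][a-zA-Z0-9_]*"
  facts <- list()
  clauses <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (!grepl("\\.$", line)) {
      abort(sprintf("line %d: statement must end with '.'", i))
    }
    stmt <- trimws(sub("\\.$", "", line))
    if (grepl("::", stmt, fixed = TRUE)) {
      m <- regmatches(stmt, regexec(
        paste0("^([0-9]*\\.?[0-9]+)\\s*::\\s*(", atom_re, ")$"), stmt))[[1]]
      if (length(m) == 0) abort(sprintf("line %d: malformed fact `%s`", i, stmt))
      facts[[length(facts) + 1]] <- list(atom = m[3], prob = as.numeric(m[2]))
    } else if (grepl(":-", stmt, fixed = TRUE)) {
      parts <- strsplit(stmt, ":-", fixed = TRUE)[[1]]
      if (length(parts) != 2) abort(sprintf("line %d: malformed clause", i))
      head <- trimws(parts[1])
      body <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
      ok <- grepl(paste0("^", atom_re, "$"), c(head, body))
      if (!all(ok)) abort(sprintf("line %d: malformed atom in clause", i))
      clauses[[length(clauses) + 1]] <- list(head = head, body = body)
    } else {
      abort(sprintf("line %d: expected `p::atom.` or `head :- body.`", i))
    }
  }
  prob_program(
    facts = tibble::tibble(
      atom = purrr::map_chr(facts, "atom"),
      prob = purrr::map_dbl(facts, "prob")
    ),
    clauses = clauses
  )
}

#' @rdname parse_prob_program
#' @param program A [prob_program()].
#' @export
render_prob_program <- function(program) {
  stopifnot(inherits(program, "prob_program"))
  fact_lines <- sprintf("%s::%s.", format(program$facts$prob, trim = TRUE),
                        program$facts$atom)
  clause_lines <- purrr::map_chr(program$clauses, function(cl) {
    sprintf("%s :- %s.", cl$head, paste(cl$body, collapse = ", "))
  })
  paste(c(fact_lines, clause_lines), collapse = "\n")
}

#' @rdname parse_prob_program
#' @param path Path to a program file.
#' @export
read_prob_program <- function(path) {
  parse_prob_program(readLines(path, warn = FALSE))
}

# Logical truth matrix (worlds x atoms) for all atoms, given a worlds x facts
# assignment matrix, chaining clause heads in topological order.
derive_truth <- function(program, fact_matrix) {
  truth <- as.data.frame(fact_matrix)
  names(truth) <- program$facts$atom
  for (h in program$topo) {
    cols <- purrr::map(purrr::keep(program$clauses, ~ .x$head == h),
                       function(cl) {
                         Reduce(`&`, truth[cl$body])
                       })
    truth[[h]] <- Reduce(`|`, cols)
  }
  truth
}

#' Enumerate possible worlds
#'
#' Expands all \eqn{2^{|facts|}} truth assignments of the probabilistic facts
#' together with their weights (products of fact probabilities); weights sum
#' to one. Serves as the brute-force oracle behind [query_marginal()].
#'
#' @param program A [prob_program()].
#' @param max_facts Enumeration cap (default 20); programs with more facts
#'   are refused.
#' @return A tibble with one logical column per fact atom and a `weight`
#'   column.
#' @export
enumerate_worlds <- function(program, max_facts = 20) {
  stopifnot(inherits(program, "prob_program"))
  n <- nrow(program$facts)
  if (n > max_facts) {
    abort(sprintf(
      "program has %d facts; enumeration is capped at %d (raise `max_facts` deliberately)",
      n, max_facts))
  }
  if (n == 0) {
    return(tibble::tibble(weight = 1))
  }
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- program$facts$atom
  w <- rep(1, nrow(grid))
  for (j in seq_len(n)) {
    p <- program$facts$prob[j]
    w <- w * ifelse(grid[[j]], p, 1 - p)
  }
  out <- tibble::as_tibble(grid)
  out$weight <- w
  out
}

#' Exact marginal query
#'
#' Returns the probability that `atom` is derivable under the independent-
#' facts possible-world semantics. Inference restricts the program to the
#' dependency cone of the queried atom before summing over assignments of the
#' relevant facts, so desk-scale programs with many irrelevant facts stay
#' cheap; results are exact and seed-independent.
#'
#' @param program A [prob_program()].
#' @param atom Atom to query.
#' @return The marginal probability, a number in \[0, 1\].
#' @examples
#' p <- parse_prob_program("0.5::wbc.\n0.6::tachypnea.\ncall :- wbc.\ncall :- tachypnea.")
#' query_marginal(p, "call")  # 1 - 0.5 * 0.4 = 0.8
#' @export
query_marginal <- function(program, atom) {
  stopifnot(inherits(program, "prob_program"))
  known <- c(program$facts$atom, program$heads)
  if (!atom %in% known) {
    abort(sprintf("unknown atom `%s`", atom))
  }
  cone <- dependency_cone(program, atom)
  sub <- prob_program(
    facts = program$facts[program$facts$atom %in% cone, , drop = FALSE],
    clauses = purrr::keep(program$clauses, ~ .x$head %in% cone)
  )
  if (atom %in% sub$facts$atom) {
    return(sub$facts$prob[sub$facts$atom == atom])
  }
  worlds <- enumerate_worlds(sub, max_facts = 30)
  fact_cols <- setdiff(names(worlds), "weight")
  truth <- derive_truth(sub, as.matrix(worlds[fact_cols]))
  sum(worlds$weight[truth[[atom]]])
}

# All atoms the query atom transitively depends on (including itself).
dependency_cone <- function(program, atom) {
  cone <- character()
  frontier <- atom
  while (length(frontier)) {
    cone <- union(cone, frontier)
    bodies <- unlist(purrr::map(
      purrr::keep(program$clauses, ~ .x$head %in% frontier), "body"))
    frontier <- setdiff(unique(bodies), cone)
  }
  cone
}
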