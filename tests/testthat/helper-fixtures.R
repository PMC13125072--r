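# Shared fixtures, built in code at test time.

small_cohort <- function(n_patients = 30, records = 12, seed = 42,
                         missing_rate = 0.03) {
  generate_cohort(cohort_config(n_patients = n_patients,
                                records_per_patient = records,
                                missing_rate = missing_rate, seed = seed))
}

# A single record tibble with explicit vitals in threshold units.
one_record <- function(...) {
  tibble::tibble(patient_id = "P0001", tick = 0L, ...)
}

# Random acyclic probabilistic-logic program with <= n_facts facts and a few
# layered clauses; used for the query-vs-enumeration oracle property.
random_program <- function(n_facts, n_clauses) {
  facts <- tibble::tibble(
    atom = paste0("f", seq_len(n_facts)),
    prob = round(runif(n_facts), 3)
  )
  atoms_so_far <- facts$atom
  clauses <- list()
  for (k in seq_len(n_clauses)) {
    head <- paste0("h", k)
    body <- sample(atoms_so_far, size = sample(1:min(3, length(atoms_so_far)), 1))
    clauses[[k]] <- list(head = head, body = body)
    atoms_so_far <- c(atoms_so_far, head)
  }
  prob_program(facts, clauses)
}

# Enumeration-based marginal, kept textually independent of query_marginal():
# walks every world row and re-derives the atom by naive repeated sweeps.
brute_marginal <- function(program, atom) {
  worlds <- enumerate_worlds(program)
  fact_atoms <- setdiff(names(worlds), "weight")
  total <- 0
  for (i in seq_len(nrow(worlds))) {
    true_atoms <- fact_atoms[unlist(worlds[i, fact_atoms])]
    repeat {
      added <- FALSE
      for (cl in program$clauses) {
        if (!(cl$head %in% true_atoms) && all(cl$body %in% true_atoms)) {
          true_atoms <- c(true_atoms, cl$head)
          added <- TRUE
        }
      }
      if (!added) break
    }
    if (atom %in% true_atoms) total <- total + worlds$weight[i]
  }
  total
}
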