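# Independent oracles used across the suite.

# Evaluate a statement by translating it to a base-R logical expression and
# eval()ing it -- a path entirely separate from evaluate_statement().
oracle_eval <- function(stmt, assignment) {
  to_expr <- function(s) {
    if (inherits(s, "helo_atom")) {
      return(sprintf("assignment[['%s']]", render_statement(s)))
    }
    parts <- vapply(s$operands, to_expr, character(1))
    switch(s$connective,
      AND = paste0("(", paste(parts, collapse = " & "), ")"),
      OR = paste0("(", paste(parts, collapse = " | "), ")"),
      NOT = paste0("(!", parts[[1]], ")"),
      IMPLIES = sprintf("((!%s) | %s)", parts[[1]], parts[[2]]),
      IFF = sprintf("(%s == %s)", parts[[1]], parts[[2]])
    )
  }
  eval(parse(text = to_expr(stmt)))
}

# Random propositional formula over the given atoms.
random_formula <- function(atoms, depth = 3) {
  if (depth == 0 || runif(1) < 0.35) {
    return(atoms[[sample.int(length(atoms), 1)]])
  }
  conn <- sample(c("AND", "OR", "NOT", "IMPLIES", "IFF"), 1)
  n_ops <- switch(conn, NOT = 1L, IMPLIES = 2L, IFF = 2L,
                  sample(2:3, 1))
  combine_statements(conn, lapply(seq_len(n_ops), function(i) {
    random_formula(atoms, depth - 1)
  }))
}

make_atoms <- function(n) {
  lapply(seq_len(n), function(i) {
    atomic_statement(paste0("p", i), entity("x"), entity("y"))
  })
}

# All 2^n truth assignments over the atoms, as named logical vectors.
all_assignments <- function(atoms) {
  keys <- vapply(atoms, render_statement, character(1))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(keys)))
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(as.logical(grid[i, ]), keys)
  })
}

# GP posterior by direct dense solve() -- independent of the package's
# Cholesky implementation.
gp_direct_oracle <- function(X, y, Xs, amplitude, lengthscale, noise_sd,
                             jitter) {
  X <- as.matrix(X); Xs <- as.matrix(Xs)
  kfun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    amplitude^2 * exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  K <- kfun(X, X) + diag(noise_sd^2 + jitter, nrow(X))
  Ks <- kfun(Xs, X)
  Kinv_y <- solve(K, y - mean(y))
  mu <- mean(y) + as.numeric(Ks %*% Kinv_y)
  var <- amplitude^2 - diag(Ks %*% solve(K, t(Ks)))
  list(mu = mu, sd = sqrt(pmax(var, 0)))
}

# Small random knowledge base for round-trip property tests.
random_kb <- function(seed) {
  set.seed(seed)
  kb <- kb_new()
  n_stmt <- sample(2:5, 1)
  ids <- paste0("s", seq_len(n_stmt))
  for (i in seq_len(n_stmt)) {
    atoms <- make_atoms(3)
    expr <- if (runif(1) < 0.5) atoms[[1]] else random_formula(atoms, 2)
    kb <- kb_add_statement(kb, research_statement(
      ids[i], expr, role = sample(c("research_hypothesis", "assumption",
                                    "conclusion", "scientific_law"), 1)
    ))
  }
  for (j in seq_len(sample(1:3, 1))) {
    ev_id <- paste0("e", j)
    kb <- kb_add_evidence(kb, evidence_item(
      ev_id, paste("evidence", j), sample(c("publication", "experiment"), 1),
      date = sprintf("20%02d-01-01", sample(10:20, 1))
    ))
    kb <- link_evidence(kb, sample(ids, 1), ev_id,
                        sample(c("supports", "refutes", "disputes"), 1))
  }
  for (m in seq_len(sample(1:4, 1))) {
    kb <- attach_probability(kb, sample(ids, 1), probability_record(
      runif(1), sample(c("prior", "posterior"), 1),
      sample(c("bayesian_inference", "expert_estimation", "induction"), 1),
      sprintf("20%02d-0%d-01", sample(10:20, 1), sample(1:9, 1))
    ))
  }
  if (n_stmt >= 2) {
    kb <- kb_add_homology(kb, ids[1], ids[2], weight = round(runif(1), 3))
    kb$hypothesis_sets <- list(hs = uniform_set(ids))
  }
  kb
}

# Random valid experiment likelihood table over n hypotheses x m outcomes.
random_experiment <- function(id, n, m, cost = runif(1, 0.5, 3)) {
  lik <- matrix(rgamma(n * m, 1), n, m)
  lik <- lik / rowSums(lik)
  experiment_spec(id, cost, paste0("o", seq_len(m)), lik)
}
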