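SUM_TOL <- 1e-9

new_hypothesis_set <- function(tbl) {
  structure(tbl, class = c("helo_hypothesis_set", class(tibble::tibble())))
}

#' Construct a hypothesis set
#'
#' A hypothesis set is a mutually exclusive, exhaustive collection of
#' hypotheses whose probabilities sum to 1. It is represented as a tibble
#' with columns `member` (statement ids) and `prob`; every engine operation
#' returns a new set, never mutates one in place.
#'
#' @param members Character vector of unique statement ids.
#' @param probs Numeric vector in \[0, 1\], same length, summing to 1 within
#'   `1e-9` (then renormalized exactly).
#' @return A `helo_hypothesis_set` tibble.
#' @export
hypothesis_set <- function(members, probs) {
  if (!length(members) || anyDuplicated(members)) {
    stop("`members` must be a non-empty vector of unique ids", call. = FALSE)
  }
  if (length(probs) != length(members)) {
    stop("`probs` must parallel `members`", call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > SUM_TOL) {
    stop(sprintf("probabilities must sum to 1 (got %.12f)", sum(probs)),
         call. = FALSE)
  }
  new_hypothesis_set(tibble::tibble(
    member = as.character(members),
    prob = as.numeric(probs) / sum(probs)
  ))
}

#' Uniform prior over a hypothesis set
#'
#' Assigns each of the n members the prior 1/n, as Adam did for its 8
#' abduced gene-deletion hypotheses.
#'
#' @param member_ids Character vector of unique statement ids.
#' @return A `helo_hypothesis_set`.
#' @examples
#' uniform_set(paste0("h", 1:8))  # each prior 1/8
#' @export
uniform_set <- function(member_ids) {
  hypothesis_set(member_ids, rep(1 / length(member_ids), length(member_ids)))
}

#' @export
print.helo_hypothesis_set <- function(x, ...) {
  cat("<hypothesis set> ", nrow(x), " members, entropy ",
      format(entropy_bits(x), digits = 4), " bits\n", sep = "")
  NextMethod()
}

check_set <- function(set) {
  stopifnot(inherits(set, "helo_hypothesis_set"))
  if (abs(sum(set$prob) - 1) > SUM_TOL) {
    stop("hypothesis set probabilities no longer sum to 1", call. = FALSE)
  }
  invisible(set)
}

#' Eliminate hypotheses and renormalize
#'
#' Removes the rejected members and renormalizes the survivors so their
#' probabilities again sum to 1; each cycle of rejection therefore raises
#' the probability of every surviving hypothesis. Eliminating all members,
#' or leaving only zero-probability survivors, is an error.
#'
#' @param set A `helo_hypothesis_set`.
#' @param rejected_ids Ids to remove (must be members; may be empty).
#' @return The surviving `helo_hypothesis_set`.
#' @examples
#' s <- hypothesis_set(c("a", "b", "c"), c(0.5, 0.3, 0.2))
#' eliminate(s, "a")  # b = 0.6, c = 0.4
#' @export
eliminate <- function(set, rejected_ids) {
  check_set(set)
  if (!all(rejected_ids %in% set$member)) {
    stop("rejected ids must be members of the set", call. = FALSE)
  }
  survivors <- set[!set$member %in% rejected_ids, ]
  if (!nrow(survivors)) {
    stop("cannot reject every hypothesis: empty hypothesis set", call. = FALSE)
  }
  mass <- sum(survivors$prob)
  if (mass <= 0) {
    stop("surviving hypotheses carry zero probability mass", call. = FALSE)
  }
  survivors$prob <- survivors$prob / mass
  new_hypothesis_set(survivors)
}

#' Specify an experiment with per-hypothesis outcome likelihoods
#'
#' @param id Experiment id.
#' @param cost Nonnegative cost (arbitrary currency units, e.g. the price of
#'   the compounds an auxotrophic experiment consumes).
#' @param outcomes Character vector of outcome labels.
#' @param likelihood Matrix of `P(outcome | hypothesis)`: one row per
#'   hypothesis (rownames are member ids), one column per outcome; each row
#'   sums to 1 within `1e-9`.
#' @return An object of class `helo_experiment`.
#' @export
experiment_spec <- function(id, cost, outcomes, likelihood) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(cost) || length(cost) != 1L || cost < 0) {
    stop("`cost` must be a nonnegative number", call. = FALSE)
  }
  likelihood <- as.matrix(likelihood)
  if (ncol(likelihood) != length(outcomes)) {
    stop("`likelihood` must have one column per outcome", call. = FALSE)
  }
  if (any(likelihood < 0) || any(likelihood > 1)) {
    stop("likelihoods must lie in [0, 1]", call. = FALSE)
  }
  bad <- abs(rowSums(likelihood) - 1) > SUM_TOL
  if (any(bad)) {
    stop("every hypothesis's likelihood row must sum to 1", call. = FALSE)
  }
  colnames(likelihood) <- outcomes
  structure(
    list(id = id, cost = as.numeric(cost), outcomes = as.character(outcomes),
         likelihood = likelihood),
    class = "helo_experiment"
  )
}

likelihood_for <- function(experiment, members) {
  lik <- experiment$likelihood
  if (!is.null(rownames(lik))) {
    if (!all(members %in% rownames(lik))) {
      stop("experiment likelihood table is missing rows for some set members",
           call. = FALSE)
    }
    lik <- lik[members, , drop = FALSE]
  } else if (nrow(lik) != length(members)) {
    stop("likelihood table rows do not match the hypothesis set", call. = FALSE)
  }
  lik
}

#' Bayesian update of a hypothesis set
#'
#' Applies Bayes' rule: each posterior is proportional to the prior times
#' the likelihood of the observed outcome under that hypothesis, then the
#' vector is renormalized to sum to 1. A zero likelihood eliminates the
#' hypothesis; elimination is the special case of indicator likelihoods.
#'
#' @param set A `helo_hypothesis_set`.
#' @param experiment A `helo_experiment` covering the set's members.
#' @param observed_outcome One of the experiment's outcome labels.
#' @return The posterior `helo_hypothesis_set`.
#' @export
bayes_update <- function(set, experiment, observed_outcome) {
  check_set(set)
  stopifnot(inherits(experiment, "helo_experiment"))
  if (!observed_outcome %in% experiment$outcomes) {
    stop(sprintf("`%s` is not an outcome of experiment `%s`",
                 observed_outcome, experiment$id), call. = FALSE)
  }
  lik <- unname(likelihood_for(experiment, set$member)[, observed_outcome])
  post <- set$prob * lik
  mass <- sum(post)
  if (mass <= 0) {
    stop("outcome impossible under every hypothesis", call. = FALSE)
  }
  out <- set
  out$prob <- post / mass
  new_hypothesis_set(out)
}

#' Shannon entropy of a hypothesis set, in bits
#'
#' Uses the convention `0 * log2(0) = 0`. A uniform 8-member set has 3 bits;
#' a degenerate set has 0.
#'
#' @param set A `helo_hypothesis_set` (or a bare probability vector).
#' @return Entropy in bits.
#' @export
entropy_bits <- function(set) {
  p <- if (is.numeric(set)) set else set$prob
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Expected information gain of an experiment
#'
#' The expected reduction in hypothesis-set entropy from observing the
#' experiment's outcome:
#' `H(set) - sum_o P(o) * H(set | o)` with `P(o) = sum_h P(h) P(o | h)`.
#' Always between 0 (an experiment whose likelihood rows are identical
#' across hypotheses tells us nothing) and `entropy_bits(set)`.
#'
#' @inheritParams bayes_update
#' @return Expected information gain in bits.
#' @export
expected_information_gain <- function(set, experiment) {
  check_set(set)
  stopifnot(inherits(experiment, "helo_experiment"))
  lik <- likelihood_for(experiment, set$member)
  p_out <- as.numeric(set$prob %*% lik)
  h_cond <- 0
  for (j in seq_along(p_out)) {
    if (p_out[j] <= 0) next
    post <- set$prob * lik[, j] / p_out[j]
    h_cond <- h_cond + p_out[j] * entropy_bits(post)
  }
  max(0, entropy_bits(set) - h_cond)
}

#' Choose the next experiment
#'
#' Scores each candidate by expected information gain per unit cost,
#' `gain / (cost + 1e-9)`, and returns the id of the best; ties are broken
#' by candidate order. This mirrors the three ingredients the Adam system
#' weighed — hypothesis probabilities, compound cost, and predicted
#' information gain — as a simple, replaceable policy.
#'
#' @param set A `helo_hypothesis_set`.
#' @param candidates Non-empty list of `helo_experiment` objects.
#' @return The chosen experiment's id (with the score vector as attribute
#'   `"scores"`).
#' @export
select_experiment <- function(set, candidates) {
  check_set(set)
  if (!length(candidates)) stop("no candidate experiments", call. = FALSE)
  stopifnot(all(vapply(candidates, inherits, logical(1), "helo_experiment")))
  scores <- vapply(candidates, function(ex) {
    expected_information_gain(set, ex) / (ex$cost + 1e-9)
  }, numeric(1))
  if (max(scores) <= 0) {
    warning("no candidate experiment is informative; returning the first",
            call. = FALSE)
  }
  best <- which.max(scores)
  structure(candidates[[best]]$id, scores = scores)
}
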