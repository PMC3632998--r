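test_that("uniform_set assigns 1/n and rejects degenerate input", {
  s8 <- uniform_set(paste0("h", 1:8))
  expect_equal(s8$prob, rep(1 / 8, 8))
  expect_equal(sum(s8$prob), 1)

  s1 <- uniform_set("only")
  expect_equal(s1$prob, 1)

  s3 <- uniform_set(c("a", "b", "c"))
  expect_equal(sum(s3$prob), 1)

  expect_error(uniform_set(character()), "non-empty")
  expect_error(uniform_set(c("a", "a")), "unique")
  expect_error(hypothesis_set(c("a", "b"), c(0.9, 0.2)), "sum to 1")
})

test_that("eliminate renormalizes survivors and raises their probabilities", {
  s <- hypothesis_set(c("a", "b", "c"), c(0.5, 0.3, 0.2))
  out <- eliminate(s, "a")
  expect_equal(out$prob, c(0.3 / 0.5, 0.2 / 0.5))  # hand renormalization

  # rejecting none returns an identical set
  expect_equal(eliminate(s, character())$prob, s$prob)

  # survivors strictly increase when positive mass was rejected
  expect_true(all(out$prob > s$prob[s$member %in% out$member]))

  expect_error(eliminate(s, c("a", "b", "c")), "empty hypothesis set")
  expect_error(eliminate(s, "zzz"), "members")
})

test_that("bayes_update is proportional-to-likelihood with renormalization", {
  s <- hypothesis_set(c("a", "b"), c(0.5, 0.5))
  ex <- experiment_spec("e", 1, c("pos", "neg"),
                        rbind(a = c(0.8, 0.2), b = c(0.2, 0.8)))
  # hand Bayes arithmetic: priors (.5,.5), likelihoods (.8,.2) -> (.8,.2)
  expect_equal(bayes_update(s, ex, "pos")$prob, c(0.8, 0.2))

  # equal likelihoods leave the set unchanged
  flat <- experiment_spec("f", 1, c("pos", "neg"),
                          rbind(a = c(0.5, 0.5), b = c(0.5, 0.5)))
  expect_equal(bayes_update(s, flat, "pos")$prob, s$prob)

  # zero likelihood eliminates the hypothesis
  kill <- experiment_spec("k", 1, c("pos", "neg"),
                          rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(bayes_update(s, kill, "pos")$prob, c(1, 0))

  expect_error(bayes_update(s, ex, "maybe"), "not an outcome")
  s10 <- hypothesis_set(c("a", "b"), c(1, 0))
  expect_error(bayes_update(s10, kill, "neg"), "impossible under every")
})

test_that("eliminate equals bayes_update with indicator likelihoods", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    p <- rgamma(n, 1); p <- p / sum(p)
    ids <- paste0("h", seq_len(n))
    s <- hypothesis_set(ids, p)
    rejected <- sample(ids, sample(seq_len(n - 1), 1))
    lik <- cbind(consistent = as.numeric(!ids %in% rejected),
                 inconsistent = as.numeric(ids %in% rejected))
    rownames(lik) <- ids
    ex <- experiment_spec("ind", 1, colnames(lik), lik)
    via_bayes <- bayes_update(s, ex, "consistent")
    via_elim <- eliminate(s, rejected)
    kept <- via_bayes[via_bayes$member %in% via_elim$member, ]
    expect_equal(kept$prob, via_elim$prob, tolerance = 1e-12)
    expect_equal(sum(via_bayes$prob), 1, tolerance = 1e-9)
  }
})

test_that("entropy_bits handles uniform, degenerate and mixed sets", {
  expect_equal(entropy_bits(uniform_set(paste0("h", 1:8))), 3)
  expect_equal(entropy_bits(hypothesis_set(c("a", "b"), c(1, 0))), 0)
  expect_equal(entropy_bits(c(0.5, 0.25, 0.25)), 1.5)
})

test_that("expected information gain matches brute-force outcome enumeration", {
  # uninformative experiment: identical rows, zero gain
  s <- uniform_set(c("a", "b", "c"))
  same <- experiment_spec("u", 1, c("x", "y"),
                          matrix(rep(c(0.3, 0.7), each = 3), 3))
  expect_equal(expected_information_gain(s, same), 0)

  # perfectly discriminating binary experiment on uniform-2: 1 bit
  s2 <- uniform_set(c("a", "b"))
  disc <- experiment_spec("d", 1, c("x", "y"), rbind(c(1, 0), c(0, 1)))
  expect_equal(expected_information_gain(s2, disc), 1)

  # random 3x2 tables vs brute-force oracle
  set.seed(13)
  for (rep in 1:30) {
    p <- rgamma(3, 1); p <- p / sum(p)
    s3 <- hypothesis_set(c("a", "b", "c"), p)
    ex <- random_experiment("r", 3, 2)
    # oracle: enumerate outcomes, compute posterior entropy directly
    gain_oracle <- local({
      H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
      lik <- ex$likelihood
      po <- as.numeric(p %*% lik)
      H(p) - sum(vapply(seq_along(po), function(j) {
        po[j] * H(p * lik[, j] / po[j])
      }, numeric(1)))
    })
    gain <- expected_information_gain(s3, ex)
    expect_equal(gain, gain_oracle, tolerance = 1e-12)
    expect_gte(gain, 0)
    expect_lte(gain, entropy_bits(s3) + 1e-12)
  }
})

test_that("select_experiment maximizes gain per unit cost with order tie-breaks", {
  s <- uniform_set(c("a", "b"))
  disc <- function(id, cost) {
    experiment_spec(id, cost, c("x", "y"), rbind(c(1, 0), c(0, 1)))
  }
  # equal gain, costs 1 vs 2: cheaper chosen
  expect_equal(as.character(select_experiment(s, list(disc("pricey", 2),
                                                      disc("cheap", 1)))),
               "cheap")

  # zero-gain candidates: first wins, with a warning
  flat <- function(id) {
    experiment_spec(id, 1, c("x", "y"), rbind(c(0.5, 0.5), c(0.5, 0.5)))
  }
  expect_warning(choice <- select_experiment(s, list(flat("f1"), flat("f2"))),
                 "informative")
  expect_equal(as.character(choice), "f1")

  expect_error(select_experiment(s, list()), "no candidate")

  # randomized pools vs exhaustive scoring oracle
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(2:5, 1)
    p <- rgamma(n, 1); p <- p / sum(p)
    set_r <- hypothesis_set(paste0("h", seq_len(n)), p)
    pool <- lapply(1:4, function(i) random_experiment(paste0("e", i), n, 3))
    scores <- vapply(pool, function(ex) {
      expected_information_gain(set_r, ex) / (ex$cost + 1e-9)
    }, numeric(1))
    expect_equal(as.character(select_experiment(set_r, pool)),
                 pool[[which.max(scores)]]$id)
  }
})

test_that("probabilities sum to 1 after arbitrary operation sequences", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    s <- uniform_set(paste0("h", seq_len(n)))
    for (step in seq_len(sample(1:6, 1))) {
      if (nrow(s) > 1 && runif(1) < 0.4) {
        s <- eliminate(s, sample(s$member, sample(nrow(s) - 1, 1)))
      } else {
        s <- bayes_update(s, random_experiment("e", nrow(s), sample(2:4, 1)),
                          observed_outcome = paste0("o", 1))
      }
      expect_equal(sum(s$prob), 1, tolerance = 1e-9)
      expect_true(all(s$prob >= 0 & s$prob <= 1))
    }
  }
})
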