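seeded_kb <- function() {
  kb <- kb_new()
  kb <- kb_add_statement(kb, research_statement(
    "h1", atomic_statement("regulates", "SIRT1", "human_life_span")))
  kb <- kb_add_statement(kb, research_statement(
    "h2", atomic_statement("regulates", "sir-2.1", "nematode_life_span")))
  kb
}

test_that("probability records validate bounds, method and timestamp", {
  expect_error(probability_record(1.2, "posterior", "expert_estimation",
                                  "2001-01-01"), "\\[0, 1\\]")
  expect_error(probability_record(-0.1, "prior", "deduction", "2001-01-01"),
               "\\[0, 1\\]")
  expect_error(probability_record(0.5, "posterior", "wishful_thinking",
                                  "2001-01-01"))
  expect_error(probability_record(0.5, "posterior", "deduction",
                                  "sometime in spring"), "timestamp")
  rec <- probability_record(0.8, "posterior", "expert_estimation",
                            "2001-03-08")
  expect_s3_class(rec, "helo_probability_record")
})

test_that("trajectories are append-only, timestamp-sorted, with stable tie order", {
  kb <- seeded_kb()
  expect_error(attach_probability(kb, "nope", probability_record(
    0.5, "prior", "deduction", "2001-01-01")), "unknown statement")

  kb <- attach_probability(kb, "h1", probability_record(
    0.8, "posterior", "expert_estimation", "2001-03-08"))
  kb <- attach_probability(kb, "h1", probability_record(
    0.5, "prior", "expert_estimation", "2000-01-01"))
  traj <- probability_trajectory(kb, "h1")
  expect_equal(traj$value, c(0.5, 0.8))  # sorted despite insertion order

  # identical timestamps: both kept, insertion order preserved
  kb <- attach_probability(kb, "h1", probability_record(
    0.55, "posterior", "bayesian_inference", "2011-09-22"))
  kb <- attach_probability(kb, "h1", probability_record(
    0.60, "posterior", "bayesian_inference", "2011-09-22"))
  traj <- probability_trajectory(kb, "h1")
  expect_equal(nrow(traj), 4)
  expect_equal(utils::tail(traj$value, 2), c(0.55, 0.60))

  # earlier records never mutated by later attachments
  expect_equal(traj$value[1:2], c(0.5, 0.8))
})

test_that("current_probability returns the latest record (full-sort oracle) or NULL", {
  kb <- seeded_kb()
  expect_null(current_probability(kb, "h1"))

  set.seed(3)
  stamps <- sprintf("20%02d-%02d-%02d", sample(1:20), sample(1:12, 20, TRUE),
                    sample(1:28, 20, TRUE))
  vals <- runif(20)
  for (i in seq_along(stamps)) {
    kb <- attach_probability(kb, "h1", probability_record(
      vals[i], "posterior", "bayesian_inference", stamps[i]))
  }
  # oracle: sort all records by parsed time, take the last
  ord <- order(as.POSIXct(stamps, tz = "UTC", format = "%Y-%m-%d"),
               seq_along(stamps))
  expect_equal(current_probability(kb, "h1")$value, vals[ord[20]])

  # `at` cutoff returns the latest record not after the cutoff
  expect_equal(current_probability(kb, "h1", at = stamps[ord[5]])$value,
               vals[ord[5]])
})

test_that("evidence links validate endpoints, group by relation, and are idempotent", {
  kb <- seeded_kb()
  kb <- kb_add_evidence(kb, evidence_item(
    "burnett_2011", "no longevity boost in worm and fly", "publication",
    "2011-09-22"))
  kb <- kb_add_evidence(kb, evidence_item(
    "kanfi_2012", "Sirt6 extends male mouse lifespan", "publication",
    "2012-02-23"))

  expect_error(link_evidence(kb, "h1", "missing_ev", "supports"),
               "unknown evidence")
  expect_error(link_evidence(kb, "ghost", "burnett_2011", "refutes"),
               "unknown statement")
  expect_error(link_evidence(kb, "h1", "burnett_2011", "contradicts"))

  kb <- link_evidence(kb, "h1", "burnett_2011", "refutes")
  kb <- link_evidence(kb, "h1", "kanfi_2012", "supports")
  kb <- link_evidence(kb, "h1", "burnett_2011", "refutes")  # duplicate
  ev <- kb_evidence_for(kb, "h1")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$evidence_id[ev$relation == "refutes"], "burnett_2011")
  expect_equal(ev$evidence_id[ev$relation == "supports"], "kanfi_2012")
})

test_that("homological_update applies linear transfer with clipping in the right direction", {
  base_kb <- function(w, p_src, p_tgt) {
    kb <- seeded_kb()
    kb <- kb_add_homology(kb, "h2", "h1", weight = w)
    kb <- attach_probability(kb, "h2", probability_record(
      p_src, "prior", "expert_estimation", "2000-01-01"))
    kb <- attach_probability(kb, "h1", probability_record(
      p_tgt, "prior", "expert_estimation", "2000-01-01"))
    kb
  }

  # weight 0: a new record is appended but the value is unchanged
  kb <- homological_update(base_kb(0, 0.9, 0.8), "h2", "h1", 0.1, "2011-01-01")
  expect_equal(current_probability(kb, "h1")$value, 0.8)
  expect_equal(nrow(probability_trajectory(kb, "h1")), 2)

  # hand arithmetic: weight 1, source 0.9 -> 0.4, target 0.8 -> 0.3
  kb <- homological_update(base_kb(1, 0.9, 0.8), "h2", "h1", 0.4, "2011-01-01")
  cur <- current_probability(kb, "h1")
  expect_equal(cur$value, 0.3)
  expect_equal(cur$method, "homological_inference")
  # the source's new value is recorded too
  expect_equal(current_probability(kb, "h2")$value, 0.4)

  # increase with weight 0.5: target strictly increases, clipped at 1
  kb <- homological_update(base_kb(0.5, 0.2, 0.95), "h2", "h1", 0.9,
                           "2012-01-01")
  expect_equal(current_probability(kb, "h1")$value, 1)  # 0.95 + 0.35 clipped

  # missing priors must be seeded first
  kb0 <- kb_add_homology(seeded_kb(), "h2", "h1")
  expect_error(homological_update(kb0, "h2", "h1", 0.5, "2011-01-01"),
               "seeded|prior")

  # self-links and out-of-range weights rejected at link creation
  expect_error(kb_add_homology(seeded_kb(), "h1", "h1"), "self-link")
  expect_error(kb_add_homology(seeded_kb(), "h2", "h1", weight = 1.5),
               "\\[0, 1\\]")
})

test_that("any operation sequence keeps stored probabilities in [0,1] and sign of transfer matches source", {
  set.seed(19)
  for (rep in 1:25) {
    w <- runif(1)
    p_src <- runif(1)
    p_tgt <- runif(1)
    new_src <- runif(1)
    kb <- seeded_kb()
    kb <- kb_add_homology(kb, "h2", "h1", weight = w)
    kb <- attach_probability(kb, "h2", probability_record(
      p_src, "prior", "expert_estimation", "2000-01-01"))
    kb <- attach_probability(kb, "h1", probability_record(
      p_tgt, "prior", "expert_estimation", "2000-01-01"))
    kb <- homological_update(kb, "h2", "h1", new_src, "2011-01-01")
    expect_true(all(kb$prob_records$value >= 0 & kb$prob_records$value <= 1))
    new_tgt <- current_probability(kb, "h1")$value
    clipped <- (p_tgt + w * (new_src - p_src)) != new_tgt
    if (w > 0 && !clipped) {
      expect_equal(sign(new_tgt - p_tgt), sign(new_src - p_src))
    }
  }
})
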