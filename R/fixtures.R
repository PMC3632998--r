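#' Specify a synthetic compound library
#'
#' The generator emulates a screening library with a smooth latent
#' activity surface: features are drawn uniformly on the unit hypercube and
#' the latent activity is a baseline plus a sum of Gaussian bumps,
#' `latent(x) = baseline + sum_j height_j * exp(-||x - center_j||^2 / (2 * width_j^2))`,
#' observed with additive Normal noise. Values are on a pGI50-like scale
#' (higher = more potent).
#'
#' @param n_compounds Library size, `>= 1`.
#' @param n_features Feature dimension.
#' @param centers Matrix of bump centers (one row per bump, `n_features`
#'   columns).
#' @param widths,heights Per-bump width and height vectors.
#' @param baseline Additive baseline activity.
#' @param noise_sd Measurement noise standard deviation, `>= 0`.
#' @param seed Integer seed; identical specs yield bit-identical libraries.
#' @return A list of class `helo_library_spec`.
#' @export
library_spec <- function(n_compounds = 500, n_features = 2,
                         centers = default_bumps(n_features)$centers,
                         widths = default_bumps(n_features)$widths,
                         heights = default_bumps(n_features)$heights,
                         baseline = 4, noise_sd = 0.1, seed = 1) {
  centers <- matrix(as.numeric(centers), ncol = n_features)
  stopifnot(n_compounds >= 1, n_features >= 1, noise_sd >= 0,
            length(widths) == nrow(centers),
            length(heights) == nrow(centers),
            all(widths > 0))
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_features = as.integer(n_features),
         centers = centers, widths = as.numeric(widths),
         heights = as.numeric(heights), baseline = as.numeric(baseline),
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "helo_library_spec"
  )
}

default_bumps <- function(n_features) {
  centers <- rbind(
    c(0.20, 0.25), c(0.75, 0.70), c(0.55, 0.15)
  )[, seq_len(min(2, n_features)), drop = FALSE]
  if (n_features > 2) {
    centers <- cbind(centers, matrix(0.5, nrow(centers), n_features - 2))
  }
  if (n_features == 1) centers <- centers[, 1, drop = FALSE]
  list(centers = centers, widths = c(0.12, 0.10, 0.16),
       heights = c(3.0, 4.5, 2.5))
}

#' Default synthetic library: a desk-scale screening analogue
#'
#' 500 compounds in 2 feature dimensions, 3 Gaussian activity bumps over a
#' baseline of 4 (activities span roughly 4-8.5, pGI50-like), noise
#' standard deviation 0.1. On libraries of this shape, informed selection
#' strategies separate clearly from random selection within a budget of 60
#' measurements averaged over 20 repetitions.
#'
#' @param seed Integer seed.
#' @return A `helo_library_spec`.
#' @export
default_library_spec <- function(seed = 1) library_spec(seed = seed)

latent_activity <- function(spec, X) {
  out <- rep(spec$baseline, nrow(X))
  for (j in seq_len(nrow(spec$centers))) {
    d2 <- rowSums((X - matrix(spec$centers[j, ], nrow(X), ncol(X),
                              byrow = TRUE))^2)
    out <- out + spec$heights[j] * exp(-0.5 * d2 / spec$widths[j]^2)
  }
  out
}

#' Generate a synthetic compound library
#'
#' Draws features uniformly on `[0, 1]^d` from the seeded generator and
#' sets each compound's activity to the latent surface value plus
#' `Normal(0, noise_sd)` noise. With `noise_sd = 0` the activity equals the
#' latent function exactly. The same spec (including seed) always yields a
#' bit-identical library.
#'
#' @param spec A [library_spec()].
#' @return A tibble of class `helo_library` with columns `compound_id`,
#'   `f1`..`fd`, and `activity`; the noiseless latent values are kept in
#'   attribute `"latent"` and the spec in attribute `"spec"`.
#' @examples
#' lib <- gen_compound_library(library_spec(n_compounds = 50, seed = 7))
#' @export
gen_compound_library <- function(spec) {
  stopifnot(inherits(spec, "helo_library_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  d <- spec$n_features
  X <- matrix(stats::runif(n * d), n, d)
  latent <- latent_activity(spec, X)
  noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
  lib <- tibble::tibble(compound_id = sprintf("C%05d", seq_len(n)))
  feats <- as.data.frame(X)
  names(feats) <- paste0("f", seq_len(d))
  lib <- dplyr::bind_cols(lib, tibble::as_tibble(feats))
  lib$activity <- latent + noise
  attr(lib, "latent") <- latent
  attr(lib, "spec") <- spec
  class(lib) <- c("helo_library", class(lib))
  lib
}

# ---- Adam / AAA pathway fixture ---------------------------------------

aaa_genes <- c("ARO1", "ARO2", "ARO3", "ARO4", "ARO7", "TRP2", "TYR1", "PHA2")

#' The yeast aromatic amino acid pathway elimination fixture
#'
#' Encodes the Robot Scientist worked example: 8 abduced hypotheses about
#' which gene of the S. cerevisiae aromatic amino acid (AAA) pathway has
#' been deleted in a mutant strain, each with uniform prior 1/8, plus a
#' scripted schedule of auxotrophic-experiment cycles. Each cycle rejects
#' one or more hypotheses and renormalizes the survivors; after the full
#' replay exactly one hypothesis remains at posterior 1 and all others at
#' 0. The particular genes rejected per cycle are illustrative.
#'
#' @return A list with the uniform `set` (a [hypothesis_set()]), the
#'   elimination `cycles` (list of id vectors rejected per cycle), and a
#'   knowledge base `kb` holding the 8 hypothesis statements with their
#'   1/8 priors (method `abduction`).
#' @examples
#' fx <- aaa_fixture()
#' replay_elimination(fx$set, fx$cycles)$history
#' @export
aaa_fixture <- function() {
  ids <- paste0("aaa_h_", aaa_genes)
  kb <- kb_new()
  strain <- entity("aaa_mutant_strain", label = "AAA pathway deletion mutant")
  for (i in seq_along(aaa_genes)) {
    g <- aaa_genes[i]
    stmt <- research_statement(
      ids[i],
      atomic_statement("deleted", entity(g, source_ontology = "SGD"), strain),
      role = "research_hypothesis",
      free_text = sprintf("The gene %s has been deleted from the mutant strain.", g)
    )
    kb <- kb_add_statement(kb, stmt)
    kb <- attach_probability(kb, ids[i], probability_record(
      1 / 8, "prior", "abduction", "2009-01-01",
      procedure = "uniform prior over the abduced hypothesis set"
    ))
  }
  set <- uniform_set(ids)
  kb$hypothesis_sets <- list(aaa = set)
  cycles <- list(
    paste0("aaa_h_", c("ARO3", "ARO4", "PHA2")),
    paste0("aaa_h_", c("TRP2", "TYR1")),
    paste0("aaa_h_", c("ARO7", "ARO2"))
  )
  list(set = set, cycles = cycles, kb = kb)
}

#' Replay a scripted elimination schedule
#'
#' Applies [eliminate()] cycle by cycle, recording every member's
#' probability after each cycle. When a knowledge base is supplied, each
#' surviving member gains a posterior record (method `deduction`) and each
#' rejected member a posterior record of 0, so statement trajectories
#' mirror the engine's updates. Replays are deterministic.
#'
#' @param set A `helo_hypothesis_set`.
#' @param cycles List of character vectors: the member ids rejected in each
#'   cycle.
#' @param kb Optional `helo_kb` containing the member statements.
#' @param start_date ISO date of the first cycle; subsequent cycles advance
#'   by one day.
#' @return A list with `history` (tibble: `cycle`, `member`, `prob`; cycle
#'   0 is the initial set, eliminated members appear with probability 0),
#'   the final `set`, and the updated `kb` (or `NULL`).
#' @export
replay_elimination <- function(set, cycles, kb = NULL,
                               start_date = "2009-02-01") {
  check_set(set)
  all_members <- set$member
  snapshot <- function(cycle, s) {
    probs <- stats::setNames(rep(0, length(all_members)), all_members)
    probs[s$member] <- s$prob
    tibble::tibble(cycle = cycle, member = all_members,
                   prob = unname(probs))
  }
  history <- list(snapshot(0L, set))
  day0 <- as.Date(start_date)
  for (i in seq_along(cycles)) {
    set <- eliminate(set, cycles[[i]])
    history[[i + 1L]] <- snapshot(i, set)
    if (!is.null(kb)) {
      ts <- format(day0 + (i - 1), "%Y-%m-%d")
      rejected_before <- unlist(cycles[seq_len(i - 1)])
      for (m in all_members) {
        if (m %in% rejected_before) next  # trajectory already closed at 0
        p <- if (m %in% set$member) set$prob[set$member == m] else 0
        kb <- attach_probability(kb, m, probability_record(
          p, "posterior", "deduction", ts,
          procedure = sprintf("elimination cycle %d", i)
        ))
      }
    }
  }
  list(history = dplyr::bind_rows(history), set = set, kb = kb)
}

# ---- sirtuin fixture ---------------------------------------------------

#' The sirtuin lifespan worked example
#'
#' Builds and (by default) replays the knowledge base tracking the
#' hypothesis h1 "SIRT1 regulates human life span" together with its
#' model-organism counterparts: h2 (C. elegans sir-2.1), h3 (yeast SIR2)
#' and h4 (mouse Sirt6), connected to h1 by homology links of weight 0.5.
#'
#' The replayed timeline: priors seeded in 2000; the 2001 Tissenbaum &
#' Guarente nematode result raises h2 and leads to an expert posterior of
#' 0.8 on h1; literature-mining counts place the yeast hypothesis h3 near
#' 1.0 (method `statistical_calculation`); the 2011 Burnett report refutes
#' h2, and homological transfer lowers P(h1); the 2012 Kanfi report that
#' Sirt6 extends lifespan in male mice supports h4, and homological
#' transfer raises P(h1) again. Only the 0.8 value is anchored; the 2011
#' and 2012 steps are direction-of-change updates.
#'
#' @param replay If `FALSE`, return the knowledge base with only the
#'   seeded year-2000 priors (no evidence events applied).
#' @return A `helo_kb`.
#' @examples
#' kb <- sirtuin_fixture()
#' probability_trajectory(kb, "h1")
#' @export
sirtuin_fixture <- function(replay = TRUE) {
  kb <- kb_new()
  lifespan <- list(
    h1 = c("SIRT1", "human_life_span", "Homo sapiens"),
    h2 = c("sir-2.1", "nematode_life_span", "Caenorhabditis elegans"),
    h3 = c("SIR2", "yeast_life_span", "Saccharomyces cerevisiae"),
    h4 = c("Sirt6", "mouse_life_span", "Mus musculus")
  )
  for (id in names(lifespan)) {
    gene <- lifespan[[id]][1]
    span <- lifespan[[id]][2]
    org <- lifespan[[id]][3]
    kb <- kb_add_statement(kb, research_statement(
      id,
      atomic_statement("regulates", entity(gene), entity(span)),
      role = "research_hypothesis",
      free_text = sprintf("%s regulates life span in %s.", gene, org)
    ))
  }
  for (src in c("h2", "h3", "h4")) {
    kb <- kb_add_homology(kb, src, "h1", weight = 0.5)
  }

  kb <- kb_add_evidence(kb, evidence_item(
    "tissenbaum_guarente_2001",
    "Increased dosage of the SIRT1 homolog extends lifespan in C. elegans.",
    "publication", "2001-03-08"
  ))
  kb <- kb_add_evidence(kb, evidence_item(
    "yeast70_literature_counts",
    "Literature-mining counts: SIR2 dominates aging-related yeast gene mentions.",
    "database", "2010-06-01"
  ))
  kb <- kb_add_evidence(kb, evidence_item(
    "burnett_2011",
    "Overexpressing the sirtuin gene in C. elegans and D. melanogaster did not boost longevity.",
    "publication", "2011-09-22"
  ))
  kb <- kb_add_evidence(kb, evidence_item(
    "kanfi_2012",
    "The sirtuin Sirt6 regulates lifespan in male mice.",
    "publication", "2012-02-23"
  ))

  # year-2000 priors, before the evidence timeline starts
  seed_priors <- c(h1 = 0.5, h2 = 0.6, h3 = 0.9, h4 = 0.5)
  for (id in names(seed_priors)) {
    kb <- attach_probability(kb, id, probability_record(
      seed_priors[[id]], "prior", "expert_estimation", "2000-01-01"
    ))
  }
  if (!replay) return(kb)

  # 2001: nematode lifespan extension; expert places h1 at 0.8
  kb <- link_evidence(kb, "h2", "tissenbaum_guarente_2001", "supports")
  kb <- link_evidence(kb, "h1", "tissenbaum_guarente_2001", "supports")
  kb <- attach_probability(kb, "h2", probability_record(
    0.85, "posterior", "bayesian_inference", "2001-03-08",
    source = "tissenbaum_guarente_2001"
  ))
  kb <- attach_probability(kb, "h1", probability_record(
    0.8, "posterior", "expert_estimation", "2001-03-08",
    source = "tissenbaum_guarente_2001"
  ))

  # yeast hypothesis pinned near 1 by literature counts
  kb <- link_evidence(kb, "h3", "yeast70_literature_counts", "supports")
  kb <- attach_probability(kb, "h3", probability_record(
    0.97, "posterior", "statistical_calculation", "2010-06-01",
    procedure = "aging-sentence keyword counts over a literature database",
    source = "yeast70_literature_counts"
  ))

  # 2011: refutation in worm and fly lowers h2, and h1 with it
  kb <- link_evidence(kb, "h2", "burnett_2011", "refutes")
  kb <- link_evidence(kb, "h1", "burnett_2011", "refutes")
  kb <- homological_update(kb, "h2", "h1", 0.35, "2011-09-22",
                           evidence_id = "burnett_2011",
                           source_method = "bayesian_inference")

  # 2012: male-mouse support raises h4, and h1 with it
  kb <- link_evidence(kb, "h4", "kanfi_2012", "supports")
  kb <- link_evidence(kb, "h1", "kanfi_2012", "supports")
  kb <- homological_update(kb, "h4", "h1", 0.8, "2012-02-23",
                           evidence_id = "kanfi_2012",
                           source_method = "bayesian_inference")
  kb
}
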