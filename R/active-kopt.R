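helo_strategies <- c("optimistic", "mpi", "mei", "random")

library_feature_cols <- function(library) {
  stopifnot(is.data.frame(library))
  cols <- setdiff(names(library), c("compound_id", "activity"))
  cols <- cols[vapply(library[cols], is.numeric, logical(1))]
  if (!length(cols)) stop("library has no numeric feature columns", call. = FALSE)
  cols
}

library_matrix <- function(library) {
  X <- as.matrix(library[library_feature_cols(library)])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("feature rows must be finite", call. = FALSE)
  X
}

kth_best <- function(values, k) {
  sorted <- sort(values, decreasing = TRUE)
  sorted[min(k, length(sorted))]
}

#' Run active k-optimization over a compound library
#'
#' Reproduces the active-learning screening loop: bootstrap by measuring
#' `bootstrap_n` randomly chosen compounds, then repeatedly (i) fit the GP
#' surrogate to all measurements so far, (ii) predict the activity of every
#' untested compound, (iii) score candidates with the selection strategy,
#' and (iv) measure the top-scoring compound, until `budget` compounds have
#' been measured. The `random` strategy never consults the surrogate. The
#' aim is to find the k best-performing compounds with as few measurements
#' as possible.
#'
#' Each post-bootstrap iteration records, for the selected compound, the
#' probability `P1` of beating the best of the bootstrap sample, the
#' probability `P2` of beating the current k-th best measurement, and the
#' highest such probability `P3` over all remaining untested compounds.
#' `y_kbest` is the k-th largest measured activity so far (bootstrap
#' included); a compound is never measured twice.
#'
#' @param library A compound library: data frame with `compound_id`, numeric
#'   feature columns, and an `activity` column used as the measurement
#'   oracle (see [gen_compound_library()]).
#' @param strategy One of `"optimistic"`, `"mpi"`, `"mei"`, `"random"`.
#' @param k Number of top compounds sought (default 1).
#' @param budget Total number of measurements, `>= bootstrap_n` and at most
#'   the library size.
#' @param bootstrap_n Size of the random bootstrap sample (default 10).
#' @param seed Integer seed; fixes the bootstrap and any random picks, so
#'   runs are reproducible and strategies sharing a seed share a bootstrap.
#' @param beta Optimism multiplier for the confidence-bound strategy.
#' @param control [gp_control()] hyperparameters for the surrogate.
#' @return An object of class `helo_active_run`: a list with the
#'   per-iteration tibble `iterations` (`n_measured`, `selected_id`,
#'   `acq_score`, `P1`, `P2`, `P3`, `best_so_far`, `kbest_so_far`), the
#'   bootstrap sample, the measured tibble, and the sorted `top_k`
#'   activities found.
#' @examples
#' lib <- gen_compound_library(library_spec(n_compounds = 80, seed = 1))
#' run <- run_active_optimization(lib, "mei", budget = 20, seed = 1)
#' glance(run)
#' @export
run_active_optimization <- function(library, strategy, k = 1, budget,
                                    bootstrap_n = 10, seed,
                                    beta = 2, control = gp_control()) {
  strategy <- match.arg(strategy, helo_strategies)
  X <- library_matrix(library)
  ids <- as.character(library$compound_id)
  y <- as.numeric(library$activity)
  n <- nrow(X)
  if (budget < bootstrap_n) {
    stop("`budget` must be at least `bootstrap_n`", call. = FALSE)
  }
  if (budget > n) {
    stop("`budget` exceeds the library size", call. = FALSE)
  }
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))

  measured <- sample.int(n, bootstrap_n)
  boot_kbest <- kth_best(y[measured], k)

  records <- vector("list", budget - bootstrap_n)
  step <- 0L
  while (length(measured) < budget) {
    step <- step + 1L
    untested <- setdiff(seq_len(n), measured)
    y_meas <- y[measured]
    y_kbest <- kth_best(y_meas, k)

    if (strategy == "random") {
      sel <- untested[sample.int(length(untested), 1L)]
      score <- NA_real_
      p1 <- p2 <- p3 <- NA_real_
    } else {
      gp <- fit_surrogate(X[measured, , drop = FALSE], y_meas, control)
      pred <- stats::predict(gp, X[untested, , drop = FALSE])
      score_all <- switch(strategy,
        mpi = acq_mpi(pred$.pred_mean, pred$.pred_sd, y_kbest),
        mei = acq_mei(pred$.pred_mean, pred$.pred_sd, y_kbest),
        optimistic = acq_optimistic(pred$.pred_mean, pred$.pred_sd, beta)
      )
      j <- which.max(score_all)  # first maximum = lowest compound index
      sel <- untested[j]
      score <- score_all[j]
      p_beat_kbest <- acq_mpi(pred$.pred_mean, pred$.pred_sd, y_kbest)
      p1 <- acq_mpi(pred$.pred_mean[j], pred$.pred_sd[j], boot_kbest)
      p2 <- p_beat_kbest[j]
      p3 <- max(p_beat_kbest)
    }

    measured <- c(measured, sel)
    records[[step]] <- tibble::tibble(
      n_measured = length(measured), selected_id = ids[sel],
      acq_score = score, P1 = p1, P2 = p2, P3 = p3,
      measured_activity = y[sel],
      best_so_far = max(y[measured]),
      kbest_so_far = kth_best(y[measured], k)
    )
  }

  structure(
    list(
      iterations = dplyr::bind_rows(records),
      bootstrap = tibble::tibble(compound_id = ids[measured[seq_len(bootstrap_n)]],
                                 activity = y[measured[seq_len(bootstrap_n)]]),
      measured = tibble::tibble(compound_id = ids[measured],
                                activity = y[measured]),
      top_k = sort(y[measured], decreasing = TRUE)[seq_len(min(k, budget))],
      strategy = strategy, k = k, budget = budget,
      bootstrap_n = bootstrap_n, seed = as.integer(seed)
    ),
    class = "helo_active_run"
  )
}

#' @export
print.helo_active_run <- function(x, ...) {
  cat("<active k-optimization run> strategy:", x$strategy,
      " k:", x$k, " budget:", x$budget, "\n",
      " best found:", format(max(x$measured$activity), digits = 5),
      " k-th best:", format(x$top_k[length(x$top_k)], digits = 5), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.helo_active_run <- function(x, ...) x$iterations

#' @exportS3Method
glance.helo_active_run <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy, k = x$k, budget = x$budget,
    bootstrap_n = x$bootstrap_n, seed = x$seed,
    best_found = max(x$measured$activity),
    kth_best_found = x$top_k[length(x$top_k)]
  )
}

#' Compare selection strategies over repeated runs
#'
#' Runs each strategy on freshly generated synthetic libraries (one per
#' repetition; the library and bootstrap seeds are shared across strategies
#' within a repetition, so strategies differ only in their selection rule)
#' and summarizes the best-found and k-th-best-found activity at each
#' budget checkpoint, averaged over repetitions.
#'
#' @param spec A [library_spec()] describing the synthetic libraries; its
#'   `seed` field is replaced per repetition.
#' @param strategies Character vector of strategies to compare.
#' @param k,budget,bootstrap_n,beta,control Passed to
#'   [run_active_optimization()].
#' @param reps Number of repetitions (default 20).
#' @param seed Master seed from which per-repetition seeds are drawn.
#' @param checkpoints Measurement counts at which performance is recorded;
#'   defaults to every 10 measurements from `bootstrap_n` up to `budget`.
#' @return An object of class `helo_strategy_comparison`: `results` holds
#'   one row per strategy x repetition x checkpoint; `summary` the mean and
#'   standard deviation per strategy and checkpoint.
#' @export
compare_strategies <- function(spec = default_library_spec(),
                               strategies = helo_strategies,
                               k = 1, budget = 60, bootstrap_n = 10,
                               reps = 20, seed = 1, checkpoints = NULL,
                               beta = 2, control = gp_control()) {
  strategies <- match.arg(strategies, helo_strategies, several.ok = TRUE)
  stopifnot(reps >= 1)
  if (is.null(checkpoints)) {
    checkpoints <- unique(c(seq(bootstrap_n, budget, by = 10), budget))
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, reps)

  rows <- purrr::map(seq_len(reps), function(r) {
    rspec <- spec
    rspec$seed <- rep_seeds[r]
    lib <- gen_compound_library(rspec)
    purrr::map(strategies, function(strat) {
      run <- run_active_optimization(lib, strat, k = k, budget = budget,
                                     bootstrap_n = bootstrap_n,
                                     seed = rep_seeds[r], beta = beta,
                                     control = control)
      boot_best <- max(run$bootstrap$activity)
      boot_kbest <- kth_best(run$bootstrap$activity, k)
      purrr::map(checkpoints, function(cp) {
        upto <- run$iterations[run$iterations$n_measured <= cp, ]
        tibble::tibble(
          strategy = strat, rep = r, checkpoint = cp,
          best_found = if (nrow(upto)) max(boot_best, upto$best_so_far)
                       else boot_best,
          kth_best_found = if (nrow(upto)) upto$kbest_so_far[nrow(upto)]
                           else boot_kbest
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summary <- rows |>
    dplyr::group_by(.data$strategy, .data$checkpoint) |>
    dplyr::summarise(
      mean_best = mean(.data$best_found),
      sd_best = stats::sd(.data$best_found),
      mean_kth_best = mean(.data$kth_best_found),
      sd_kth_best = stats::sd(.data$kth_best_found),
      .groups = "drop"
    )

  structure(
    list(results = rows, summary = summary, strategies = strategies,
         k = k, budget = budget, bootstrap_n = bootstrap_n, reps = reps,
         seed = as.integer(seed), spec = spec),
    class = "helo_strategy_comparison"
  )
}

#' @export
print.helo_strategy_comparison <- function(x, ...) {
  cat("<strategy comparison>", x$reps, "repetitions, budget", x$budget,
      ", k =", x$k, "\n")
  final <- x$summary[x$summary$checkpoint == max(x$summary$checkpoint), ]
  print(final[order(-final$mean_best), c("strategy", "mean_best", "sd_best")])
  invisible(x)
}

#' @exportS3Method
tidy.helo_strategy_comparison <- function(x, ...) x$summary

#' @exportS3Method
glance.helo_strategy_comparison <- function(x, ...) {
  final <- x$summary[x$summary$checkpoint == max(x$summary$checkpoint), ]
  tibble::tibble(
    reps = x$reps, budget = x$budget, k = x$k,
    best_strategy = final$strategy[which.max(final$mean_best)],
    worst_strategy = final$strategy[which.min(final$mean_best)]
  )
}
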