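KB_SCHEMA_VERSION <- "1.0"

helo_class_for_role <- c(
  research_hypothesis = "research hypothesis",
  assumption = "assumption",
  conclusion = "conclusion",
  scientific_law = "scientific law",
  theorem = "theorem"
)

helo_class_for_kind <- c(
  prior = "prior probability",
  posterior = "posterior probability"
)

helo_class_for_method <- c(
  bayesian_inference = "Bayesian inference",
  expert_estimation = "expert estimation",
  statistical_calculation = "statistical calculation",
  deduction = "deduction",
  abduction = "abduction",
  induction = "induction",
  homological_inference = "homological inference"
)

helo_class_for_relation <- c(
  supports = "HAS-SUPPORTING-EVIDENCE",
  refutes = "HAS-REFUTING-EVIDENCE",
  disputes = "HAS-DISPUTING-EVIDENCE"
)

known_helo_classes <- unname(c(
  helo_class_for_role, helo_class_for_kind, helo_class_for_method,
  helo_class_for_relation,
  "entity", "evidence", "homological inference", "hypotheses set"
))

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

#' Export a knowledge base to JSON
#'
#' Serializes the knowledge base as a JSON document with arrays
#' `entities`, `statements`, `evidence`, `links`, `homology_links`,
#' `probability_records` and `hypothesis_sets`. Each record carries a
#' `helo_class` string naming its ontology class (e.g. "prior
#' probability", "expert estimation") for alignment with the HELO
#' vocabulary, and the document carries an `@context` pointing at the HELO
#' source repository. Key order is fixed, so exporting the same knowledge
#' base twice yields byte-identical text, and
#' `import_kb(export_kb(kb))` reproduces the knowledge base.
#'
#' @param kb A `helo_kb`.
#' @param path Optional file path; when given, the JSON is written there
#'   (invisibly returning the text).
#' @return JSON text (class `json`).
#' @export
export_kb <- function(kb, path = NULL) {
  stopifnot(inherits(kb, "helo_kb"))
  doc <- list(
    `@context` = "https://github.com/larisa-soldatova/HELO",
    schema_version = KB_SCHEMA_VERSION,
    entities = purrr::pmap(kb$entities, function(id, label, source_ontology,
                                                 parent_id) {
      drop_nulls(list(id = id, label = label,
                      source_ontology = na_to_null(source_ontology),
                      parent_id = na_to_null(parent_id),
                      helo_class = "entity"))
    }),
    statements = purrr::pmap(kb$statements, function(id, role, free_text,
                                                     expression) {
      drop_nulls(list(id = id, role = role,
                      expression = render_statement(expression),
                      free_text = na_to_null(free_text),
                      helo_class = unname(helo_class_for_role[role])))
    }),
    evidence = purrr::pmap(kb$evidence, function(id, description,
                                                 source_type, date) {
      drop_nulls(list(id = id, description = description,
                      source_type = source_type, date = na_to_null(date),
                      helo_class = "evidence"))
    }),
    links = purrr::pmap(kb$links, function(statement_id, evidence_id,
                                           relation) {
      list(statement_id = statement_id, evidence_id = evidence_id,
           relation = relation,
           helo_class = unname(helo_class_for_relation[relation]))
    }),
    homology_links = purrr::pmap(kb$homology_links, function(source_id,
                                                             target_id,
                                                             weight) {
      list(source_id = source_id, target_id = target_id, weight = weight,
           helo_class = "homological inference")
    }),
    probability_records = purrr::pmap(
      kb$prob_records,
      function(statement_id, value, kind, method, procedure, timestamp,
               source, seq) {
        drop_nulls(list(statement_id = statement_id, value = value,
                        kind = kind, method = method,
                        procedure = na_to_null(procedure),
                        timestamp = timestamp, source = na_to_null(source),
                        helo_class = unname(helo_class_for_kind[kind]),
                        estimation_class = unname(helo_class_for_method[method])))
      }),
    hypothesis_sets = purrr::imap(kb$hypothesis_sets, function(set, nm) {
      list(id = nm, members = as.list(set$member),
           probs = as.list(set$prob), helo_class = "hypotheses set")
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

field <- function(obj, name, default = NULL) {
  if (is.null(obj[[name]])) default else obj[[name]]
}

check_helo_class <- function(obj, what) {
  cls <- field(obj, "helo_class")
  if (!is.null(cls) && !cls %in% known_helo_classes) {
    warning(sprintf("unknown helo_class `%s` on a %s record; kept as-is",
                    cls, what), call. = FALSE)
  }
}

#' Import a knowledge base from JSON
#'
#' Reads a document produced by [export_kb()] (a file path or JSON text)
#' and rebuilds the knowledge base through the package's validating
#' constructors, so every module invariant — probability bounds, known
#' relations and estimation methods, referential integrity of every id —
#' is enforced on load. A dangling reference or an out-of-range
#' probability is a hard error naming the offending value; an unknown
#' `helo_class` only raises a warning and the object is kept.
#'
#' @param x File path or JSON character scalar.
#' @return A `helo_kb`.
#' @export
import_kb <- function(x) {
  txt <- if (length(x) == 1L && !grepl("^[[:space:]]*\\{", x) &&
             file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) {
    stop("knowledge-base document lacks `schema_version`", call. = FALSE)
  }
  kb <- kb_new()
  for (e in doc$entities %||% list()) {
    check_helo_class(e, "entity")
    kb <- kb_add_entity(kb, entity(e$id, label = field(e, "label", e$id),
                                   source_ontology = field(e, "source_ontology"),
                                   parent_id = field(e, "parent_id")))
  }
  for (s in doc$statements %||% list()) {
    check_helo_class(s, "statement")
    kb <- kb_add_statement(kb, research_statement(
      s$id, parse_statement(s$expression, entities = kb$entities),
      role = s$role, free_text = field(s, "free_text")
    ))
  }
  for (ev in doc$evidence %||% list()) {
    check_helo_class(ev, "evidence")
    kb <- kb_add_evidence(kb, evidence_item(
      ev$id, ev$description, source_type = ev$source_type,
      date = field(ev, "date")
    ))
  }
  for (l in doc$links %||% list()) {
    check_helo_class(l, "evidence link")
    kb <- link_evidence(kb, l$statement_id, l$evidence_id, l$relation)
  }
  for (h in doc$homology_links %||% list()) {
    check_helo_class(h, "homology link")
    kb <- kb_add_homology(kb, h$source_id, h$target_id, weight = h$weight)
  }
  for (p in doc$probability_records %||% list()) {
    check_helo_class(p, "probability")
    kb <- attach_probability(kb, p$statement_id, probability_record(
      p$value, p$kind, p$method, p$timestamp,
      procedure = field(p, "procedure"), source = field(p, "source")
    ))
  }
  sets <- list()
  for (hs in doc$hypothesis_sets %||% list()) {
    check_helo_class(hs, "hypothesis set")
    members <- unlist(hs$members)
    if (!all(members %in% kb$statements$id)) {
      missing <- setdiff(members, kb$statements$id)
      stop(sprintf("hypothesis set `%s` references unknown statement `%s`",
                   hs$id, missing[1]), call. = FALSE)
    }
    sets[[hs$id]] <- hypothesis_set(members, unlist(hs$probs))
  }
  kb$hypothesis_sets <- sets
  kb
}

#' Compare two knowledge bases for equality
#'
#' Equality is structural: identical entity/evidence/link tables, equal
#' statements (compared by rendering), identical probability trajectories,
#' and identical hypothesis sets. Used to verify serialization
#' round-trips.
#'
#' @param a,b `helo_kb` objects.
#' @return Logical scalar.
#' @export
kb_equal <- function(a, b) {
  stopifnot(inherits(a, "helo_kb"), inherits(b, "helo_kb"))
  render_all <- function(kb) {
    s <- kb$statements
    s$expression <- vapply(s$expression, render_statement, character(1))
    s
  }
  probs <- function(kb) dplyr::select(kb$prob_records, -"seq")
  sets_equal <- function(x, y) {
    identical(sort(names(x)), sort(names(y))) &&
      all(vapply(names(x), function(nm) {
        isTRUE(all.equal(as.data.frame(x[[nm]]), as.data.frame(y[[nm]])))
      }, logical(1)))
  }
  identical(as.data.frame(a$entities), as.data.frame(b$entities)) &&
    identical(as.data.frame(render_all(a)), as.data.frame(render_all(b))) &&
    identical(as.data.frame(a$evidence), as.data.frame(b$evidence)) &&
    identical(as.data.frame(a$links), as.data.frame(b$links)) &&
    isTRUE(all.equal(as.data.frame(a$homology_links),
                     as.data.frame(b$homology_links))) &&
    isTRUE(all.equal(as.data.frame(probs(a)), as.data.frame(probs(b)))) &&
    sets_equal(a$hypothesis_sets, b$hypothesis_sets)
}

#' Read a compound library from CSV/TSV
#'
#' Expects a header with `compound_id`, numeric feature columns, and
#' optionally an `activity` column with measured activities.
#'
#' @param path File path; tab- or comma-separated is inferred from the
#'   extension (`.tsv`/`.tab` vs anything else).
#' @return A tibble of class `helo_library`.
#' @export
read_compound_library <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"compound_id" %in% names(df)) {
    stop("library file must have a `compound_id` column", call. = FALSE)
  }
  lib <- tibble::as_tibble(df)
  library_matrix(lib)  # validates numeric, finite features
  class(lib) <- c("helo_library", class(lib))
  lib
}

#' Write a compound library to CSV
#'
#' @param library A compound library data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(library, path) {
  utils::write.csv(as.data.frame(library), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export an active run's iteration table
#'
#' Writes one row per post-bootstrap iteration with the columns
#' `n_measured`, `P1`, `P2`, `P3`, `selected_id` (plus acquisition score
#' and running bests) as CSV, or the whole run as JSON.
#'
#' @param run A `helo_active_run`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_active_run <- function(run, path, format = c("csv", "json")) {
  stopifnot(inherits(run, "helo_active_run"))
  format <- match.arg(format)
  if (format == "csv") {
    cols <- c("n_measured", "P1", "P2", "P3", "selected_id", "acq_score",
              "measured_activity", "best_so_far", "kbest_so_far")
    utils::write.csv(as.data.frame(run$iterations[cols]), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    out <- list(
      strategy = run$strategy, k = run$k, budget = run$budget,
      bootstrap_n = run$bootstrap_n, seed = run$seed,
      iterations = run$iterations, top_k = run$top_k
    )
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, dataframe = "rows"), path)
  }
  invisible(path)
}
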