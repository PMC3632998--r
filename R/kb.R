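helo_methods <- c(
  "bayesian_inference", "expert_estimation", "statistical_calculation",
  "deduction", "abduction", "induction", "homological_inference"
)

helo_relations <- c("supports", "refutes", "disputes")

helo_source_types <- c("publication", "experiment", "database", "expert")

#' Create an empty knowledge base
#'
#' A knowledge base holds entities, research statements, evidence items,
#' statement-evidence links, homology links between hypotheses, probability
#' records, and named hypothesis sets. All tables are tibbles; statement
#' expressions live in a list-column. Every mutating operation returns a new
#' knowledge base; probability trajectories are append-only.
#'
#' @return An object of class `helo_kb`.
#' @examples
#' kb <- kb_new()
#' @export
kb_new <- function() {
  structure(
    list(
      entities = tibble::tibble(
        id = character(), label = character(),
        source_ontology = character(), parent_id = character()
      ),
      statements = tibble::tibble(
        id = character(), role = character(), free_text = character(),
        expression = list()
      ),
      evidence = tibble::tibble(
        id = character(), description = character(),
        source_type = character(), date = character()
      ),
      links = tibble::tibble(
        statement_id = character(), evidence_id = character(),
        relation = character()
      ),
      homology_links = tibble::tibble(
        source_id = character(), target_id = character(), weight = double()
      ),
      prob_records = tibble::tibble(
        statement_id = character(), value = double(), kind = character(),
        method = character(), procedure = character(),
        timestamp = character(), source = character(), seq = integer()
      ),
      hypothesis_sets = list()
    ),
    class = "helo_kb"
  )
}

#' @export
print.helo_kb <- function(x, ...) {
  cat("<helo knowledge base>\n")
  cat("  statements:         ", nrow(x$statements), "\n")
  cat("  entities:           ", nrow(x$entities), "\n")
  cat("  evidence items:     ", nrow(x$evidence), "\n")
  cat("  evidence links:     ", nrow(x$links), "\n")
  cat("  homology links:     ", nrow(x$homology_links), "\n")
  cat("  probability records:", nrow(x$prob_records), "\n")
  cat("  hypothesis sets:    ", length(x$hypothesis_sets), "\n")
  invisible(x)
}

parse_timestamp <- function(x) {
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    out <- as.POSIXct(x, tz = "UTC", format = fmt)
    if (!any(is.na(out))) return(out)
  }
  stop(sprintf("unparseable ISO-8601 timestamp: `%s`",
               paste(x[is.na(out)], collapse = ", ")), call. = FALSE)
}

#' Add an entity to a knowledge base
#'
#' @param kb A `helo_kb`.
#' @param ent A `helo_entity`.
#' @return The updated knowledge base.
#' @export
kb_add_entity <- function(kb, ent) {
  stopifnot(inherits(kb, "helo_kb"), inherits(ent, "helo_entity"))
  if (ent$id %in% kb$entities$id) {
    stop(sprintf("entity id `%s` already present", ent$id), call. = FALSE)
  }
  if (!is.null(ent$parent_id)) {
    # walk the existing parent chain to guard against cycles
    seen <- ent$id
    cur <- ent$parent_id
    while (!is.null(cur)) {
      if (cur %in% seen) {
        stop(sprintf("entity `%s` would create a parent cycle", ent$id),
             call. = FALSE)
      }
      seen <- c(seen, cur)
      i <- match(cur, kb$entities$id)
      cur <- if (is.na(i)) NULL else na_to_null(kb$entities$parent_id[[i]])
    }
  }
  kb$entities <- dplyr::bind_rows(kb$entities, tibble::tibble(
    id = ent$id, label = ent$label %||% ent$id,
    source_ontology = ent$source_ontology %||% NA_character_,
    parent_id = ent$parent_id %||% NA_character_
  ))
  kb
}

register_statement_entities <- function(kb, stmt) {
  for (atom in statement_atoms(stmt)) {
    for (ent in list(atom$subject, atom$object)) {
      if (!ent$id %in% kb$entities$id) kb <- kb_add_entity(kb, ent)
    }
  }
  kb
}

#' Add a research statement to a knowledge base
#'
#' Entities occurring in the statement's atoms are auto-registered.
#'
#' @param kb A `helo_kb`.
#' @param stmt A `helo_research_statement`, or a `helo_statement` when `id`
#'   and `role` are given separately.
#' @param id,role,free_text Used only when `stmt` is a bare logical
#'   expression.
#' @return The updated knowledge base.
#' @export
kb_add_statement <- function(kb, stmt, id = NULL,
                             role = "research_hypothesis", free_text = NULL) {
  stopifnot(inherits(kb, "helo_kb"))
  if (inherits(stmt, "helo_statement")) {
    if (is.null(id)) stop("`id` required for a bare expression", call. = FALSE)
    stmt <- research_statement(id, stmt, role = role, free_text = free_text)
  }
  stopifnot(inherits(stmt, "helo_research_statement"))
  if (stmt$id %in% kb$statements$id) {
    stop(sprintf("statement id `%s` already present", stmt$id), call. = FALSE)
  }
  kb <- register_statement_entities(kb, stmt$expression)
  kb$statements <- dplyr::bind_rows(kb$statements, tibble::tibble(
    id = stmt$id, role = stmt$role,
    free_text = stmt$free_text %||% NA_character_,
    expression = list(stmt$expression)
  ))
  kb
}

#' Create an evidence item
#'
#' @param id Unique id.
#' @param description What the evidence reports.
#' @param source_type One of `"publication"`, `"experiment"`, `"database"`,
#'   `"expert"`.
#' @param date ISO-8601 date.
#' @return An object of class `helo_evidence`.
#' @export
evidence_item <- function(id, description, source_type = "publication",
                          date = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  source_type <- match.arg(source_type, helo_source_types)
  if (!is.null(date)) parse_timestamp(date)
  structure(
    list(id = id, description = description, source_type = source_type,
         date = date),
    class = "helo_evidence"
  )
}

#' Add an evidence item to a knowledge base
#'
#' @param kb A `helo_kb`.
#' @param ev A `helo_evidence`.
#' @return The updated knowledge base.
#' @export
kb_add_evidence <- function(kb, ev) {
  stopifnot(inherits(kb, "helo_kb"), inherits(ev, "helo_evidence"))
  if (ev$id %in% kb$evidence$id) {
    stop(sprintf("evidence id `%s` already present", ev$id), call. = FALSE)
  }
  kb$evidence <- dplyr::bind_rows(kb$evidence, tibble::tibble(
    id = ev$id, description = ev$description, source_type = ev$source_type,
    date = ev$date %||% NA_character_
  ))
  kb
}

#' Construct a validated probability record
#'
#' A probability record is a timestamped value in \[0, 1\] with a kind
#' (prior or posterior), the method by which it was estimated, an optional
#' procedure note, and an optional source evidence id.
#'
#' @param value Probability in \[0, 1\].
#' @param kind `"prior"` or `"posterior"`.
#' @param method One of the estimation methods: `"bayesian_inference"`,
#'   `"expert_estimation"`, `"statistical_calculation"`, `"deduction"`,
#'   `"abduction"`, `"induction"`, `"homological_inference"`.
#' @param timestamp ISO-8601 date or date-time.
#' @param procedure Optional note on the algorithm or implementation used.
#' @param source Optional evidence item id that triggered the record.
#' @return An object of class `helo_probability_record`.
#' @export
probability_record <- function(value, kind, method, timestamp,
                               procedure = NULL, source = NULL) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop("probability `value` must be a number in [0, 1]", call. = FALSE)
  }
  kind <- match.arg(kind, c("prior", "posterior"))
  method <- match.arg(method, helo_methods)
  parse_timestamp(timestamp)
  structure(
    list(value = as.numeric(value), kind = kind, method = method,
         timestamp = timestamp, procedure = procedure, source = source),
    class = "helo_probability_record"
  )
}

#' Attach a probability record to a statement
#'
#' Appends the record to the statement's trajectory; nothing is ever
#' overwritten. The trajectory is kept sorted by timestamp, with ties broken
#' by insertion order, so the full history of how a statement's probability
#' changed — and by what inference — is preserved.
#'
#' @param kb A `helo_kb`.
#' @param statement_id Id of a statement in `kb`.
#' @param record A `helo_probability_record`.
#' @return The updated knowledge base.
#' @export
attach_probability <- function(kb, statement_id, record) {
  stopifnot(inherits(kb, "helo_kb"),
            inherits(record, "helo_probability_record"))
  if (!statement_id %in% kb$statements$id) {
    stop(sprintf("unknown statement `%s`", statement_id), call. = FALSE)
  }
  if (!is.null(record$source) && !record$source %in% kb$evidence$id) {
    stop(sprintf("record source `%s` is not a known evidence id",
                 record$source), call. = FALSE)
  }
  nxt <- if (nrow(kb$prob_records)) max(kb$prob_records$seq) + 1L else 1L
  kb$prob_records <- dplyr::bind_rows(kb$prob_records, tibble::tibble(
    statement_id = statement_id, value = record$value, kind = record$kind,
    method = record$method, procedure = record$procedure %||% NA_character_,
    timestamp = record$timestamp, source = record$source %||% NA_character_,
    seq = nxt
  ))
  ord <- order(parse_timestamp(kb$prob_records$timestamp),
               kb$prob_records$seq)
  kb$prob_records <- kb$prob_records[ord, ]
  kb
}

#' Probability trajectory of a statement
#'
#' @param kb A `helo_kb`.
#' @param statement_id Statement id.
#' @return A tibble of probability records sorted by timestamp (ties by
#'   insertion order), possibly empty.
#' @export
probability_trajectory <- function(kb, statement_id) {
  stopifnot(inherits(kb, "helo_kb"))
  if (!statement_id %in% kb$statements$id) {
    stop(sprintf("unknown statement `%s`", statement_id), call. = FALSE)
  }
  dplyr::filter(kb$prob_records, .data$statement_id == .env$statement_id)
}

#' Current probability of a statement
#'
#' Returns the latest record by timestamp (ties resolved by insertion
#' order), or `NULL` when the statement has no trajectory yet.
#'
#' @inheritParams probability_trajectory
#' @param at Optional timestamp: return the latest record at or before this
#'   time instead of the overall latest.
#' @return A one-row tibble or `NULL`.
#' @export
current_probability <- function(kb, statement_id, at = NULL) {
  traj <- probability_trajectory(kb, statement_id)
  if (!is.null(at)) {
    cutoff <- parse_timestamp(at)
    traj <- traj[parse_timestamp(traj$timestamp) <= cutoff, ]
  }
  if (!nrow(traj)) return(NULL)
  traj[nrow(traj), ]
}

#' Link a statement to an evidence item
#'
#' Records that the evidence supports, refutes, or disputes the statement.
#' Adding an identical link twice is idempotent.
#'
#' @param kb A `helo_kb`.
#' @param statement_id,evidence_id Existing ids in `kb`.
#' @param relation One of `"supports"`, `"refutes"`, `"disputes"`.
#' @return The updated knowledge base.
#' @export
link_evidence <- function(kb, statement_id, evidence_id, relation) {
  stopifnot(inherits(kb, "helo_kb"))
  if (length(relation) != 1L || !relation %in% helo_relations) {
    stop(sprintf("unknown evidence relation `%s` (use %s)",
                 paste(relation, collapse = "/"),
                 paste(helo_relations, collapse = ", ")), call. = FALSE)
  }
  if (!statement_id %in% kb$statements$id) {
    stop(sprintf("unknown statement `%s`", statement_id), call. = FALSE)
  }
  if (!evidence_id %in% kb$evidence$id) {
    stop(sprintf("unknown evidence `%s`", evidence_id), call. = FALSE)
  }
  row <- tibble::tibble(statement_id = statement_id,
                        evidence_id = evidence_id, relation = relation)
  kb$links <- dplyr::distinct(dplyr::bind_rows(kb$links, row))
  kb
}

#' Evidence linked to a statement, grouped by relation
#'
#' @inheritParams probability_trajectory
#' @return A tibble joining links with evidence metadata, one row per link,
#'   with a `relation` column (`supports` / `refutes` / `disputes`).
#' @export
kb_evidence_for <- function(kb, statement_id) {
  stopifnot(inherits(kb, "helo_kb"))
  if (!statement_id %in% kb$statements$id) {
    stop(sprintf("unknown statement `%s`", statement_id), call. = FALSE)
  }
  kb$links |>
    dplyr::filter(.data$statement_id == .env$statement_id) |>
    dplyr::left_join(kb$evidence, by = c(evidence_id = "id")) |>
    dplyr::arrange(.data$relation, .data$evidence_id)
}

#' Declare a homology link between two hypotheses
#'
#' Homological inference transfers probabilistic support between hypotheses
#' about homologous genes in different organisms (e.g. yeast SIR2 to human
#' SIRT1). The weight in \[0, 1\] scales how strongly a change in the source
#' hypothesis moves the target.
#'
#' @param kb A `helo_kb`.
#' @param source_id,target_id Statement ids; self-links are rejected.
#' @param weight Transfer weight in \[0, 1\], default 0.5.
#' @return The updated knowledge base.
#' @export
kb_add_homology <- function(kb, source_id, target_id, weight = 0.5) {
  stopifnot(inherits(kb, "helo_kb"))
  if (!all(c(source_id, target_id) %in% kb$statements$id)) {
    stop("both homology endpoints must be statements in the KB", call. = FALSE)
  }
  if (identical(source_id, target_id)) {
    stop("homology self-links are not allowed", call. = FALSE)
  }
  if (!is.numeric(weight) || weight < 0 || weight > 1) {
    stop("homology `weight` must lie in [0, 1]", call. = FALSE)
  }
  kb$homology_links <- dplyr::distinct(dplyr::bind_rows(
    kb$homology_links,
    tibble::tibble(source_id = source_id, target_id = target_id,
                   weight = as.numeric(weight))
  ))
  kb
}

#' Propagate a probability change along a homology link
#'
#' When new evidence moves the probability of a model-organism hypothesis
#' (the link source), the target hypothesis is updated by linear transfer
#' with clipping:
#' `p_target_new = clip(p_target + weight * (p_source_new - p_source_old), 0, 1)`.
#' The direction of the target's change therefore matches the direction of
#' the source's change whenever the weight is positive and no clipping
#' occurs. Both the source's new record and the target's derived record
#' (method `homological_inference`) are appended, so both trajectories stay
#' complete.
#'
#' @param kb A `helo_kb`.
#' @param source_id,target_id Endpoints of an existing homology link.
#' @param new_source_prob The source hypothesis's new probability in
#'   \[0, 1\].
#' @param timestamp ISO-8601 timestamp of the triggering event.
#' @param evidence_id Optional evidence id recorded as the source of both
#'   new records.
#' @param source_method Estimation method stored on the source's new record
#'   (default `"bayesian_inference"`; use `"expert_estimation"` when the new
#'   value is an expert revision).
#' @return The updated knowledge base.
#' @export
homological_update <- function(kb, source_id, target_id, new_source_prob,
                               timestamp, evidence_id = NULL,
                               source_method = "bayesian_inference") {
  stopifnot(inherits(kb, "helo_kb"))
  link <- kb$homology_links |>
    dplyr::filter(.data$source_id == .env$source_id,
                  .data$target_id == .env$target_id)
  if (!nrow(link)) {
    stop(sprintf("no homology link %s -> %s", source_id, target_id),
         call. = FALSE)
  }
  src_cur <- current_probability(kb, source_id)
  tgt_cur <- current_probability(kb, target_id)
  if (is.null(src_cur) || is.null(tgt_cur)) {
    stop("both endpoints need a seeded probability before homological ",
         "transfer; attach prior records first", call. = FALSE)
  }
  w <- link$weight[[1]]
  new_target <- min(1, max(0, tgt_cur$value +
                             w * (new_source_prob - src_cur$value)))
  kb <- attach_probability(kb, source_id, probability_record(
    new_source_prob, "posterior", source_method, timestamp,
    source = evidence_id
  ))
  attach_probability(kb, target_id, probability_record(
    new_target, "posterior", "homological_inference", timestamp,
    procedure = sprintf("linear transfer, weight %.3g, from %s", w, source_id),
    source = evidence_id
  ))
}
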