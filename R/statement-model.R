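#' Create an ontology-style entity
#'
#' Entities are the classes or instances that atomic research statements
#' relate. They carry an opaque id, a display label, an optional source
#' ontology tag (e.g. `"GO"`), and an optional parent entity id used for
#' generalization (replacing a specific gene by its parent class).
#'
#' @param id Non-empty character scalar, unique within a knowledge base.
#' @param label Human-readable label; defaults to `id`.
#' @param source_ontology Optional character tag naming the ontology the
#'   entity comes from.
#' @param parent_id Optional id of a more generic parent entity.
#' @return An object of class `helo_entity`.
#' @examples
#' sirt1 <- entity("SIRT1", source_ontology = "SGD")
#' @export
entity <- function(id, label = id, source_ontology = NULL, parent_id = NULL) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("entity `id` must be a non-empty string", call. = FALSE)
  }
  structure(
    list(
      id = id,
      label = label,
      source_ontology = source_ontology,
      parent_id = parent_id
    ),
    class = "helo_entity"
  )
}

as_entity <- function(x) {
  if (inherits(x, "helo_entity")) return(x)
  if (is.character(x) && length(x) == 1L) return(entity(x))
  stop("expected a `helo_entity` or a single entity id string", call. = FALSE)
}

#' @export
print.helo_entity <- function(x, ...) {
  onto <- if (is.null(x$source_ontology)) "" else paste0(" [", x$source_ontology, "]")
  cat("<entity> ", x$id, onto, "\n", sep = "")
  invisible(x)
}

helo_connectives <- c("AND", "OR", "NOT", "IMPLIES", "IFF")

helo_roles <- c(
  "research_hypothesis", "assumption", "conclusion", "scientific_law", "theorem"
)

#' Build an atomic research statement
#'
#' An atomic statement has the form `PREDICATE(subject, object)` where the
#' predicate is a relation name and subject/object are entities. Two calls
#' with identical arguments produce structurally equal atoms.
#'
#' @param predicate Non-empty relation name, e.g. `"regulates"`.
#' @param subject,object Entities (or entity id strings, which are promoted
#'   to bare entities).
#' @return An object of classes `helo_atom`, `helo_statement`.
#' @examples
#' h1 <- atomic_statement("regulates", entity("SIRT1"), entity("human_life_span"))
#' render_statement(h1)
#' @export
atomic_statement <- function(predicate, subject, object) {
  if (!is.character(predicate) || length(predicate) != 1L ||
      is.na(predicate) || !nzchar(predicate)) {
    stop("`predicate` must be a non-empty string", call. = FALSE)
  }
  structure(
    list(
      predicate = predicate,
      subject = as_entity(subject),
      object = as_entity(object)
    ),
    class = c("helo_atom", "helo_statement")
  )
}

#' Combine statements with a logical connective
#'
#' Builds a compound statement from operands using one of the connectives
#' AND, OR, NOT, IMPLIES, IFF. Arity is enforced: NOT takes exactly one
#' operand, IMPLIES and IFF exactly two, AND and OR at least two. Nesting to
#' arbitrary depth is supported.
#'
#' @param connective One of `"AND"`, `"OR"`, `"NOT"`, `"IMPLIES"`, `"IFF"`.
#' @param operands List of statements (atomic or compound).
#' @return An object of classes `helo_compound`, `helo_statement`.
#' @examples
#' a <- atomic_statement("deleted", "LAC4", "strain")
#' b <- atomic_statement("carbon_source", "lactose", "medium")
#' c <- atomic_statement("phenotype", "strain", "no_growth")
#' rule <- combine_statements("IMPLIES", list(combine_statements("AND", list(a, b)), c))
#' @export
combine_statements <- function(connective, operands) {
  connective <- match.arg(connective, helo_connectives)
  if (inherits(operands, "helo_statement")) operands <- list(operands)
  if (!is.list(operands) ||
      !all(vapply(operands, inherits, logical(1), "helo_statement"))) {
    stop("`operands` must be a list of statements", call. = FALSE)
  }
  n <- length(operands)
  ok <- switch(connective,
    NOT = n == 1L,
    IMPLIES = n == 2L,
    IFF = n == 2L,
    n >= 2L
  )
  if (!ok) {
    stop(sprintf("connective %s cannot take %d operand(s)", connective, n),
         call. = FALSE)
  }
  structure(
    list(connective = connective, operands = operands),
    class = c("helo_compound", "helo_statement")
  )
}

#' @rdname combine_statements
#' @param ... Statements passed as operands.
#' @export
stmt_and <- function(...) combine_statements("AND", list(...))

#' @rdname combine_statements
#' @export
stmt_or <- function(...) combine_statements("OR", list(...))

#' @rdname combine_statements
#' @param x A statement.
#' @export
stmt_not <- function(x) combine_statements("NOT", list(x))

#' @rdname combine_statements
#' @param lhs,rhs Statements.
#' @export
stmt_implies <- function(lhs, rhs) combine_statements("IMPLIES", list(lhs, rhs))

#' @rdname combine_statements
#' @export
stmt_iff <- function(lhs, rhs) combine_statements("IFF", list(lhs, rhs))

#' Render a statement to plain text
#'
#' Atoms render as `predicate(subject_id, object_id)`; compounds use the
#' connective keywords with parentheses, e.g.
#' `((deleted(LAC4, strain) AND carbon_source(lactose, medium)) IMPLIES
#' phenotype(strain, no_growth))`. The rendering parses back with
#' [parse_statement()].
#'
#' @param stmt A statement.
#' @return A character scalar.
#' @export
render_statement <- function(stmt) {
  stopifnot(inherits(stmt, "helo_statement"))
  if (inherits(stmt, "helo_atom")) {
    return(sprintf("%s(%s, %s)", stmt$predicate, stmt$subject$id, stmt$object$id))
  }
  parts <- vapply(stmt$operands, render_statement, character(1))
  if (stmt$connective == "NOT") {
    sprintf("(NOT %s)", parts[[1]])
  } else {
    paste0("(", paste(parts, collapse = paste0(" ", stmt$connective, " ")), ")")
  }
}

# Canonical rendering: operands of the commutative connectives AND/OR are
# sorted, so equality ignores their order while display order is preserved.
canonical_render <- function(stmt) {
  if (inherits(stmt, "helo_atom")) return(render_statement(stmt))
  parts <- vapply(stmt$operands, canonical_render, character(1))
  if (stmt$connective %in% c("AND", "OR")) parts <- sort(parts)
  if (stmt$connective == "NOT") {
    sprintf("(NOT %s)", parts[[1]])
  } else {
    paste0("(", paste(parts, collapse = paste0(" ", stmt$connective, " ")), ")")
  }
}

#' Structural statement equality
#'
#' Identity is structural: connective, operands and atom fields. Operand
#' order is ignored for the commutative connectives AND and OR.
#'
#' @param a,b Statements.
#' @return Logical scalar.
#' @export
statements_equal <- function(a, b) {
  canonical_render(a) == canonical_render(b)
}

#' @export
print.helo_statement <- function(x, ...) {
  kind <- if (inherits(x, "helo_atom")) "atom" else tolower(x$connective)
  cat("<statement:", kind, "> ", render_statement(x), "\n", sep = "")
  invisible(x)
}

#' Replace an entity throughout a statement
#'
#' Every occurrence of `old` (matched by entity id) in the statement's atoms
#' is replaced by `new`; the input statement is not modified. Substituting an
#' entity that does not occur returns a statement equal to the input, and
#' substitution is idempotent when `old` equals `new`. This is how
#' generalization is expressed: a specific gene entity can be replaced by its
#' parent ontology class.
#'
#' @param stmt A statement.
#' @param old,new Entities (or id strings).
#' @return A statement of the same shape.
#' @export
substitute_entity <- function(stmt, old, new) {
  old <- as_entity(old)
  new <- as_entity(new)
  if (inherits(stmt, "helo_atom")) {
    subj <- if (stmt$subject$id == old$id) new else stmt$subject
    obj <- if (stmt$object$id == old$id) new else stmt$object
    return(atomic_statement(stmt$predicate, subj, obj))
  }
  combine_statements(
    stmt$connective,
    lapply(stmt$operands, substitute_entity, old = old, new = new)
  )
}

#' List the distinct atoms of a statement
#'
#' @param stmt A statement.
#' @return A named list of `helo_atom` objects keyed by their rendering.
#' @export
statement_atoms <- function(stmt) {
  if (inherits(stmt, "helo_atom")) {
    out <- list(stmt)
    names(out) <- render_statement(stmt)
    return(out)
  }
  atoms <- list()
  for (op in stmt$operands) atoms <- c(atoms, statement_atoms(op))
  atoms[!duplicated(names(atoms))]
}

#' Evaluate a statement under a truth assignment
#'
#' Applies standard propositional semantics for AND/OR/NOT/IMPLIES/IFF. The
#' assignment maps atoms, keyed by their plain-text rendering (see
#' [render_statement()]), to logical values; every atom occurring in the
#' statement must have an entry.
#'
#' @param stmt A statement.
#' @param assignment Named logical vector keyed by atom renderings.
#' @return Logical scalar.
#' @examples
#' a <- atomic_statement("p", "x", "y")
#' b <- atomic_statement("q", "x", "y")
#' evaluate_statement(stmt_implies(a, b), c("p(x, y)" = FALSE, "q(x, y)" = TRUE))
#' @export
evaluate_statement <- function(stmt, assignment) {
  if (inherits(stmt, "helo_atom")) {
    key <- render_statement(stmt)
    if (!key %in% names(assignment)) {
      stop(sprintf("no truth value assigned to atom `%s`", key), call. = FALSE)
    }
    return(isTRUE(as.logical(assignment[[key]])))
  }
  vals <- vapply(stmt$operands, evaluate_statement, logical(1),
                 assignment = assignment)
  switch(stmt$connective,
    AND = all(vals),
    OR = any(vals),
    NOT = !vals[[1]],
    IMPLIES = !vals[[1]] || vals[[2]],
    IFF = vals[[1]] == vals[[2]]
  )
}

#' Wrap a logical expression as a research statement
#'
#' A research statement gives a logical expression an id, a role from the
#' statement hierarchy (research hypothesis, assumption, conclusion,
#' scientific law, theorem), and optional free text. Production-rule laws are
#' research statements with role `scientific_law` and an IMPLIES expression.
#'
#' @param id Unique non-empty id.
#' @param expression An atomic or compound statement.
#' @param role One of `"research_hypothesis"`, `"assumption"`,
#'   `"conclusion"`, `"scientific_law"`, `"theorem"`.
#' @param free_text Optional prose rendering.
#' @return An object of class `helo_research_statement`.
#' @export
research_statement <- function(id, expression,
                               role = "research_hypothesis",
                               free_text = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("`id` must be a non-empty string", call. = FALSE)
  }
  stopifnot(inherits(expression, "helo_statement"))
  role <- match.arg(role, helo_roles)
  structure(
    list(id = id, expression = expression, role = role, free_text = free_text),
    class = "helo_research_statement"
  )
}

#' @export
print.helo_research_statement <- function(x, ...) {
  cat("<research statement> ", x$id, " (", x$role, ")\n  ",
      render_statement(x$expression), "\n", sep = "")
  invisible(x)
}

# ---- plain-text parser -------------------------------------------------

tokenize_statement <- function(text) {
  pat <- "\\(|\\)|,|[^(),[:space:]]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) stop("empty statement text", call. = FALSE)
  regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
}

#' Parse a statement from plain text
#'
#' Inverse of [render_statement()]: accepts
#' `predicate(subject_id, object_id)` atoms and compounds built with
#' AND/OR/NOT/IMPLIES/IFF inside parentheses. Entity ids are resolved
#' against `entities` when supplied (a list of `helo_entity`, or a data
#' frame with an `id` column); otherwise bare entities are created.
#'
#' @param text Character scalar.
#' @param entities Optional entity lookup.
#' @return A statement.
#' @examples
#' parse_statement("(regulates(SIR2, yeast_life_span) IMPLIES regulates(SIRT1, human_life_span))")
#' @export
parse_statement <- function(text, entities = NULL) {
  lookup <- entity_lookup(entities)
  toks <- tokenize_statement(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  expect <- function(tok) {
    got <- advance()
    if (!identical(got, tok)) {
      stop(sprintf("expected `%s` but found `%s`", tok,
                   if (is.na(got)) "<end>" else got), call. = FALSE)
    }
  }
  resolve <- function(id) {
    if (!is.null(lookup[[id]])) lookup[[id]] else entity(id)
  }
  parse_atom <- function() {
    pred <- advance()
    expect("(")
    subj <- advance()
    expect(",")
    obj <- advance()
    expect(")")
    atomic_statement(pred, resolve(subj), resolve(obj))
  }
  parse_expr <- function() {
    if (identical(peek(), "(")) parse_group() else parse_atom()
  }
  parse_group <- function() {
    expect("(")
    if (identical(peek(), "NOT")) {
      advance()
      inner <- parse_expr()
      expect(")")
      return(combine_statements("NOT", list(inner)))
    }
    ops <- list(parse_expr())
    conn <- NULL
    while (!identical(peek(), ")")) {
      tok <- advance()
      if (is.na(tok) || !tok %in% helo_connectives) {
        stop(sprintf("expected a connective, found `%s`",
                     if (is.na(tok)) "<end>" else tok), call. = FALSE)
      }
      if (is.null(conn)) {
        conn <- tok
      } else if (!identical(conn, tok)) {
        stop("mixed connectives inside one group; add parentheses",
             call. = FALSE)
      }
      ops <- c(ops, list(parse_expr()))
    }
    expect(")")
    if (is.null(conn)) return(ops[[1]])  # plain grouping parens
    combine_statements(conn, ops)
  }
  out <- parse_expr()
  if (pos <= length(toks)) {
    stop(sprintf("trailing tokens after statement: `%s`", toks[[pos]]),
         call. = FALSE)
  }
  out
}

entity_lookup <- function(entities) {
  if (is.null(entities)) return(list())
  if (is.data.frame(entities)) {
    out <- lapply(seq_len(nrow(entities)), function(i) {
      entity(
        entities$id[[i]],
        label = entities$label[[i]] %||% entities$id[[i]],
        source_ontology = na_to_null(entities$source_ontology[[i]]),
        parent_id = na_to_null(entities$parent_id[[i]])
      )
    })
    names(out) <- entities$id
    return(out)
  }
  if (is.list(entities)) {
    stopifnot(all(vapply(entities, inherits, logical(1), "helo_entity")))
    names(entities) <- vapply(entities, `[[`, character(1), "id")
    return(entities)
  }
  stop("`entities` must be NULL, a list of entities, or a data frame",
       call. = FALSE)
}

na_to_null <- function(x) if (is.null(x) || is.na(x)) NULL else x

`%||%` <- function(x, y) if (is.null(x)) y else x
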