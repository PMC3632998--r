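test_that("atoms are canonical, render as predicate(subject, object), and compare structurally", {
  sirt1 <- entity("SIRT1")
  span <- entity("human_life_span")
  h1 <- atomic_statement("regulates", sirt1, span)
  expect_equal(render_statement(h1), "regulates(SIRT1, human_life_span)")

  # identical inputs give structurally equal atoms
  expect_true(statements_equal(h1, atomic_statement("regulates", sirt1, span)))

  # reflexive subject == object is allowed
  e <- entity("e")
  refl <- atomic_statement("p", e, e)
  expect_equal(refl$subject$id, refl$object$id)

  expect_error(atomic_statement("", sirt1, span), "non-empty")
})

test_that("connective arity is enforced and nesting works to arbitrary depth", {
  a <- atomic_statement("deleted", "lactase_genes", "strain")
  b <- atomic_statement("sole_carbon_source", "lactose", "medium")
  cc <- atomic_statement("phenotype", "strain", "no_growth")

  rule <- stmt_implies(stmt_and(a, b), cc)
  expect_equal(
    render_statement(rule),
    paste0("((deleted(lactase_genes, strain) AND ",
           "sole_carbon_source(lactose, medium)) IMPLIES ",
           "phenotype(strain, no_growth))")
  )
  expect_error(combine_statements("IMPLIES", list(a)), "1 operand")
  expect_error(combine_statements("NOT", list(a, b)), "2 operand")
  expect_error(combine_statements("AND", list(a)), "1 operand")

  deep <- Reduce(function(acc, i) stmt_not(acc), 1:10, accumulate = FALSE,
                 init = a)
  expect_s3_class(deep, "helo_compound")
})

test_that("equality ignores operand order for AND/OR but not IMPLIES", {
  a <- atomic_statement("p", "x", "y")
  b <- atomic_statement("q", "x", "y")
  expect_true(statements_equal(stmt_and(a, b), stmt_and(b, a)))
  expect_true(statements_equal(stmt_or(a, b), stmt_or(b, a)))
  expect_false(statements_equal(stmt_implies(a, b), stmt_implies(b, a)))
  # display order is preserved even though equality is order-free
  expect_equal(render_statement(stmt_and(b, a)), "(q(x, y) AND p(x, y))")
})

test_that("substitute_entity replaces every leaf occurrence and is non-destructive", {
  gene <- entity("YGR254W", source_ontology = "SGD")
  parent <- entity("GO:0004634", source_ontology = "GO",
                   label = "phosphopyruvate hydratase activity")
  atom <- atomic_statement("has_activity", gene, entity("enolase_activity"))

  general <- substitute_entity(atom, gene, parent)
  expect_equal(general$subject$id, "GO:0004634")
  expect_equal(atom$subject$id, "YGR254W")  # original untouched

  # absent entity: result equals input
  same <- substitute_entity(atom, entity("absent"), parent)
  expect_true(statements_equal(same, atom))

  # idempotent when old == new
  expect_true(statements_equal(substitute_entity(atom, gene, gene), atom))

  # nested compound: all occurrences replaced, checked against a
  # walk-every-leaf oracle
  set.seed(42)
  x <- entity("x")
  z <- entity("z")
  for (i in 1:25) {
    f <- random_formula(make_atoms(3), 3)
    g <- substitute_entity(f, x, z)
    count_id <- function(s, id) {
      if (inherits(s, "helo_atom")) {
        return((s$subject$id == id) + (s$object$id == id))
      }
      sum(vapply(s$operands, count_id, numeric(1), id = id))
    }
    expect_equal(count_id(g, "x"), 0)
    expect_equal(count_id(g, "z"), count_id(f, "x") + count_id(f, "z"))
  }
})

test_that("evaluate_statement follows propositional semantics and matches truth-table oracle", {
  a <- atomic_statement("a", "x", "y")
  b <- atomic_statement("b", "x", "y")
  cc <- atomic_statement("c", "x", "y")
  keys <- vapply(list(a, b, cc), render_statement, character(1))

  # modus-ponens violation: (a AND b) IMPLIES c with a=T b=T c=F
  rule <- stmt_implies(stmt_and(a, b), cc)
  expect_false(evaluate_statement(
    rule, stats::setNames(c(TRUE, TRUE, FALSE), keys)))

  # vacuous implication
  expect_true(evaluate_statement(
    stmt_implies(a, b), stats::setNames(c(FALSE, FALSE, TRUE), keys)))

  # missing atom errors by name
  expect_error(evaluate_statement(rule, c("a(x, y)" = TRUE)), "b\\(x, y\\)")

  # random formulas of <= 4 atoms agree with the enumeration oracle on
  # every assignment
  set.seed(7)
  for (rep in 1:40) {
    atoms <- make_atoms(sample(2:4, 1))
    f <- random_formula(atoms, 3)
    for (asgn in all_assignments(atoms)) {
      expect_identical(evaluate_statement(f, asgn), oracle_eval(f, asgn))
    }
  }
})

test_that("statement text round-trips through parse_statement", {
  set.seed(11)
  for (rep in 1:30) {
    f <- random_formula(make_atoms(3), 3)
    txt <- render_statement(f)
    expect_true(statements_equal(parse_statement(txt), f))
    expect_equal(render_statement(parse_statement(txt)), txt)
  }
  expect_error(parse_statement("(p(a, b) AND"), "expected")
  expect_error(parse_statement("(p(a, b) AND q(a, b) OR r(a, b))"), "mixed")
})

test_that("research statements validate their role and carry laws as IMPLIES rules", {
  a <- atomic_statement("observed", "evidence_1", "assay")
  law <- research_statement("law1", stmt_implies(a, a), role = "scientific_law")
  expect_equal(law$role, "scientific_law")
  expect_error(research_statement("x", a, role = "wild_guess"))
})
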