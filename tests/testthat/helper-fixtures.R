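# Small deterministic fixtures and lazily computed shared runs (the
# default synthetic cohorts are expensive; compute each once per test
# session).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_cohort_1000 <- function() {
  cached("cohort_1000", generate_cohort(sim_config(n_patients = 1000,
                                                   seed = 20260101)))
}

default_run_1000 <- function() {
  cached("run_1000", {
    sc <- default_cohort_1000()
    suppressMessages(run_phenomap(sc$cohort))
  })
}

default_cohort_5000 <- function() {
  cached("cohort_5000", generate_cohort(sim_config(n_patients = 5000,
                                                   seed = 20260102)))
}

default_run_5000 <- function() {
  cached("run_5000", {
    sc <- default_cohort_5000()
    suppressMessages(run_phenomap(sc$cohort))
  })
}

# a tiny cohort data frame with every required column, no missingness
tiny_cohort <- function(n = 40, seed = 7) {
  sc <- generate_cohort(sim_config(n_patients = n, seed = seed,
                                   missing_rate_per_feature = numeric()))
  sc$cohort
}

unclass_noattr <- function(x) {
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  x
}

expect_same_mapper <- function(graph, oracle) {
  got <- graph_signature(graph$members, graph$edges)
  want <- graph_signature(oracle$nodes, oracle$edges)
  expect_identical(got$nodes, want$nodes)
  expect_identical(got$edges, want$edges)
}
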