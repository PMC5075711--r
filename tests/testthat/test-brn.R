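test_that("validate_brn returns violations as data, not errors", {
  x <- era_brn()
  expect_length(validate_brn(x), 0)

  bad <- brn(c("a", "b"),
             data.frame(source = "a", target = "b", sign = "+",
                        threshold = 2L),
             validate = FALSE)
  v <- validate_brn(bad)
  expect_length(v, 1)
  expect_match(v, "threshold 2 outside 1..1", fixed = TRUE)

  dup <- brn(c("a", "b"),
             data.frame(source = c("a", "a"), target = c("b", "b"),
                        sign = c("+", "-")),
             validate = FALSE)
  expect_match(validate_brn(dup), "duplicate interaction a -> b",
               all = FALSE)

  expect_match(validate_brn(brn(data.frame(name = "a", max_level = 0L),
                                validate = FALSE)),
               "max_level", all = FALSE)
})

test_that("resources follow the activator-present / inhibitor-absent rule", {
  x <- era_brn()
  e <- era_entities()

  # input entities have no predecessors, hence an empty resource set
  expect_identical(compute_resources(x, c(0, 0, 0, 0, 0), e[1]),
                   character(0))
  expect_identical(compute_resources(x, c(1, 1, 1, 1, 1), e[1]),
                   character(0))

  # p53 at rest: both inhibitors (ER-alpha, Mdm2) below threshold are
  # resources, the absent activator BRCA1 is not
  expect_setequal(compute_resources(x, c(0, 0, 0, 0, 0), "p53"),
                  c("ER-alpha", "Mdm2"))
  # p53 with everything on: only the activator BRCA1 helps
  expect_setequal(compute_resources(x, c(1, 1, 1, 1, 1), "p53"), "BRCA1")

  expect_error(compute_resources(x, c(0, 0, 0, 0, 0), "nope"),
               "unknown entity")
})

test_that("resources are invariant to levels of non-predecessors", {
  x <- era_brn()
  set.seed(42)
  for (i in 1:50) {
    st <- sample(0:1, 5, replace = TRUE)
    base <- compute_resources(x, st, "BRCA1")  # only predecessor: p53
    st2 <- st
    st2[c(1, 2, 3, 5)] <- sample(0:1, 4, replace = TRUE)
    st2[4] <- st[4]
    expect_identical(compute_resources(x, st2, "BRCA1"), base)
  }
})

test_that("target levels reproduce the reference parameter table", {
  x <- era_brn()
  k <- era_parameters()
  expect_identical(target_level(x, k, c(0, 0, 0, 0, 0), "p53"), 1L)
  expect_identical(target_level(x, k, c(0, 0, 0, 0, 0), "IGF-1R/EGFR"), 1L)
  expect_identical(target_level(x, k, c(1, 1, 1, 1, 1), "IGF-1R/EGFR"), 1L)
  expect_identical(target_level(x, k, c(0, 0, 0, 0, 0), "ER-alpha"), 0L)

  # totality is enforced
  k2 <- unclass(k)
  k2[["Mdm2"]] <- k2[["Mdm2"]]["{}"]
  expect_error(target_level(x, structure(k2, class = "parameterization"),
                            c(0, 0, 0, 1, 0), "Mdm2"),
               "not total")
})

test_that("asynchronous successors move one entity one step toward target", {
  x <- era_brn()
  k <- era_parameters()

  # metastatic deadlock: no successors
  expect_identical(nrow(successors(x, k, c(1, 1, 0, 0, 0))), 0L)
  # resting state: receptors and p53 both tend upward
  expect_setequal(state_label(successors(x, k, c(0, 0, 0, 0, 0))),
                  c("(1,0,0,0,0)", "(0,0,0,1,0)"))

  # single unregulated Boolean entity already at target
  x1 <- brn("a")
  k1 <- parameterization(x1, list(a = c("{}" = 0L)))
  expect_identical(nrow(successors(x1, k1, 0L)), 0L)
})

test_that("state graph enumerates the full product space", {
  x <- era_brn()
  k <- era_parameters()
  g <- build_state_graph(x, k)
  expect_identical(nrow(g$states), 32L)

  # one Boolean entity tending to 1: two nodes, one edge
  x1 <- brn("a")
  k1 <- parameterization(x1, list(a = c("{}" = 1L)))
  g1 <- build_state_graph(x1, k1)
  expect_identical(nrow(g1$states), 2L)
  expect_identical(g1$labels[g1$edges[, 1]], "(0)")
  expect_identical(g1$labels[g1$edges[, 2]], "(1)")

  # mutual inhibition: exactly the two exclusive fixed points
  m <- motif("positive-2-loop")
  gm <- build_state_graph(m$brn, m$parameterization)
  expect_setequal(find_deadlocks(gm), c("(1,0)", "(0,1)"))

  expect_error(build_state_graph(x, k, max_states = 10),
               "exceeding max_states")
})

test_that("every transition changes exactly one coordinate by one unit", {
  for (seed in 1:10) {
    g <- random_state_graph(seed)
    if (!nrow(g$edges)) next
    d <- abs(g$states[g$edges[, 1], , drop = FALSE] -
             g$states[g$edges[, 2], , drop = FALSE])
    expect_true(all(rowSums(d) == 1))
    expect_true(all(d <= 1))
  }
})

test_that("a state is terminal iff every entity sits at its target", {
  x <- era_brn()
  k <- era_parameters()
  g <- build_state_graph(x, k)
  outdeg <- tabulate(g$edges[, 1], nbins = 32)
  for (i in seq_len(32)) {
    at_target <- all(vapply(g$entities, function(e)
      g$states[i, e] == target_level(x, k, g$states[i, ], e), logical(1)))
    expect_identical(outdeg[i] == 0, at_target)
  }
  # the reference network has a second fixed point with everything on
  expect_true("(1,1,1,1,1)" %in% find_deadlocks(g))
})

test_that("successors agree with the literal-rule oracle on random inputs", {
  # 1000 random (BRN, K, state) triples
  for (seed in 1:200) {
    x <- random_brn(n_entities = 2 + seed %% 3, edge_density = 0.6,
                    max_level = 1 + seed %% 2, seed = seed)
    k <- random_parameterization(x, monotone = seed %% 2 == 0,
                                 seed = seed + 1000)
    maxl <- x$entities$max_level
    set.seed(seed + 2000)
    for (r in 1:5) {
      st <- vapply(maxl, function(m) sample(0:m, 1), integer(1))
      got <- successors(x, k, st)
      want <- oracle_successors(x, k, st)
      expect_setequal(state_label(got),
                      if (nrow(want)) state_label(want) else character(0))
    }
  }
})
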