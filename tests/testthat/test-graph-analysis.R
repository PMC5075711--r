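ref_graph <- function() {
  ref <- load_reference_network()
  build_state_graph(ref$brn, ref$parameterization)
}

test_that("deadlocks are exactly the out-degree-zero states", {
  g <- ref_graph()
  dead <- find_deadlocks(g)
  expect_true("(1,1,0,0,0)" %in% dead)
  # exhaustive cross-check against per-state successor calls
  ref <- load_reference_network()
  manual <- g$labels[vapply(seq_len(32), function(i)
    nrow(successors(ref$brn, ref$parameterization, g$states[i, ])) == 0L,
    logical(1))]
  expect_setequal(dead, manual)

  # a single self-consistent state is its own deadlock
  x1 <- brn("a"); k1 <- parameterization(x1, list(a = c("{}" = 0L)))
  g1 <- build_state_graph(x1, k1)
  expect_identical(find_deadlocks(g1), "(0)")
})

test_that("cycle enumeration is complete, canonical and deterministic", {
  g <- ref_graph()
  cyc <- enumerate_elementary_cycles(g, labels = FALSE)
  # agreement with the rotate-and-deduplicate oracle
  expect_identical(length(cyc), oracle_cycles(32, g$edges))
  # canonical rotation: minimum index first; no repeated states
  for (cy in cyc) {
    expect_identical(cy[1], min(cy))
    expect_identical(anyDuplicated(cy), 0L)
  }
  # determinism
  expect_identical(enumerate_elementary_cycles(g),
                   enumerate_elementary_cycles(g))

  # the low-risk-zone oscillation is among the cycles
  labs <- enumerate_elementary_cycles(g)
  p1_osc <- c("(0,0,0,0,0)", "(0,0,0,1,0)", "(0,0,0,1,1)", "(0,0,0,0,1)")
  expect_true(any(vapply(labs, function(cy)
    identical(cy, p1_osc), logical(1))))
  # and every hop of it is a real transition
  ref <- load_reference_network()
  seq5 <- lapply(p1_osc, parse_state)
  for (i in seq_along(seq5)) {
    nxt <- seq5[[if (i == length(seq5)) 1 else i + 1]]
    succ <- successors(ref$brn, ref$parameterization, seq5[[i]])
    expect_true(state_label(nxt) %in% state_label(succ))
  }
})

test_that("cycle enumeration agrees with the oracle on random graphs", {
  for (seed in 1:20) {
    x <- random_brn(3, edge_density = 0.6, seed = seed)
    k <- random_parameterization(x, seed = seed + 50)
    g <- build_state_graph(x, k)  # at most 8 states here
    expect_identical(length(enumerate_elementary_cycles(g)),
                     oracle_cycles(nrow(g$states), g$edges))
  }
})

test_that("DAGs have no cycles and deadlocks sit on no cycle", {
  m <- motif("input-chain")
  g <- build_state_graph(m$brn, m$parameterization)
  expect_length(enumerate_elementary_cycles(g), 0)

  g2 <- ref_graph()
  dead <- find_deadlocks(g2)
  for (cy in enumerate_elementary_cycles(g2))
    expect_length(intersect(cy, dead), 0)
})

test_that("zone classification matches the published partition", {
  g <- ref_graph()
  zp <- classify_zones(g, era_zone_scheme())
  fx <- era_fixtures()
  expect_identical(lengths(zp$zones),
                   c(P1 = 8L, P2a = 8L, P2b = 10L, P3 = 6L))
  for (z in names(fx$zones))
    expect_setequal(zp$zones[[z]], fx$zones[[z]])
  # partition property: disjoint and exhaustive
  expect_identical(sort(unlist(zp$zones, use.names = FALSE)),
                   sort(g$labels))
  # the receptor-on high-risk block holds the two p53-active exceptions
  expect_true(all(c("(1,1,0,1,0)", "(1,1,0,1,1)") %in% zp$zones$P2b))

  expect_error(classify_zones(g, list(list(name = "only",
    when = function(s) s[, 1] == 0))), "not exhaustive")
})

test_that("no cycle touches the metastatic zone", {
  g <- ref_graph()
  zp <- classify_zones(g, era_zone_scheme())
  zone_of <- setNames(zp$assignment, g$labels)
  for (cy in enumerate_elementary_cycles(g))
    expect_false("P3" %in% zone_of[cy])
})

test_that("path queries handle identity, reachability and blockage", {
  g <- ref_graph()
  r0 <- find_paths(g, "(0,0,0,0,0)", "(0,0,0,0,0)")
  expect_true(r0$reachable)
  expect_identical(r0$paths, list("(0,0,0,0,0)"))

  r1 <- find_paths(g, "(0,0,0,0,0)", "(1,1,0,0,0)", max_length = 10)
  expect_true(r1$reachable)
  expect_gt(length(r1$paths), 0)
  # every reported path is a chain of genuine transitions
  edge_set <- paste(g$edges[, 1], g$edges[, 2])
  for (p in r1$paths[seq_len(min(5, length(r1$paths)))]) {
    ix <- match(p, g$labels)
    expect_true(all(paste(ix[-length(ix)], ix[-1]) %in% edge_set))
  }

  # receptors never switch off: the receptor-on block cannot reach the
  # resting zone
  r2 <- find_paths(g, "(1,0,0,0,0)", "(0,0,0,0,0)")
  expect_false(r2$reachable)
})

test_that("the analysis report serializes losslessly", {
  g <- ref_graph()
  rep <- analyze_state_graph(g, scheme = era_zone_scheme(),
                             reachability = list(c("(0,0,0,0,0)",
                                                   "(1,1,0,0,0)")))
  path <- tempfile(fileext = ".json")
  write_report_json(rep[c("n_states", "deadlocks", "n_cycles", "zones")],
                    path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$n_states, rep$n_states)
  expect_setequal(back$deadlocks, rep$deadlocks)
  expect_identical(back$n_cycles, rep$n_cycles)
})
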