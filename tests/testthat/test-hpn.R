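test_that("case-study variants have the published structure", {
  for (m in list(build_homeostatic_model(), build_pathological_model())) {
    expect_identical(nrow(m$places), 7L)
    expect_identical(nrow(m$transitions), 8L)
    expect_identical(nrow(m$arcs), 18L)
    expect_true(all(m$transitions$rate == 1))
    mk <- setNames(m$places$marking, m$places$name)
    expect_identical(mk[["Ligand"]], 5)
    expect_identical(mk[["Receptor"]], 5)
    expect_true(all(mk[setdiff(names(mk), c("Ligand", "Receptor"))] == 0))
  }
  # the homeostatic variant carries the Mdm2 -> ER-alpha-production
  # negative feedback as an inhibitory arc
  h <- build_homeostatic_model()
  expect_true(any(h$arcs$from == "Mdm2" & h$arcs$kind == "inhibitory"))
  # the pathological variant suppresses p53 production via ER-alpha
  p <- build_pathological_model()
  expect_true(any(p$arcs$from == "ER-alpha" & p$arcs$to == "p53_prod" &
                  p$arcs$kind == "inhibitory"))
})

test_that("model validation rejects malformed nets", {
  pl <- data.frame(name = "A", marking = 1)
  tr <- data.frame(name = "t", rate = 1)
  expect_error(hpn_model(pl, tr,
    data.frame(from = "t", to = "A", kind = "inhibitory", weight = 1)),
    "place -> transition")
  expect_error(hpn_model(pl, tr,
    data.frame(from = "A", to = "A", kind = "normal", weight = 1)),
    "does not join")
  expect_error(hpn_model(data.frame(name = "A", marking = -1), tr,
    data.frame(from = "A", to = "t", kind = "normal", weight = 1)),
    "negative initial marking")
})

test_that("the ODE engine reproduces closed-form kinetics", {
  # irreversible A -> B at unit rate: A(t) = 5 exp(-t)
  m <- hpn_model(
    places = data.frame(name = c("A", "B"), marking = c(5, 0)),
    transitions = data.frame(name = "t1", rate = 1),
    arcs = data.frame(from = c("A", "t1"), to = c("t1", "B"),
                      kind = "normal", weight = 1))
  tr <- simulate_ode(m, 1, n_out = 101)
  expect_equal(tr$A[101], 5 * exp(-1), tolerance = 1e-6)
  expect_equal(tr$A + tr$B, rep(5, 101), tolerance = 1e-8)

  # all-zero marking with no source transition stays identically zero
  m0 <- hpn_model(
    places = data.frame(name = c("A", "B"), marking = c(0, 0)),
    transitions = data.frame(name = "t1", rate = 1),
    arcs = data.frame(from = c("A", "t1"), to = c("t1", "B"),
                      kind = "normal", weight = 1))
  tr0 <- simulate_ode(m0, 10, n_out = 11)
  expect_true(all(as.matrix(tr0[, -1]) == 0))
})

test_that("test arcs read without consuming; inhibitory arcs gate", {
  # catalytic production: B grows at rate A, A untouched
  m <- hpn_model(
    places = data.frame(name = c("A", "B"), marking = c(2, 0)),
    transitions = data.frame(name = "t1", rate = 1),
    arcs = data.frame(from = c("A", "t1"), to = c("t1", "B"),
                      kind = c("test", "normal"), weight = 1))
  tr <- simulate_ode(m, 3, n_out = 31)
  expect_equal(tr$A, rep(2, 31), tolerance = 1e-8)
  expect_equal(tr$B[31], 6, tolerance = 1e-5)

  # a source gated off by its own product at weight 2 plateaus there
  m2 <- hpn_model(
    places = data.frame(name = "P", marking = 0),
    transitions = data.frame(name = "make", rate = 1),
    arcs = data.frame(from = c("P", "make"), to = c("make", "P"),
                      kind = c("inhibitory", "normal"), weight = c(2, 1)))
  tr2 <- simulate_ode(m2, 3)
  expect_equal(tr2$P[nrow(tr2)], 2, tolerance = 0.02)
  # the smooth-gate option removes the switching stiffness at the
  # threshold while settling at the same level
  tr3 <- simulate_ode(m2, 10, smooth_gate = TRUE)
  expect_equal(tr3$P[nrow(tr3)], 2, tolerance = 0.25)
})

test_that("simulated markings stay non-negative and conserve mass", {
  trh <- simulate_ode(build_homeostatic_model(), 100)
  trp <- simulate_ode(build_pathological_model(), 100)
  expect_gte(min(as.matrix(trh[, -1])), -1e-7)
  expect_gte(min(as.matrix(trp[, -1])), -1e-7)
  # the pathological ligand -> complex -> ER-alpha chain is conservative
  total <- trp$Ligand + trp$Complex + trp$`ER-alpha`
  expect_lt(max(abs(total - total[1])), 1e-6)
})

test_that("pathological ER-alpha accumulates the ligand stock", {
  trp <- simulate_ode(build_pathological_model(), 100)
  er <- as.numeric(plateau_level(trp, "ER-alpha", window = 0.2))
  expect_lt(abs(er - 5) / 5, 0.05)
  expect_lt(attr(plateau_level(trp, "ER-alpha"), "flatness"), 0.01)
})

test_that("plateau readout averages the trailing window", {
  flat <- structure(data.frame(time = 0:100, A = rep(5, 101)),
                    class = c("hpn_trace", "data.frame"))
  expect_identical(as.numeric(plateau_level(flat, "A")), 5)
  dec <- structure(data.frame(time = seq(0, 50, by = 0.5),
                              A = 5 * exp(-seq(0, 50, by = 0.5))),
                   class = c("hpn_trace", "data.frame"))
  expect_lt(as.numeric(plateau_level(dec, "A", window = 0.1)), 1e-8)
  expect_error(plateau_level(flat, "Z"), "unknown place")
})

test_that("the sign matrix reproduces the qualitative comparison table", {
  trh <- simulate_ode(build_homeostatic_model(), 100)
  trp <- simulate_ode(build_pathological_model(), 100)
  sm <- expression_sign_matrix(trh, trp)
  fx <- era_fixtures()$table2
  m <- merge(sm, fx, by = "entity", suffixes = c("", ".ref"))
  expect_identical(nrow(m), 6L)
  expect_identical(m$homeostasis, m$homeostasis.ref)
  expect_identical(m$disease, m$disease.ref)
  # within-run contract: tumor suppressors dominate ER-alpha at
  # homeostasis and are dominated under disease
  er_h <- as.numeric(plateau_level(trh, "ER-alpha"))
  er_p <- as.numeric(plateau_level(trp, "ER-alpha"))
  for (tsg in c("BRCA1", "p53", "Mdm2")) {
    expect_gt(as.numeric(plateau_level(trh, tsg)), er_h)
    expect_lt(as.numeric(plateau_level(trp, tsg)), er_p)
  }
})

test_that("the stochastic engine is reproducible and converges to the ODE", {
  m <- hpn_model(
    places = data.frame(name = c("A", "B"), marking = c(5, 0)),
    transitions = data.frame(name = "t1", rate = 1),
    arcs = data.frame(from = c("A", "t1"), to = c("t1", "B"),
                      kind = "normal", weight = 1))
  s1 <- simulate_stochastic_avg(m, runs = 20, t_end = 2, seed = 7)
  s2 <- simulate_stochastic_avg(m, runs = 20, t_end = 2, seed = 7)
  expect_identical(s1, s2)

  # single run of a pure source is an integer staircase
  src <- hpn_model(
    places = data.frame(name = "P", marking = 0),
    transitions = data.frame(name = "make", rate = 1),
    arcs = data.frame(from = "make", to = "P", kind = "normal",
                      weight = 1))
  st <- simulate_stochastic_avg(src, runs = 1, t_end = 5, seed = 3)
  expect_true(all(st$P == floor(st$P)))
  expect_true(all(diff(st$P) >= 0))

  # run-averaged error against the ODE shrinks with the number of runs
  ode <- simulate_ode(m, 2, n_out = 201)
  err <- vapply(c(10, 100, 1000), function(r) {
    s <- simulate_stochastic_avg(m, runs = r, t_end = 2, seed = 11,
                                 n_out = 201)
    mean(abs(s$A - ode$A))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.1)
})

test_that("the pathological stochastic mean tracks the ODE plateau", {
  m <- build_pathological_model()
  ode <- simulate_ode(m, 100)
  er_ode <- as.numeric(plateau_level(ode, "ER-alpha"))
  st <- simulate_stochastic_avg(m, runs = 1000, t_end = 100, seed = 5,
                                n_out = 101)
  er_st <- as.numeric(plateau_level(st, "ER-alpha"))
  expect_lt(abs(er_st - er_ode) / er_ode, 0.1)
})
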