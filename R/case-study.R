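#' The ER-alpha associated breast-cancer regulatory network
#'
#' Five entities in fixed coordinate order (IGF-1R/EGFR, ER-alpha,
#' BRCA1, p53, Mdm2), all Boolean, with seven signed interactions:
#' growth-factor receptors activate ER-alpha; p53 activates ER-alpha,
#' BRCA1 and Mdm2; ER-alpha and Mdm2 inhibit p53; BRCA1 activates p53.
#' The sign of the p53 -> ER-alpha edge is the one free bit of the
#' published description; [confirm_sign_assignment()] pins it by brute
#' force against the qualitative reference facts.
#'
#' @param p53_to_er_sign sign of the p53 -> ER-alpha interaction.
#' @return a [brn()].
#' @export
era_brn <- function(p53_to_er_sign = "+") {
  stopifnot(p53_to_er_sign %in% c("+", "-"))
  e <- era_entities()
  brn(e, data.frame(
    source = c(e[1], e[4], e[2], e[3], e[5], e[4], e[4]),
    target = c(e[2], e[2], e[4], e[4], e[4], e[3], e[5]),
    sign   = c("+", p53_to_er_sign, "-", "+", "-", "+", "+"),
    threshold = 1L))
}

#' @rdname era_brn
#' @export
era_entities <- function() {
  c("IGF-1R/EGFR", "ER-alpha", "BRCA1", "p53", "Mdm2")
}

#' Reference logical parameters of the ER-alpha network
#'
#' The selected parameter set of the case study: receptors rise
#' unconditionally; ER-alpha rises when either the receptors or p53 are
#' resources; BRCA1 and Mdm2 track p53; p53 rises exactly when BRCA1 is
#' a resource or both of its inhibitors (ER-alpha, Mdm2) are absent.
#'
#' @return a [parameterization()] for [era_brn()].
#' @export
era_parameters <- function() {
  e <- era_entities()
  igf <- e[1]; er <- e[2]; brca <- e[3]; p53 <- e[4]; mdm2 <- e[5]
  tab <- list()
  tab[[igf]] <- c(1L); names(tab[[igf]]) <- resource_key(character(0))
  tab[[er]] <- stats::setNames(
    c(0L, 1L, 1L, 1L),
    c(resource_key(character(0)), resource_key(p53),
      resource_key(igf), resource_key(c(igf, p53))))
  tab[[brca]] <- stats::setNames(
    c(0L, 1L), c(resource_key(character(0)), resource_key(p53)))
  tab[[p53]] <- stats::setNames(
    c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L),
    c(resource_key(character(0)), resource_key(er), resource_key(mdm2),
      resource_key(brca), resource_key(c(er, mdm2)),
      resource_key(c(er, brca)), resource_key(c(brca, mdm2)),
      resource_key(c(er, brca, mdm2))))
  tab[[mdm2]] <- stats::setNames(
    c(0L, 1L), c(resource_key(character(0)), resource_key(p53)))
  parameterization(era_brn(), tab)
}

#' Risk-zone classification rule of the case study
#'
#' Zones key on the two metastasis drivers: P1 (low risk, both
#' IGF-1R/EGFR and ER-alpha off), P2a (high risk, ER-alpha on only),
#' P2b (high risk, receptors on; also contains the receptor-on states
#' with p53 active but BRCA1 off), P3 (metastatic: both drivers on,
#' excluding the p53-on/BRCA1-off states).
#'
#' @return a scheme for [classify_zones()].
#' @export
era_zone_scheme <- function() {
  e <- era_entities()
  igf <- e[1]; er <- e[2]; brca <- e[3]; p53 <- e[4]
  list(
    list(name = "P1", when = function(s) s[, igf] == 0 & s[, er] == 0),
    list(name = "P2a", when = function(s) s[, igf] == 0 & s[, er] == 1),
    list(name = "P2b", when = function(s)
      s[, igf] == 1 & (s[, er] == 0 | (s[, p53] == 1 & s[, brca] == 0))),
    list(name = "P3", when = function(s) rep(TRUE, nrow(s))))
}

#' Published reference facts of the case-study analysis
#'
#' The printed zone membership lists, the initial and deadlocked states,
#' the expected state and cycle counts, and the qualitative
#' homeostasis/disease expression-sign matrix.
#'
#' @return a named list of fixtures.
#' @export
era_fixtures <- function() {
  list(
    n_states = 32L,
    n_cycles = 75L,
    initial = "(0,0,0,0,0)",
    deadlock = "(1,1,0,0,0)",
    zones = list(
      P1 = c("(0,0,0,0,0)", "(0,0,0,1,0)", "(0,0,0,1,1)", "(0,0,1,1,1)",
             "(0,0,1,0,1)", "(0,0,1,0,0)", "(0,0,1,1,0)", "(0,0,0,0,1)"),
      P2a = c("(0,1,1,1,0)", "(0,1,0,1,0)", "(0,1,0,1,1)", "(0,1,1,1,1)",
              "(0,1,1,0,1)", "(0,1,0,0,1)", "(0,1,1,0,0)", "(0,1,0,0,0)"),
      P2b = c("(1,0,0,0,1)", "(1,0,0,0,0)", "(1,0,0,1,0)", "(1,0,0,1,1)",
              "(1,0,1,1,1)", "(1,0,1,0,1)", "(1,0,1,0,0)", "(1,0,1,1,0)",
              "(1,1,0,1,0)", "(1,1,0,1,1)"),
      P3 = c("(1,1,1,1,0)", "(1,1,1,1,1)", "(1,1,1,0,1)", "(1,1,1,0,0)",
             "(1,1,0,0,1)", "(1,1,0,0,0)")),
    table2 = data.frame(
      entity = c("Ligand", "Receptor", "ER-alpha", "BRCA1", "p53", "Mdm2"),
      homeostasis = c("-", "-", "-", "+", "+", "++"),
      disease = c("+", "+", "++", "-", "-", "-"),
      stringsAsFactors = FALSE))
}

#' Load the reference network and parameters from the shipped config
#'
#' @return list with `brn` and `parameterization` (identical to
#'   [era_brn()] / [era_parameters()]; the config file is the reviewable
#'   data form of the same model).
#' @export
load_reference_network <- function() {
  path <- system.file("extdata", "era_brn.yaml", package = "kinlogic",
                      mustWork = TRUE)
  read_brn_config(path)
}

# qualitative reference facts used to pin the free sign; returns TRUE
# when the graph built from this sign reproduces all of them
era_sign_facts <- function(x, k) {
  g <- build_state_graph(x, k)
  fx <- era_fixtures()
  init <- parse_state(fx$initial)
  succ <- state_label(successors(x, k, init))
  if (!setequal(succ, c("(1,0,0,0,0)", "(0,0,0,1,0)"))) return(FALSE)
  if (!(fx$deadlock %in% find_deadlocks(g))) return(FALSE)
  if (!find_paths(g, fx$initial, fx$deadlock, 0L)$reachable) return(FALSE)
  zp <- classify_zones(g, era_zone_scheme())
  zone_of <- stats::setNames(zp$assignment, g$labels)
  cyc <- enumerate_elementary_cycles(g)
  zones_hit <- lapply(cyc, function(cy) unique(unname(zone_of[cy])))
  if (any(vapply(zones_hit, function(z) "P3" %in% z, logical(1))))
    return(FALSE)
  # oscillations must connect the two IGF-off zones, and receptor-on
  # cycles must stay in P2b
  if (!any(vapply(zones_hit, function(z)
    all(c("P1", "P2a") %in% z), logical(1)))) return(FALSE)
  p2b <- vapply(zones_hit, function(z) "P2b" %in% z, logical(1))
  if (any(vapply(zones_hit[p2b], function(z)
    !identical(z, "P2b"), logical(1)))) return(FALSE)
  TRUE
}

#' Confirm the free interaction sign by brute force
#'
#' Builds the state graph under both candidate signs of the
#' p53 -> ER-alpha edge and keeps the one reproducing the qualitative
#' reference facts (initial-state successors, deadlock and its
#' reachability, cycle-free metastatic zone, P1/P2a passage, P2b
#' closure). Errors loudly if neither or both qualify.
#'
#' @return the confirmed sign (`"+"` or `"-"`).
#' @export
confirm_sign_assignment <- function() {
  ok <- vapply(c("+", "-"), function(sg)
    era_sign_facts(era_brn(sg), era_parameters()), logical(1))
  if (sum(ok) != 1L)
    stop("sign-assignment oracle failed: ",
         if (sum(ok) == 0L) "neither" else "both",
         " candidate sign(s) reproduce the reference facts")
  c("+", "-")[ok]
}

#' Discrete analysis of the case-study network
#'
#' Builds the asynchronous state graph of the reference network and
#' reports the state count, deadlocks, elementary-cycle census, zone
#' partition, cycle/zone overlap, and reachability of the metastatic
#' deadlock from the resting initial state.
#'
#' @param check_sign run [confirm_sign_assignment()] first.
#' @return a named list report.
#' @export
run_discrete_analysis <- function(check_sign = TRUE) {
  if (check_sign) sign_used <- confirm_sign_assignment()
  else sign_used <- "+"
  ref <- load_reference_network()
  g <- build_state_graph(ref$brn, ref$parameterization)
  fx <- era_fixtures()
  rep <- analyze_state_graph(
    g, scheme = era_zone_scheme(),
    reachability = list(c(fx$initial, fx$deadlock)))
  rep$sign_p53_to_er <- sign_used
  rep$initial <- fx$initial
  rep$initial_successors <-
    state_label(successors(ref$brn, ref$parameterization,
                           parse_state(fx$initial)))
  rep
}

# ---- continuous (hybrid Petri net) case study ----

era_hpn_places <- function() {
  data.frame(
    name = c("Ligand", "Receptor", "Complex", "ER-alpha", "BRCA1",
             "p53", "Mdm2"),
    kind = "continuous",
    marking = c(5, 5, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Case-study hybrid Petri net variants
#'
#' Both variants have 7 places, 8 mass-action transitions (all rate
#' constants 1) and 18 arcs; ligand and receptor start with 5 tokens.
#'
#' `build_homeostatic_model()`: ligand-receptor binding forms the
#' signaling complex (self-limited through an inhibitory feedback of the
#' complex on binding); the complex drives ER-alpha production, which is
#' gated off by the Mdm2 negative feedback (inhibitory arc); p53 is
#' synthesized at a basal rate and degraded in an Mdm2-assisted way;
#' BRCA1 and Mdm2 production track p53 and self-limit. The tumor
#' suppressors settle above ER-alpha, which is driven to zero.
#'
#' `build_pathological_model()`: ER-alpha suppresses p53 production and
#' promotes tumor-suppressor degradation; the tumor-suppressor feedback
#' onto ER-alpha is absent, the receptor is a catalytic (test) input,
#' and the Ligand -> Complex -> ER-alpha chain is conservative with no
#' ER-alpha sink, so ER-alpha accumulates the initial ligand stock and
#' plateaus near 5 while the tumor suppressors decay.
#'
#' The topologies are shipped as config data
#' (`inst/extdata/hpn_homeostatic.yaml`, `hpn_pathological.yaml`); the
#' builders load them.
#'
#' @return an [hpn_model()].
#' @export
build_homeostatic_model <- function() {
  read_hpn_config(system.file("extdata", "hpn_homeostatic.yaml",
                              package = "kinlogic", mustWork = TRUE))
}

#' @rdname build_homeostatic_model
#' @export
build_pathological_model <- function() {
  read_hpn_config(system.file("extdata", "hpn_pathological.yaml",
                              package = "kinlogic", mustWork = TRUE))
}

# plateau of a place at horizon t (trailing window of [0, t])
plateau_at <- function(trace, place, t, window = 0.2) {
  idx <- trace$time >= t * (1 - window) & trace$time <= t
  v <- trace[[place]][idx]
  structure(mean(v), flatness = max(v) - min(v))
}

#' Qualitative expression signs from paired simulations
#'
#' For each entity the homeostatic and pathological plateaus are
#' compared: the larger side is scored "+" (the other "-"), upgraded to
#' "++" when the gap exceeds `strong` expression units; gaps below
#' `margin` score "0" on both sides.
#'
#' @param home,disease `"hpn_trace"` objects from the two variants.
#' @param entities data.frame mapping `entity` to trace `place` column;
#'   defaults to the six case-study readouts (complex excluded).
#' @param t horizon at which plateaus are read.
#' @param margin tie margin (expression units).
#' @param strong gap above which the winning side scores "++".
#' @return data.frame with columns `entity`, `homeostasis`, `disease`.
#' @export
expression_sign_matrix <- function(home, disease, entities = NULL,
                                   t = max(home$time), margin = 0.05,
                                   strong = 1.5) {
  if (is.null(entities))
    entities <- data.frame(
      entity = c("Ligand", "Receptor", "ER-alpha", "BRCA1", "p53", "Mdm2"),
      place = c("Ligand", "Receptor", "ER-alpha", "BRCA1", "p53", "Mdm2"),
      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(entities)), function(i) {
    h <- as.numeric(plateau_at(home, entities$place[i], t))
    d <- as.numeric(plateau_at(disease, entities$place[i], t))
    gap <- d - h
    if (abs(gap) <= margin) c("0", "0")
    else if (gap > 0) c("-", if (gap > strong) "++" else "+")
    else c(if (-gap > strong) "++" else "+", "-")
  })
  data.frame(entity = entities$entity,
             homeostasis = vapply(res, `[`, "", 1),
             disease = vapply(res, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Continuous analysis of the case study
#'
#' Simulates both hybrid Petri-net variants deterministically to the
#' requested horizons, reads plateau levels, and computes the
#' homeostasis/disease sign matrix.
#'
#' @param horizons observation horizons (time units).
#' @param n_out grid points for the longest horizon.
#' @param stochastic_runs if > 0, additionally run the run-averaged
#'   stochastic engine with this many runs (slower).
#' @param seed seed for the stochastic engine.
#' @return a named list report with `structure` counts, `plateaus` (per
#'   variant, place and horizon), `sign_matrix`, and the final traces.
#' @export
run_continuous_analysis <- function(horizons = c(10, 50, 100),
                                    n_out = 1001, stochastic_runs = 0,
                                    seed = 1) {
  models <- list(homeostatic = build_homeostatic_model(),
                 pathological = build_pathological_model())
  t_max <- max(horizons)
  traces <- lapply(models, simulate_ode, t_end = t_max, n_out = n_out)
  plateaus <- do.call(rbind, lapply(names(models), function(v) {
    do.call(rbind, lapply(models[[v]]$places$name, function(p) {
      do.call(rbind, lapply(horizons, function(h) {
        data.frame(variant = v, place = p, horizon = h,
                   plateau = as.numeric(plateau_at(traces[[v]], p, h)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rep <- list(
    structure = lapply(models, function(m)
      c(places = nrow(m$places), transitions = nrow(m$transitions),
        arcs = nrow(m$arcs))),
    horizons = horizons,
    plateaus = plateaus,
    sign_matrix = expression_sign_matrix(traces$homeostatic,
                                         traces$pathological),
    traces = traces)
  if (stochastic_runs > 0) {
    rep$stochastic <- lapply(models, simulate_stochastic_avg,
                             runs = stochastic_runs, t_end = t_max,
                             seed = seed)
  }
  rep
}

#' Diff a pipeline report against the published fixtures
#'
#' Exact set equality for zones and deadlock membership, count equality
#' for the state and cycle censuses, tolerance checks for the
#' pathological ER-alpha plateau, and cellwise equality for the
#' homeostasis/disease sign matrix. Checks that cannot run (absent
#' report section, or the optional supplementary CTL fixture) are
#' reported `"skipped"`, not failed.
#'
#' @param discrete report from [run_discrete_analysis()] (or `NULL`).
#' @param continuous report from [run_continuous_analysis()] (or
#'   `NULL`).
#' @param supp_ctl optional path to a transcribed supplementary CTL
#'   fixture (YAML list of formulas); when supplied, the
#'   five-accepted-sets synthesis check runs, otherwise it is skipped.
#' @param plateau_tol relative tolerance for the ER-alpha plateau.
#' @return data.frame with columns `check`, `status`
#'   (`"pass"/"fail"/"skipped"`), `detail`.
#' @export
compare_to_fixtures <- function(discrete = NULL, continuous = NULL,
                                supp_ctl = NULL, plateau_tol = 0.05) {
  fx <- era_fixtures()
  out <- list()
  add <- function(check, status, detail = "") {
    out[[length(out) + 1L]] <<- data.frame(check = check, status = status,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  if (is.null(discrete)) {
    for (chk in c("state_count", "deadlock", "deadlock_reachable",
                  "zone_partition", "cycle_count", "cycles_avoid_P3"))
      add(chk, "skipped", "no discrete report")
  } else {
    add("state_count",
        if (identical(discrete$n_states, fx$n_states)) "pass" else "fail",
        paste0("computed ", discrete$n_states, ", reference ", fx$n_states))
    add("deadlock",
        if (fx$deadlock %in% discrete$deadlocks) "pass" else "fail",
        paste0("deadlocks: ", paste(discrete$deadlocks, collapse = " ")))
    reach <- discrete$reachability[[1]]$reachable
    add("deadlock_reachable", if (isTRUE(reach)) "pass" else "fail",
        paste0(fx$initial, " -> ", fx$deadlock))
    zones_ok <- all(vapply(names(fx$zones), function(z)
      setequal(discrete$zones[[z]], fx$zones[[z]]), logical(1)))
    add("zone_partition", if (zones_ok) "pass" else "fail",
        paste0("sizes ", paste(lengths(discrete$zones), collapse = "/")))
    add("cycle_count",
        if (identical(discrete$n_cycles, fx$n_cycles)) "pass" else "fail",
        paste0("computed ", discrete$n_cycles, ", reference ",
               fx$n_cycles))
    avoid <- !any(vapply(discrete$cycle_zones, function(z)
      "P3" %in% z, logical(1)))
    add("cycles_avoid_P3", if (avoid) "pass" else "fail",
        paste0(discrete$n_cycles, " cycles checked"))
  }
  if (is.null(continuous)) {
    for (chk in c("hpn_structure", "er_plateau", "sign_matrix"))
      add(chk, "skipped", "no continuous report")
  } else {
    struct_ok <- all(vapply(continuous$structure, function(s)
      all(s == c(7, 8, 18)), logical(1)))
    add("hpn_structure", if (struct_ok) "pass" else "fail",
        paste(vapply(continuous$structure, paste, "", collapse = "-"),
              collapse = ", "))
    pl <- continuous$plateaus
    er <- pl$plateau[pl$variant == "pathological" & pl$place == "ER-alpha" &
                     pl$horizon == max(pl$horizon)]
    add("er_plateau",
        if (abs(er - 5) / 5 <= plateau_tol) "pass" else "fail",
        paste0("pathological ER-alpha plateau ", signif(er, 4)))
    sm <- continuous$sign_matrix
    ref <- fx$table2
    m <- merge(sm, ref, by = "entity", suffixes = c("", ".ref"))
    sign_ok <- nrow(m) == nrow(ref) &&
      all(m$homeostasis == m$homeostasis.ref) &&
      all(m$disease == m$disease.ref)
    add("sign_matrix", if (sign_ok) "pass" else "fail",
        paste(m$entity, m$homeostasis, m$disease, collapse = "; "))
  }
  if (is.null(supp_ctl)) {
    add("five_accepted_sets", "skipped",
        "supplementary CTL fixture not supplied")
  } else {
    forms <- yaml::read_yaml(supp_ctl)
    ref <- load_reference_network()
    res <- filter_by_ctl(ref$brn, as.list(unlist(forms)),
                         mode = "initial")
    ok <- res$accepted_count == 5L &&
      synthesis_contains(res, ref$brn, ref$parameterization)
    add("five_accepted_sets", if (ok) "pass" else "fail",
        paste0(res$accepted_count, " accepted sets"))
  }
  do.call(rbind, out)
}

#' One-command reproduction pipeline
#'
#' Runs the discrete and continuous analyses of the case study, diffs
#' every result against the published fixtures, and writes the report
#' (JSON), the fixture diff (CSV), the state graph (DOT) and the
#' simulated traces (CSV) to a directory.
#'
#' @param out_dir output directory (created if needed).
#' @param skip_continuous omit the hybrid Petri-net stage.
#' @param supp_ctl optional supplementary CTL fixture path (see
#'   [compare_to_fixtures()]).
#' @return invisibly, a list with `discrete`, `continuous` and `diff`.
#' @export
reproduce_case_study <- function(out_dir = "era-report",
                                 skip_continuous = FALSE,
                                 supp_ctl = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  discrete <- run_discrete_analysis()
  continuous <- if (skip_continuous) NULL else run_continuous_analysis()
  diff <- compare_to_fixtures(discrete, continuous, supp_ctl = supp_ctl)
  ref <- load_reference_network()
  g <- build_state_graph(ref$brn, ref$parameterization)
  write_state_graph(g, file.path(out_dir, "state_graph.dot"), "dot")
  write_report_json(discrete[setdiff(names(discrete), "cycles")],
                    file.path(out_dir, "discrete_report.json"))
  if (!is.null(continuous)) {
    write_trace_csv(continuous$traces$homeostatic,
                    file.path(out_dir, "trace_homeostatic.csv"))
    write_trace_csv(continuous$traces$pathological,
                    file.path(out_dir, "trace_pathological.csv"))
    utils::write.csv(continuous$plateaus,
                     file.path(out_dir, "plateaus.csv"), row.names = FALSE)
    utils::write.csv(continuous$sign_matrix,
                     file.path(out_dir, "sign_matrix.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(diff, file.path(out_dir, "fixture_diff.csv"),
                   row.names = FALSE)
  invisible(list(discrete = discrete, continuous = continuous,
                 diff = diff))
}
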