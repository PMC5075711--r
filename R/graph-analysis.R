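#' Convert a state graph to igraph
#'
#' @param graph a [build_state_graph()] result.
#' @return an igraph directed graph whose vertex `name` attribute holds
#'   the canonical state labels.
#' @export
as_igraph <- function(graph) {
  n <- nrow(graph$states)
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, t(graph$edges))
  igraph::set_vertex_attr(g, "name", value = graph$labels)
}

#' Fixed points (deadlocks) of a state graph
#'
#' A deadlock is a state with no outgoing transitions: every entity is
#' already at its target level.
#'
#' @inheritParams as_igraph
#' @return character vector of deadlock state labels.
#' @export
find_deadlocks <- function(graph) {
  n <- nrow(graph$states)
  outdeg <- tabulate(graph$edges[, 1], nbins = n)
  graph$labels[outdeg == 0L]
}

#' Enumerate elementary directed cycles
#'
#' Complete, duplicate-free enumeration of the simple directed cycles of
#' the state graph. Each cycle is reported once, canonically rotated so
#' its smallest state index comes first (DFS rooted at the minimum
#' vertex of each cycle, Johnson-style); output order is deterministic.
#'
#' @inheritParams as_igraph
#' @param max_cycles emitting more cycles than this is an error
#'   (guards pathological graphs).
#' @param labels return cycles as label vectors (default) or as integer
#'   state-index vectors.
#' @return list of cycles; each cycle lists its states once, in order
#'   (the closing edge back to the first state is implicit).
#' @export
enumerate_elementary_cycles <- function(graph, max_cycles = 100000,
                                        labels = TRUE) {
  n <- nrow(graph$states)
  adj <- lapply(seq_len(n), function(v)
    sort(graph$edges[graph$edges[, 1] == v, 2]))
  out <- vector("list", 0)
  path <- integer(0)
  onpath <- logical(n)
  emit <- function(cyc) {
    if (length(out) >= max_cycles)
      stop("more than ", max_cycles, " elementary cycles; raise max_cycles")
    out[[length(out) + 1L]] <<- cyc
  }
  for (s in seq_len(n)) {
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      onpath[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w == s) emit(path)
        else if (w > s && !onpath[w]) dfs(w)
      }
      onpath[v] <<- FALSE
      path <<- path[-length(path)]
    }
    dfs(s)
  }
  if (labels) lapply(out, function(ix) graph$labels[ix]) else out
}

#' Zone classification of a state graph
#'
#' Partitions the states into named blocks by ordered predicate rules;
#' the first matching rule wins, so blocks are disjoint by construction.
#' An error is raised if any state matches no rule (the partition must
#' be exhaustive).
#'
#' @inheritParams as_igraph
#' @param scheme list of rules, each `list(name =, when = function(states))`
#'   where `when` receives the state matrix (columns named by entity)
#'   and returns a logical vector. See [era_zone_scheme()] for the
#'   breast-cancer case-study rule.
#' @return an object of class `"zone_partition"`: `zones` (named list of
#'   label vectors) and `assignment` (zone name per state).
#' @export
classify_zones <- function(graph, scheme) {
  n <- nrow(graph$states)
  assignment <- rep(NA_character_, n)
  for (rule in scheme) {
    hit <- rule$when(graph$states)
    if (!is.logical(hit) || length(hit) != n)
      stop("zone rule '", rule$name, "' did not return one logical per state")
    assignment[is.na(assignment) & hit] <- rule$name
  }
  if (anyNA(assignment))
    stop("zone scheme is not exhaustive: unassigned states ",
         paste(graph$labels[is.na(assignment)], collapse = ", "))
  zones <- lapply(vapply(scheme, `[[`, "", "name"), function(z)
    graph$labels[assignment == z])
  names(zones) <- vapply(scheme, `[[`, "", "name")
  structure(list(zones = zones, assignment = assignment),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  for (z in names(x$zones))
    cat(z, " (", length(x$zones[[z]]), "): ",
        paste(x$zones[[z]], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Simple paths and reachability between two states
#'
#' @inheritParams as_igraph
#' @param source,target state vectors or canonical labels.
#' @param max_length maximum number of transitions in an enumerated
#'   path; reachability is decided by full search regardless.
#' @return list with `paths` (list of label vectors, each a simple path
#'   including both endpoints; the trivial empty path when
#'   `source == target`) and `reachable` (logical).
#' @export
find_paths <- function(graph, source, target, max_length = 10L) {
  lab_s <- if (is.character(source)) source else state_label(source)
  lab_t <- if (is.character(target)) target else state_label(target)
  i <- match(lab_s, graph$labels); j <- match(lab_t, graph$labels)
  if (is.na(i)) stop("source state ", lab_s, " not in graph")
  if (is.na(j)) stop("target state ", lab_t, " not in graph")
  if (i == j)
    return(list(paths = list(lab_s), reachable = TRUE))
  ig <- as_igraph(graph)
  d <- igraph::distances(ig, v = i, to = j, mode = "out")[1, 1]
  reach <- is.finite(d)
  paths <- if (reach && max_length > 0L) {
    sp <- igraph::all_simple_paths(ig, from = i, to = j, mode = "out",
                                   cutoff = max_length)
    lapply(sp, function(p) graph$labels[as.integer(p)])
  } else list()
  list(paths = paths, reachable = reach)
}

#' Structured analysis report for a state graph
#'
#' Bundles deadlocks, the elementary-cycle census, the zone partition
#' and optional reachability queries into one JSON-serializable list.
#'
#' @inheritParams classify_zones
#' @param reachability optional list of `c(source_label, target_label)`
#'   pairs to test.
#' @param max_cycles passed to [enumerate_elementary_cycles()].
#' @return a named list report.
#' @export
analyze_state_graph <- function(graph, scheme = NULL, reachability = NULL,
                                max_cycles = 100000) {
  cycles <- enumerate_elementary_cycles(graph, max_cycles = max_cycles)
  rep <- list(
    n_states = nrow(graph$states),
    n_transitions = nrow(graph$edges),
    deadlocks = find_deadlocks(graph),
    n_cycles = length(cycles),
    cycles = cycles)
  if (!is.null(scheme)) {
    zp <- classify_zones(graph, scheme)
    rep$zones <- zp$zones
    zone_of <- stats::setNames(zp$assignment, graph$labels)
    rep$cycle_zones <- lapply(cycles, function(cy)
      sort(unique(unname(zone_of[cy]))))
  }
  if (!is.null(reachability)) {
    rep$reachability <- lapply(reachability, function(q) {
      r <- find_paths(graph, q[1], q[2], max_length = 0L)
      list(from = q[1], to = q[2], reachable = r$reachable)
    })
  }
  rep
}
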