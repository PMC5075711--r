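#' Constraints on the logical-parameter search space
#'
#' @param monotonicity Snoussi-style monotonicity: adding a resource
#'   never lowers the target level (`K(R1) <= K(R2)` whenever
#'   `R1` is a subset of `R2`).
#' @param observability every regulator must change some K value.
#' @param value_bounds optional named list of `c(min, max)` per entity.
#' @return an object of class `"synthesis_constraints"`.
#' @export
synthesis_constraints <- function(monotonicity = FALSE,
                                  observability = FALSE,
                                  value_bounds = NULL) {
  structure(list(monotonicity = isTRUE(monotonicity),
                 observability = isTRUE(observability),
                 value_bounds = value_bounds),
            class = "synthesis_constraints")
}

# all admissible K tables for one entity, one row per table, columns in
# bitmask order over the sorted predecessor names
entity_tables <- function(x, entity, constraints = synthesis_constraints()) {
  preds <- sort(unique(x$interactions$source[
    x$interactions$target == entity]))
  np <- length(preds)
  maxl <- x$entities$max_level[match(entity, x$entities$name)]
  lo <- 0L; hi <- maxl
  vb <- constraints$value_bounds[[entity]]
  if (!is.null(vb)) { lo <- max(lo, vb[1]); hi <- min(hi, vb[2]) }
  vals <- lo:hi
  nslots <- 2L^np
  tabs <- as.matrix(expand.grid(rev(rep(list(vals), nslots)),
                                KEEP.OUT.ATTRS = FALSE))[,
                      rev(seq_len(nslots)), drop = FALSE]
  storage.mode(tabs) <- "integer"
  dimnames(tabs) <- NULL
  keep <- rep(TRUE, nrow(tabs))
  if (constraints$monotonicity && np > 0L) {
    for (b1 in 0:(nslots - 1L)) for (p in seq_len(np)) {
      bit <- 2L^(p - 1L)
      if (bitwAnd(b1, bit) == 0L) {
        b2 <- bitwOr(b1, bit)
        keep <- keep & (tabs[, b1 + 1L] <= tabs[, b2 + 1L])
      }
    }
  }
  if (constraints$observability && np > 0L) {
    for (p in seq_len(np)) {
      bit <- 2L^(p - 1L)
      changes <- rep(FALSE, nrow(tabs))
      for (b1 in 0:(nslots - 1L)) if (bitwAnd(b1, bit) == 0L)
        changes <- changes | (tabs[, b1 + 1L] != tabs[, bitwOr(b1, bit) + 1L])
      keep <- keep & changes
    }
  }
  tabs[keep, , drop = FALSE]
}

#' Count admissible parameterizations
#'
#' The candidate space factorizes over entities, so the count is the
#' product of per-entity admissible table counts (both monotonicity and
#' observability are per-entity properties).
#'
#' @param x a [brn()] object.
#' @param constraints a [synthesis_constraints()].
#' @return numeric count (may exceed integer range).
#' @export
count_parameterizations <- function(x, constraints = synthesis_constraints()) {
  prod(vapply(x$entities$name, function(e)
    nrow(entity_tables(x, e, constraints)), numeric(1)))
}

#' Enumerate parameterizations as a lazy stream
#'
#' Candidates are produced in deterministic lexicographic order over
#' (entities in declaration order, resource sets in canonical subset
#' order, values ascending); the last entity's table varies fastest.
#'
#' @inheritParams count_parameterizations
#' @param cap refuse to enumerate more candidates than this.
#' @return an object of class `"param_stream"` with fields `count` and
#'   `next_value()`, which returns the next [parameterization()] or
#'   `NULL` when exhausted.
#' @examples
#' net <- brn(c("a", "b"),
#'            data.frame(source = "a", target = "b", sign = "+"))
#' s <- enumerate_parameterizations(net)
#' s$count  # 2 tables for the input entity x 4 for its target
#' @export
enumerate_parameterizations <- function(x,
                                        constraints = synthesis_constraints(),
                                        cap = 2^21) {
  total <- count_parameterizations(x, constraints)
  if (total > cap)
    stop("parameterization space has ", format(total, big.mark = ","),
         " candidates, exceeding cap = ", cap)
  tpl <- state_space_template(x)
  tabs <- lapply(x$entities$name, function(e)
    entity_tables(x, e, constraints))
  sizes <- vapply(tabs, nrow, integer(1))
  ne <- length(tabs)
  env <- new.env(parent = emptyenv())
  env$digit <- rep(1L, ne)
  env$done <- any(sizes == 0L)
  next_kvec <- function() {
    if (env$done) return(NULL)
    kv <- unlist(lapply(seq_len(ne), function(j)
      tabs[[j]][env$digit[j], ]), use.names = FALSE)
    # odometer increment, last entity fastest
    j <- ne
    repeat {
      if (j == 0L) { env$done <- TRUE; break }
      if (env$digit[j] < sizes[j]) {
        env$digit[j] <- env$digit[j] + 1L
        break
      }
      env$digit[j] <- 1L
      j <- j - 1L
    }
    kv
  }
  structure(list(count = total,
                 next_value = function() {
                   kv <- next_kvec()
                   if (is.null(kv)) NULL else vector_to_param(tpl, kv)
                 },
                 next_kvec = next_kvec,
                 template = tpl),
            class = "param_stream")
}

#' Filter parameterizations by CTL properties
#'
#' Re-implements the SMBioNet workflow: enumerate every admissible
#' parameterization of the network, build each candidate's asynchronous
#' state graph, and keep the candidates whose graph satisfies all the
#' given CTL formulas.
#'
#' @inheritParams enumerate_parameterizations
#' @param formulas list of [parse_ctl()] formulas (or formula strings).
#' @param mode `"initial"`: every formula must hold in each state of
#'   `initial_states`; `"all"`: every formula must hold in every state.
#' @param initial_states matrix/vector of states (or labels) for
#'   `mode = "initial"`; defaults to the all-zero state.
#' @param progress report progress every this many candidates
#'   (0 = silent).
#' @return an object of class `"synthesis_result"`: `accepted_kvec`
#'   (matrix, one row per accepted candidate in enumeration order),
#'   `tested_count`, `accepted_count`, `formulas`, `mode`, and
#'   `get_accepted(i)` returning the i-th accepted [parameterization()].
#' @export
filter_by_ctl <- function(x, formulas,
                          constraints = synthesis_constraints(),
                          mode = c("initial", "all"),
                          initial_states = NULL,
                          cap = 2^21, progress = 0) {
  mode <- match.arg(mode)
  if (!length(formulas)) stop("no CTL formulas supplied")
  formulas <- lapply(formulas, function(f)
    if (is.character(f)) parse_ctl(f) else f)
  stream <- enumerate_parameterizations(x, constraints, cap)
  tpl <- stream$template
  n <- nrow(tpl$states)
  if (mode == "initial") {
    if (is.null(initial_states))
      initial_states <- matrix(0L, 1, length(tpl$entities))
    if (is.character(initial_states))
      initial_states <- parse_state(initial_states)
    if (!is.matrix(initial_states))
      initial_states <- matrix(initial_states, nrow = 1)
    init_idx <- match(state_label(initial_states), tpl$labels)
    if (anyNA(init_idx)) stop("initial state outside the state space")
  }
  accepted <- list()
  tested <- 0L
  repeat {
    kv <- stream$next_kvec()
    if (is.null(kv)) break
    tested <- tested + 1L
    if (progress > 0 && tested %% progress == 0)
      message("synthesis: tested ", tested, " / ", stream$count,
              " candidates, accepted ", length(accepted))
    edges <- template_edges(tpl, kv)
    ok <- TRUE
    for (f in formulas) {
      sat <- ctl_eval(f, tpl$states, edges[, 1], edges[, 2], tpl$entities)
      hold <- if (mode == "all") all(sat) else all(sat[init_idx])
      if (!hold) { ok <- FALSE; break }
    }
    if (ok) accepted[[length(accepted) + 1L]] <- kv
  }
  acc <- if (length(accepted)) do.call(rbind, accepted) else
    matrix(integer(0), 0, sum(tpl$slot_sizes))
  structure(list(accepted_kvec = acc,
                 tested_count = tested,
                 accepted_count = nrow(acc),
                 formulas = formulas,
                 mode = mode,
                 get_accepted = function(i) vector_to_param(tpl, acc[i, ])),
            class = "synthesis_result")
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat("CTL parameter synthesis:", x$accepted_count, "of", x$tested_count,
      "candidates accepted (mode:", x$mode, ")\n")
  cat("formulas:\n")
  for (f in x$formulas) cat("  ", format(f), "\n")
  invisible(x)
}

#' Is a parameterization among the accepted candidates?
#'
#' @param result a [filter_by_ctl()] result.
#' @param x the [brn()] the synthesis ran on.
#' @param k a [parameterization()] to look up.
#' @return logical scalar.
#' @export
synthesis_contains <- function(result, x, k) {
  kv <- param_to_vector(x, k)
  any(apply(result$accepted_kvec, 1, function(r) all(r == kv)))
}
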