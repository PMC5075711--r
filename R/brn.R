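#' Biological regulatory network (BRN) objects
#'
#' A BRN is a labeled directed graph: entities carry a maximum discrete
#' level, and each interaction carries an integer threshold and a sign
#' ("+" activation, "-" inhibition). Dynamics follow the kinetic-logic
#' (Thomas) formalism: each entity evolves one unit at a time toward the
#' target level prescribed by its current resource set.
#'
#' @param entities a character vector of entity names (all Boolean,
#'   `max_level = 1`) or a data.frame with columns `name` and `max_level`.
#' @param interactions a data.frame with columns `source`, `target`,
#'   `sign` ("+" or "-") and optionally `threshold` (default 1).
#' @param validate if `TRUE` (default) stop when [validate_brn()] finds
#'   violations.
#' @return an object of class `"brn"` with elements `entities`
#'   (data.frame `name`, `max_level`) and `interactions` (data.frame
#'   `source`, `target`, `sign`, `threshold`).
#' @examples
#' net <- brn(c("a", "b"),
#'            data.frame(source = c("a", "b"), target = c("b", "a"),
#'                       sign = c("+", "-")))
#' @export
brn <- function(entities, interactions = NULL, validate = TRUE) {
  if (is.character(entities)) {
    entities <- data.frame(name = entities, max_level = 1L,
                           stringsAsFactors = FALSE)
  }
  entities <- data.frame(name = as.character(entities$name),
                         max_level = as.integer(entities$max_level),
                         stringsAsFactors = FALSE)
  if (is.null(interactions)) {
    interactions <- data.frame(source = character(0), target = character(0),
                               sign = character(0), threshold = integer(0),
                               stringsAsFactors = FALSE)
  }
  if (is.null(interactions$threshold)) interactions$threshold <- 1L
  interactions <- data.frame(source = as.character(interactions$source),
                             target = as.character(interactions$target),
                             sign = as.character(interactions$sign),
                             threshold = as.integer(interactions$threshold),
                             stringsAsFactors = FALSE)
  x <- structure(list(entities = entities, interactions = interactions),
                 class = "brn")
  if (validate) {
    v <- validate_brn(x)
    if (length(v)) stop("invalid BRN:\n  ", paste(v, collapse = "\n  "))
  }
  x
}

#' @export
print.brn <- function(x, ...) {
  cat("BRN with", nrow(x$entities), "entities and",
      nrow(x$interactions), "interactions\n")
  cat("entities:", paste0(x$entities$name, " (0..", x$entities$max_level, ")",
                          collapse = ", "), "\n")
  if (nrow(x$interactions)) {
    cat("interactions:\n")
    with(x$interactions,
         cat(paste0("  ", source, " -", sign, "(", threshold, ")-> ", target,
                    collapse = "\n"), "\n"))
  }
  invisible(x)
}

#' Validate a BRN
#'
#' Checks the structural invariants of the kinetic-logic formalism:
#' unique entity names, `max_level >= 1`, interaction endpoints declared,
#' thresholds within `1..max_level(source)`, at most one interaction per
#' ordered (source, target) pair, and the bound that the number of
#' distinct thresholds leaving an entity does not exceed its out-degree.
#'
#' @param x a [brn()] object (possibly built with `validate = FALSE`).
#' @return a character vector of violation messages; empty when valid.
#' @export
validate_brn <- function(x) {
  v <- character(0)
  ent <- x$entities; int <- x$interactions
  if (anyDuplicated(ent$name))
    v <- c(v, paste0("duplicate entity names: ",
                     paste(unique(ent$name[duplicated(ent$name)]),
                           collapse = ", ")))
  bad <- which(is.na(ent$max_level) | ent$max_level < 1L)
  for (i in bad)
    v <- c(v, paste0("entity '", ent$name[i], "' has max_level < 1"))
  if (nrow(int)) {
    known <- ent$name
    for (i in seq_len(nrow(int))) {
      if (!(int$source[i] %in% known))
        v <- c(v, paste0("interaction ", i, ": unknown source '",
                         int$source[i], "'"))
      if (!(int$target[i] %in% known))
        v <- c(v, paste0("interaction ", i, ": unknown target '",
                         int$target[i], "'"))
      if (!(int$sign[i] %in% c("+", "-")))
        v <- c(v, paste0("interaction ", int$source[i], "->", int$target[i],
                         ": sign must be '+' or '-'"))
      if (int$source[i] %in% known) {
        rmax <- ent$max_level[match(int$source[i], known)]
        if (is.na(int$threshold[i]) || int$threshold[i] < 1L ||
            int$threshold[i] > rmax)
          v <- c(v, paste0("interaction ", int$source[i], "->", int$target[i],
                           ": threshold ", int$threshold[i],
                           " outside 1..", rmax))
      }
    }
    key <- paste(int$source, int$target, sep = "\r")
    if (anyDuplicated(key)) {
      dups <- unique(key[duplicated(key)])
      for (d in dups) {
        p <- strsplit(d, "\r", fixed = TRUE)[[1]]
        v <- c(v, paste0("duplicate interaction ", p[1], " -> ", p[2]))
      }
    }
    # distinct thresholds leaving an entity bounded by its out-degree
    for (nm in unique(int$source)) {
      out <- int[int$source == nm, , drop = FALSE]
      if (length(unique(out$threshold)) > nrow(out))
        v <- c(v, paste0("entity '", nm, "': more distinct thresholds than ",
                         "outgoing interactions"))
    }
  }
  v
}

#' Predecessors (regulators) of an entity
#'
#' @param x a [brn()] object.
#' @param entity entity name.
#' @return data.frame of interactions targeting `entity`.
#' @export
predecessors <- function(x, entity) {
  stop_unknown_entity(x, entity)
  x$interactions[x$interactions$target == entity, , drop = FALSE]
}

stop_unknown_entity <- function(x, entity) {
  if (!(entity %in% x$entities$name))
    stop("unknown entity '", entity, "'")
  invisible(TRUE)
}

check_state <- function(x, state) {
  n <- nrow(x$entities)
  if (length(state) != n)
    stop("state has length ", length(state), ", expected ", n)
  state <- as.integer(state)
  if (any(state < 0L) || any(state > x$entities$max_level))
    stop("state levels outside entity bounds")
  state
}

#' Canonical resource-set key
#'
#' Resource sets are identified by the sorted, comma-separated member
#' names in braces, e.g. `"{BRCA1,ER}"`; the empty set is `"{}"`.
#'
#' @param members character vector of entity names (may be empty).
#' @return a single string key.
#' @export
resource_key <- function(members) {
  paste0("{", paste(sort(members), collapse = ","), "}")
}

#' Resources of an entity in a state
#'
#' A predecessor is a resource when it currently "helps" the entity:
#' an activator at or above its threshold, or an inhibitor below its
#' threshold (absence of an inhibitor is a resource).
#'
#' @inheritParams predecessors
#' @param state integer vector of levels, one per entity in declaration
#'   order.
#' @return sorted character vector of resource entity names.
#' @export
compute_resources <- function(x, state, entity) {
  stop_unknown_entity(x, entity)
  state <- check_state(x, state)
  p <- predecessors(x, entity)
  if (!nrow(p)) return(character(0))
  lev <- state[match(p$source, x$entities$name)]
  sort(p$source[(p$sign == "+" & lev >= p$threshold) |
                (p$sign == "-" & lev < p$threshold)])
}

#' Logical parameterization
#'
#' The complete map K from (entity, resource set) to the discrete level
#' the entity tends toward. The table must be total: one entry per
#' entity per subset of its predecessors.
#'
#' @param x a [brn()] object.
#' @param table named list, one element per entity; each element a named
#'   integer vector whose names are [resource_key()] strings.
#' @return an object of class `"parameterization"`.
#' @export
parameterization <- function(x, table) {
  ents <- x$entities$name
  missing_ent <- setdiff(ents, names(table))
  if (length(missing_ent))
    stop("parameterization missing entities: ",
         paste(missing_ent, collapse = ", "))
  errs <- character(0)
  out <- vector("list", length(ents)); names(out) <- ents
  for (e in ents) {
    keys <- resource_subset_keys(x, e)
    tab <- table[[e]]
    miss <- setdiff(keys, names(tab))
    if (length(miss))
      errs <- c(errs, paste0("entity '", e, "': missing K for ",
                             paste(miss, collapse = ", ")))
    extra <- setdiff(names(tab), keys)
    if (length(extra))
      errs <- c(errs, paste0("entity '", e, "': K for non-subset ",
                             paste(extra, collapse = ", ")))
    rmax <- x$entities$max_level[match(e, ents)]
    bad <- tab[!is.na(tab) & (tab < 0L | tab > rmax)]
    if (length(bad))
      errs <- c(errs, paste0("entity '", e, "': K value outside 0..", rmax))
    vals <- tab[keys]  # NA where missing; totality errors reported above
    names(vals) <- keys
    out[[e]] <- vapply(vals, as.integer, integer(1))
  }
  if (length(errs)) stop("invalid parameterization:\n  ",
                         paste(errs, collapse = "\n  "))
  structure(out, class = "parameterization")
}

#' @export
print.parameterization <- function(x, ...) {
  for (e in names(x)) {
    cat(e, ":\n", sep = "")
    cat(paste0("  K_", names(x[[e]]), " = ", x[[e]], collapse = "\n"), "\n")
  }
  invisible(x)
}

# all subset keys of entity's predecessors, in bitmask order over the
# sorted predecessor names (deterministic enumeration order)
resource_subset_keys <- function(x, entity) {
  preds <- sort(unique(x$interactions$source[
    x$interactions$target == entity]))
  k <- length(preds)
  vapply(0:(2^k - 1), function(b) {
    resource_key(preds[bitwAnd(b, 2^(seq_len(k) - 1)) > 0])
  }, character(1))
}

#' Target level of an entity in a state
#'
#' Looks up the logical parameter K for the entity's current resource
#' set; the entity evolves one discrete step toward this level.
#'
#' @inheritParams compute_resources
#' @param k a [parameterization()].
#' @return integer target level in `0..max_level(entity)`.
#' @export
target_level <- function(x, k, state, entity) {
  res <- compute_resources(x, state, entity)
  key <- resource_key(res)
  val <- k[[entity]][key]
  if (is.na(val))
    stop("parameterization not total: no K for entity '", entity,
         "', resources ", key)
  unname(val)
}

#' Asynchronous successors of a state
#'
#' One successor per entity whose level differs from its target level;
#' the successor changes that entity by exactly one unit toward the
#' target. A state with no successors is a fixed point (deadlock).
#'
#' @inheritParams target_level
#' @return integer matrix, one row per successor state (0 rows at a
#'   fixed point); columns named by entity.
#' @export
successors <- function(x, k, state) {
  state <- check_state(x, state)
  ents <- x$entities$name
  out <- list()
  for (j in seq_along(ents)) {
    tg <- target_level(x, k, state, ents[j])
    if (state[j] != tg) {
      s2 <- state
      s2[j] <- state[j] + sign(tg - state[j])
      out[[length(out) + 1L]] <- s2
    }
  }
  m <- if (length(out)) do.call(rbind, out) else
    matrix(integer(0), nrow = 0, ncol = length(ents))
  colnames(m) <- ents
  m
}

#' Canonical label of a state
#'
#' @param state integer vector of levels.
#' @return string of the form `"(v1,v2,...)"`.
#' @export
state_label <- function(state) {
  if (is.matrix(state))
    apply(state, 1, function(r) paste0("(", paste(r, collapse = ","), ")"))
  else paste0("(", paste(state, collapse = ","), ")")
}

#' Parse a canonical state label
#'
#' @param label string like `"(0,1,0,0,1)"` (or several).
#' @return integer vector (or matrix, one row per label).
#' @export
parse_state <- function(label) {
  p <- lapply(label, function(s)
    as.integer(strsplit(gsub("[()]", "", s), ",")[[1]]))
  if (length(p) == 1L) p[[1]] else do.call(rbind, p)
}

#' Build the asynchronous state graph
#'
#' Enumerates the full product state space and the unit-step
#' asynchronous transition relation.
#'
#' @inheritParams target_level
#' @param max_states guard against combinatorial blow-up; building a
#'   graph with more states than this is an error.
#' @return an object of class `"state_graph"`: `states` (integer matrix,
#'   one row per state), `labels`, `edges` (2-column integer matrix of
#'   state indices), `entities`, `max_levels`, and `adj` (successor
#'   index list).
#' @export
build_state_graph <- function(x, k, max_states = 2^20) {
  tpl <- state_space_template(x)
  n <- nrow(tpl$states)
  if (n > max_states)
    stop("state space has ", n, " states, exceeding max_states = ",
         max_states)
  kvec <- param_to_vector(x, k)
  edges <- template_edges(tpl, kvec)
  new_state_graph(tpl, edges)
}

new_state_graph <- function(tpl, edges) {
  n <- nrow(tpl$states)
  adj <- split(edges[, 2], factor(edges[, 1], levels = seq_len(n)))
  adj <- lapply(adj, as.integer)
  structure(list(states = tpl$states, labels = tpl$labels, edges = edges,
                 entities = tpl$entities, max_levels = tpl$max_levels,
                 adj = adj),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat("asynchronous state graph:", nrow(x$states), "states,",
      nrow(x$edges), "transitions\n")
  cat("entities:", paste(x$entities, collapse = ", "), "\n")
  invisible(x)
}

# ---- fast internal machinery shared with parameter synthesis ----

# Precompute, once per BRN, everything that does not depend on K:
# the full state space, per-entity resource-set index of every state,
# slot offsets into a flat K vector, and index strides for unit steps.
state_space_template <- function(x) {
  ents <- x$entities$name
  maxl <- x$entities$max_level
  grid <- expand.grid(rev(lapply(maxl, function(m) 0:m)),
                      KEEP.OUT.ATTRS = FALSE)
  states <- as.matrix(grid[, rev(seq_along(ents)), drop = FALSE])
  dimnames(states) <- list(NULL, ents)
  storage.mode(states) <- "integer"
  n <- nrow(states)
  # index arithmetic: state index = 1 + sum_j level_j * stride_j
  strides <- integer(length(ents))
  s <- 1L
  for (j in rev(seq_along(ents))) { strides[j] <- s; s <- s * (maxl[j] + 1L) }
  # per-entity: resource-set slot (1-based, bitmask order over sorted preds)
  res_idx <- matrix(1L, n, length(ents))
  slot_sizes <- integer(length(ents))
  for (j in seq_along(ents)) {
    p <- x$interactions[x$interactions$target == ents[j], , drop = FALSE]
    preds <- sort(unique(p$source))
    slot_sizes[j] <- 2L^length(preds)
    if (length(preds)) {
      b <- integer(n)
      for (kk in seq_along(preds)) {
        pi <- match(preds[kk], ents)
        row <- p[p$source == preds[kk], ]
        is_res <- if (row$sign == "+") states[, pi] >= row$threshold
                  else states[, pi] < row$threshold
        b <- b + as.integer(is_res) * 2L^(kk - 1L)
      }
      res_idx[, j] <- b + 1L
    }
  }
  offsets <- c(0L, cumsum(slot_sizes))[seq_along(ents)]
  keys <- lapply(ents, function(e) resource_subset_keys(x, e))
  list(states = states, labels = state_label(states), entities = ents,
       max_levels = maxl, strides = strides, res_idx = res_idx,
       slot_sizes = slot_sizes, offsets = offsets, keys = keys)
}

# flatten a parameterization into the template's K-vector layout
param_to_vector <- function(x, k) {
  ents <- x$entities$name
  unlist(lapply(seq_along(ents), function(j) {
    keys <- resource_subset_keys(x, ents[j])
    vals <- k[[ents[j]]][keys]
    if (anyNA(vals)) stop("parameterization not total for '", ents[j], "'")
    as.integer(vals)
  }), use.names = FALSE)
}

vector_to_param <- function(tpl, kvec) {
  out <- vector("list", length(tpl$entities))
  names(out) <- tpl$entities
  for (j in seq_along(tpl$entities)) {
    idx <- tpl$offsets[j] + seq_len(tpl$slot_sizes[j])
    v <- as.integer(kvec[idx])
    names(v) <- tpl$keys[[j]]
    out[[j]] <- v
  }
  structure(out, class = "parameterization")
}

# asynchronous unit-step edges for one flat K vector (vectorized over
# the whole state space; the hot path of parameter synthesis)
template_edges <- function(tpl, kvec) {
  n <- nrow(tpl$states)
  from <- integer(0); to <- integer(0)
  for (j in seq_along(tpl$entities)) {
    tg <- kvec[tpl$offsets[j] + tpl$res_idx[, j]]
    lev <- tpl$states[, j]
    mv <- which(lev != tg)
    if (length(mv)) {
      step <- sign(tg[mv] - lev[mv]) * tpl$strides[j]
      from <- c(from, mv)
      to <- c(to, mv + step)
    }
  }
  cbind(from = from, to = to)
}
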