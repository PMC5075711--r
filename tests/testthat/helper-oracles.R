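# Independent brute-force oracles. These re-derive expected results by
# direct definition-chasing, on small inputs only, and deliberately share
# no code with the package implementations they check.

# literal application of the evolution rules: for every entity, recompute
# the resource set by scanning the interaction table, look the target up
# in the parameter table, and move one step toward it
oracle_successors <- function(x, k, state) {
  ents <- x$entities$name
  out <- list()
  for (j in seq_along(ents)) {
    e <- ents[j]
    res <- character(0)
    for (i in seq_len(nrow(x$interactions))) {
      row <- x$interactions[i, ]
      if (row$target != e) next
      lev <- state[match(row$source, ents)]
      helping <- if (row$sign == "+") lev >= row$threshold
                 else lev < row$threshold
      if (helping) res <- c(res, row$source)
    }
    key <- paste0("{", paste(sort(res), collapse = ","), "}")
    tgt <- unname(k[[e]][key])
    if (state[j] < tgt) {
      s2 <- state; s2[j] <- state[j] + 1L
      out[[length(out) + 1L]] <- s2
    } else if (state[j] > tgt) {
      s2 <- state; s2[j] <- state[j] - 1L
      out[[length(out) + 1L]] <- s2
    }
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), 0, length(ents))
}

# all elementary cycles by enumerating every rotation from every start
# vertex, then deduplicating canonical forms (independent of the
# min-vertex-rooted enumeration in the package)
oracle_cycles <- function(n, edges) {
  adj <- lapply(seq_len(n), function(v) edges[edges[, 1] == v, 2])
  seen <- new.env(parent = emptyenv())
  count <- 0L
  for (s in seq_len(n)) {
    path <- integer(0)
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      for (w in adj[[v]]) {
        if (w == s) {
          rot <- which.min(path)
          canon <- paste(c(path[rot:length(path)],
                           path[seq_len(rot - 1L)]), collapse = "-")
          if (is.null(seen[[canon]])) {
            seen[[canon]] <- TRUE
            count <<- count + 1L
          }
        } else if (!(w %in% path)) dfs(w)
      }
      path <<- path[-length(path)]
    }
    dfs(s)
  }
  count
}

# naive path-search CTL semantics on an adjacency list (maximal-path
# convention: a path ending in a deadlock is a full path)
oracle_ctl <- function(op, phi, psi = NULL, adj) {
  n <- length(adj)
  deadlock <- lengths(adj) == 0L
  reach_from <- function(s) {  # states reachable from s (excluding s unless revisited)
    seen <- logical(n); stack <- adj[[s]]
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!seen[v]) { seen[v] <- TRUE; stack <- c(stack, adj[[v]]) }
    }
    seen
  }
  switch(op,
    EX = vapply(seq_len(n), function(s) any(phi[adj[[s]]]), logical(1)),
    EF = vapply(seq_len(n), function(s)
      phi[s] || any(phi[reach_from(s)]), logical(1)),
    AG = vapply(seq_len(n), function(s)
      phi[s] && all(phi[which(reach_from(s))]), logical(1)),
    EG = {  # exists a maximal phi-path: cycle or deadlock inside phi
      res <- logical(n)
      for (s in seq_len(n)) {
        if (!phi[s]) next
        found <- FALSE
        onpath <- logical(n)
        dfs <- function(v) {
          if (found) return()
          onpath[v] <<- TRUE
          if (deadlock[v]) found <<- TRUE
          for (w in adj[[v]]) {
            if (found) break
            if (!phi[w]) next
            if (onpath[w]) found <<- TRUE else dfs(w)
          }
          onpath[v] <<- FALSE
        }
        dfs(s)
        res[s] <- found
      }
      res
    },
    AF = {  # every maximal path hits phi
      memo <- rep(NA, n)
      onpath <- logical(n)
      af <- function(s) {
        if (phi[s]) return(TRUE)
        if (!is.na(memo[s])) return(memo[s])
        if (onpath[s]) return(FALSE)  # a phi-avoiding cycle
        if (deadlock[s]) { memo[s] <<- FALSE; return(FALSE) }
        onpath[s] <<- TRUE
        r <- all(vapply(adj[[s]], af, logical(1)))
        onpath[s] <<- FALSE
        memo[s] <<- r
        r
      }
      vapply(seq_len(n), af, logical(1))
    },
    EU = {  # exists a psi-state reached through phi-states
      res <- logical(n)
      for (s in seq_len(n)) {
        seen <- logical(n)
        dfs <- function(v) {
          if (res[s]) return()
          if (psi[v]) { res[s] <<- TRUE; return() }
          if (!phi[v] || seen[v]) return()
          seen[v] <<- TRUE
          for (w in adj[[v]]) dfs(w)
        }
        dfs(s)
      }
      res
    },
    stop("no oracle for ", op))
}

graph_adj <- function(g) {
  n <- nrow(g$states)
  lapply(seq_len(n), function(v) g$edges[g$edges[, 1] == v, 2])
}

# a small random state graph (via a random network) for property tests
random_state_graph <- function(seed, n_entities = 3, max_level = 2) {
  x <- random_brn(n_entities, edge_density = 0.5, max_level = max_level,
                  seed = seed)
  k <- random_parameterization(x, monotone = (seed %% 2 == 0),
                               seed = seed + 1)
  build_state_graph(x, k)
}
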