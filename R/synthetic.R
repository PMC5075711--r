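# run expr with a private, seeded RNG stream; the caller's random state
# is untouched
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random multivalued BRN
#'
#' Generates a valid regulatory network with the structure the analysis
#' pipeline assumes: unique entity names, signed thresholded edges, and
#' (optionally) multivalued levels. Signs and thresholds are uniform
#' over their legal ranges.
#'
#' @param n_entities number of entities (>= 1).
#' @param edge_density fraction of the possible ordered pairs to wire
#'   (self-loops excluded unless `self_loops = TRUE`).
#' @param max_level maximum discrete level; each entity's bound is drawn
#'   uniformly from `1:max_level`.
#' @param seed integer seed (generation never touches the global random
#'   state).
#' @param self_loops allow self-regulation.
#' @return a [brn()].
#' @export
random_brn <- function(n_entities, edge_density = 0.3, max_level = 1,
                       seed = 1, self_loops = FALSE) {
  stopifnot(n_entities >= 1, edge_density >= 0, edge_density <= 1,
            max_level >= 1)
  with_seed(seed, {
    nm <- paste0("v", seq_len(n_entities))
    maxl <- if (max_level == 1) rep(1L, n_entities)
            else sample.int(max_level, n_entities, replace = TRUE)
    pairs <- expand.grid(source = nm, target = nm,
                         stringsAsFactors = FALSE)
    if (!self_loops) pairs <- pairs[pairs$source != pairs$target, ]
    n_edges <- round(edge_density * nrow(pairs))
    ints <- NULL
    if (n_edges > 0) {
      pick <- sort(sample.int(nrow(pairs), n_edges))
      ints <- pairs[pick, , drop = FALSE]
      src_max <- maxl[match(ints$source, nm)]
      ints$sign <- sample(c("+", "-"), n_edges, replace = TRUE)
      ints$threshold <- vapply(src_max, function(m)
        sample.int(m, 1), integer(1))
    }
    brn(data.frame(name = nm, max_level = maxl), ints)
  })
}

#' Random (optionally monotone) parameterization
#'
#' Draws a total logical-parameter table for a BRN. With
#' `monotone = TRUE` the table satisfies the Snoussi condition (adding a
#' resource never lowers the target): raw uniform draws are closed
#' upward by taking, for each resource set, the maximum over its
#' one-smaller subsets, so every monotone table remains reachable.
#'
#' @param x a [brn()].
#' @param monotone enforce monotonicity.
#' @param seed integer seed.
#' @return a [parameterization()].
#' @export
random_parameterization <- function(x, monotone = FALSE, seed = 1) {
  with_seed(seed, {
    tab <- list()
    for (e in x$entities$name) {
      keys <- resource_subset_keys(x, e)
      maxl <- x$entities$max_level[match(e, x$entities$name)]
      vals <- sample.int(maxl + 1L, length(keys), replace = TRUE) - 1L
      names(vals) <- keys
      if (monotone && length(keys) > 1L) {
        preds <- sort(unique(x$interactions$source[
          x$interactions$target == e]))
        np <- length(preds)
        masks <- 0:(2L^np - 1L)
        popcount <- vapply(masks, function(b)
          sum(bitwAnd(b, 2L^(0:(np - 1L))) > 0L), numeric(1))
        for (b in masks[order(popcount)]) {
          if (b == 0L) next
          subs <- vapply(seq_len(np), function(p) {
            bit <- 2L^(p - 1L)
            if (bitwAnd(b, bit)) bitwAnd(b, bitwNot(bit)) else NA_integer_
          }, integer(1))
          subs <- subs[!is.na(subs)]
          vals[b + 1L] <- max(vals[b + 1L], vals[subs + 1L])
        }
      }
      tab[[e]] <- vals
    }
    parameterization(x, tab)
  })
}

#' Canonical feedback motifs with known dynamics
#'
#' Small (BRN, parameterization) pairs whose asynchronous dynamics are
#' known in closed form, used as self-checking test inputs:
#' \describe{
#'   \item{positive-2-loop}{mutual inhibition; bistable, exactly two
#'     fixed points (1,0) and (0,1), no cycles.}
#'   \item{negative-2-loop}{activator/inhibitor pair; sustained
#'     oscillation, no fixed point, one elementary 4-cycle.}
#'   \item{input-chain}{an input entity driving a target; unique fixed
#'     point (1,1), no cycles.}
#'   \item{p53-mdm2-oscillator}{p53 activates Mdm2, Mdm2 inhibits p53
#'     (the case-study low-risk-zone sub-loop); the 4-state cycle
#'     (0,0) -> (1,0) -> (1,1) -> (0,1) -> (0,0).}
#' }
#'
#' @param name motif name.
#' @return list with `brn`, `parameterization` and `expect` (a record
#'   of machine-checkable dynamic properties: `n_fixed_points`,
#'   `n_cycles`, and optionally `cycle` as a label vector).
#' @export
motif <- function(name = c("positive-2-loop", "negative-2-loop",
                           "input-chain", "p53-mdm2-oscillator")) {
  name <- match.arg(name)
  switch(name,
    "positive-2-loop" = {
      x <- brn(c("a", "b"),
               data.frame(source = c("a", "b"), target = c("b", "a"),
                          sign = c("-", "-")))
      k <- parameterization(x, list(
        a = c("{}" = 0L, "{b}" = 1L),
        b = c("{}" = 0L, "{a}" = 1L)))
      list(brn = x, parameterization = k,
           expect = list(n_fixed_points = 2L, n_cycles = 0L,
                         fixed_points = c("(1,0)", "(0,1)")))
    },
    "negative-2-loop" = {
      x <- brn(c("a", "b"),
               data.frame(source = c("a", "b"), target = c("b", "a"),
                          sign = c("+", "-")))
      k <- parameterization(x, list(
        a = c("{}" = 0L, "{b}" = 1L),
        b = c("{}" = 0L, "{a}" = 1L)))
      list(brn = x, parameterization = k,
           expect = list(n_fixed_points = 0L, n_cycles = 1L,
                         cycle = c("(0,0)", "(1,0)", "(1,1)", "(0,1)")))
    },
    "input-chain" = {
      x <- brn(c("a", "b"),
               data.frame(source = "a", target = "b", sign = "+"))
      k <- parameterization(x, list(
        a = c("{}" = 1L),
        b = c("{}" = 0L, "{a}" = 1L)))
      list(brn = x, parameterization = k,
           expect = list(n_fixed_points = 1L, n_cycles = 0L,
                         fixed_points = "(1,1)"))
    },
    "p53-mdm2-oscillator" = {
      x <- brn(c("p53", "Mdm2"),
               data.frame(source = c("p53", "Mdm2"),
                          target = c("Mdm2", "p53"),
                          sign = c("+", "-")))
      k <- parameterization(x, list(
        p53 = c("{}" = 0L, "{Mdm2}" = 1L),
        Mdm2 = c("{}" = 0L, "{p53}" = 1L)))
      list(brn = x, parameterization = k,
           expect = list(n_fixed_points = 0L, n_cycles = 1L,
                         cycle = c("(0,0)", "(1,0)", "(1,1)", "(0,1)")))
    })
}
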