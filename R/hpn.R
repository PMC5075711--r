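#' Continuous (hybrid) Petri net models
#'
#' Places hold non-negative real markings; transitions fire continuously
#' at mass-action rates. Arcs are `normal` (consumed/produced), `test`
#' (read-only input: contributes to the rate but is not consumed) or
#' `inhibitory` (gates the transition off once the source place's
#' marking reaches the arc weight). Rate of a transition =
#' `rate_constant * prod(marking(normal/test inputs) ^ weight)`, gated
#' to zero by any active inhibitory input.
#'
#' @param places data.frame with columns `name`, `kind`
#'   ("continuous"/"discrete") and `marking` (initial, >= 0).
#' @param transitions data.frame with columns `name` and `rate` (> 0).
#' @param arcs data.frame with columns `from`, `to`, `kind`
#'   ("normal"/"test"/"inhibitory") and `weight` (> 0). Each arc joins a
#'   place and a transition; test and inhibitory arcs must run
#'   place -> transition.
#' @param name model name.
#' @param variant free-text variant tag (e.g. "homeostatic").
#' @return an object of class `"hpn_model"`.
#' @export
hpn_model <- function(places, transitions, arcs, name = "hpn",
                      variant = NULL) {
  places <- data.frame(name = as.character(places$name),
                       kind = if (is.null(places$kind)) "continuous"
                              else as.character(places$kind),
                       marking = as.numeric(places$marking),
                       stringsAsFactors = FALSE)
  transitions <- data.frame(name = as.character(transitions$name),
                            rate = as.numeric(transitions$rate),
                            stringsAsFactors = FALSE)
  arcs <- data.frame(from = as.character(arcs$from),
                     to = as.character(arcs$to),
                     kind = as.character(arcs$kind),
                     weight = if (is.null(arcs$weight)) 1
                              else as.numeric(arcs$weight),
                     stringsAsFactors = FALSE)
  errs <- character(0)
  if (anyDuplicated(places$name)) errs <- c(errs, "duplicate place names")
  if (anyDuplicated(transitions$name))
    errs <- c(errs, "duplicate transition names")
  if (any(places$marking < 0)) errs <- c(errs, "negative initial marking")
  if (any(transitions$rate <= 0)) errs <- c(errs, "non-positive rate")
  if (any(arcs$weight <= 0)) errs <- c(errs, "non-positive arc weight")
  for (i in seq_len(nrow(arcs))) {
    fp <- arcs$from[i] %in% places$name
    ft <- arcs$from[i] %in% transitions$name
    tp <- arcs$to[i] %in% places$name
    tt <- arcs$to[i] %in% transitions$name
    if (!(fp && tt) && !(ft && tp))
      errs <- c(errs, paste0("arc ", arcs$from[i], " -> ", arcs$to[i],
                             " does not join a place and a transition"))
    if (arcs$kind[i] %in% c("test", "inhibitory") && !(fp && tt))
      errs <- c(errs, paste0(arcs$kind[i], " arc ", arcs$from[i], " -> ",
                             arcs$to[i], " must run place -> transition"))
    if (!arcs$kind[i] %in% c("normal", "test", "inhibitory"))
      errs <- c(errs, paste0("unknown arc kind '", arcs$kind[i], "'"))
  }
  if (length(errs)) stop("invalid HPN model:\n  ",
                         paste(errs, collapse = "\n  "))
  structure(list(places = places, transitions = transitions, arcs = arcs,
                 name = name, variant = variant),
            class = "hpn_model")
}

#' @export
print.hpn_model <- function(x, ...) {
  cat("HPN model '", x$name, "'",
      if (!is.null(x$variant)) paste0(" (", x$variant, ")"), ": ",
      nrow(x$places), " places, ", nrow(x$transitions), " transitions, ",
      nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

# index structure shared by both engines
hpn_compile <- function(model) {
  pn <- model$places$name
  tn <- model$transitions$name
  lapply(seq_along(tn), function(j) {
    a <- model$arcs
    inp <- a[a$to == tn[j] & a$kind %in% c("normal", "test"), , drop = FALSE]
    inh <- a[a$to == tn[j] & a$kind == "inhibitory", , drop = FALSE]
    outp <- a[a$from == tn[j], , drop = FALSE]
    list(rate = model$transitions$rate[j],
         in_idx = match(inp$from, pn), in_w = inp$weight,
         consume = inp$kind == "normal",
         inh_idx = match(inh$from, pn), inh_w = inh$weight,
         out_idx = match(outp$to, pn), out_w = outp$weight)
  })
}

hpn_rates <- function(tr, x, smooth_gate = FALSE, steep = 50) {
  vapply(tr, function(t) {
    r <- t$rate
    if (length(t$in_idx))
      r <- r * prod(pmax(x[t$in_idx], 0)^t$in_w)
    if (length(t$inh_idx)) {
      if (smooth_gate)
        r <- r * prod(1 / (1 + exp(steep * (x[t$inh_idx] - t$inh_w))))
      else if (any(x[t$inh_idx] >= t$inh_w)) r <- 0
    }
    r
  }, numeric(1))
}

#' Deterministic (ODE) simulation of a continuous Petri net
#'
#' Integrates the mass-action rate equations with `deSolve::ode`
#' (lsoda). Normal input places are consumed at `weight * rate`, outputs
#' produced at `weight * rate`; test inputs contribute to rates without
#' net flux; inhibitory inputs gate rates.
#'
#' @param model an [hpn_model()].
#' @param t_end simulation horizon (dimensionless time units).
#' @param n_out number of output grid points (uniform grid, default
#'   1001).
#' @param rtol,atol integration tolerances.
#' @param smooth_gate replace the hard inhibitory threshold with a steep
#'   sigmoid (helps stiff integrations; off by default).
#' @return an object of class `"hpn_trace"`: a data.frame with column
#'   `time` and one column per place, plus provenance attributes.
#' @export
simulate_ode <- function(model, t_end, n_out = 1001,
                         rtol = 1e-6, atol = 1e-9, smooth_gate = FALSE) {
  stopifnot(t_end > 0)
  tr <- hpn_compile(model)
  x0 <- stats::setNames(model$places$marking, model$places$name)
  np <- length(x0)
  deriv <- function(t, x, parms) {
    r <- hpn_rates(tr, x, smooth_gate = smooth_gate)
    dx <- numeric(np)
    for (j in seq_along(tr)) {
      t_j <- tr[[j]]
      if (r[j] == 0) next
      cons <- t_j$in_idx[t_j$consume]
      if (length(cons))
        dx[cons] <- dx[cons] - t_j$in_w[t_j$consume] * r[j]
      if (length(t_j$out_idx))
        dx[t_j$out_idx] <- dx[t_j$out_idx] + t_j$out_w * r[j]
    }
    list(dx)
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  structure(out, class = c("hpn_trace", "data.frame"),
            engine = "ode", model = model$name, variant = model$variant)
}

#' Run-averaged stochastic simulation
#'
#' A random-firing-order engine: transitions fire as discrete unit
#' events with exponential waiting times whose propensities follow the
#' same mass-action/gating rule as the continuous engine. Each firing
#' moves `round(weight)` tokens. The mean trajectory over `runs`
#' independent runs from the same initial marking is returned; it
#' converges to the ODE solution for well-stirred mass-action nets.
#'
#' @inheritParams simulate_ode
#' @param runs number of independent runs to average.
#' @param seed integer seed fixing the random stream.
#' @return an `"hpn_trace"` (mean markings on a uniform grid).
#' @export
simulate_stochastic_avg <- function(model, runs = 1000, t_end = 100,
                                    seed = 1, n_out = 201) {
  stopifnot(runs >= 1, t_end > 0)
  tr <- hpn_compile(model)
  x0 <- round(model$places$marking)
  np <- length(x0)
  grid <- seq(0, t_end, length.out = n_out)
  acc <- matrix(0, n_out, np)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(runs)) {
    x <- x0
    t_now <- 0
    gi <- 1L  # next grid point to fill
    repeat {
      props <- hpn_rates(tr, x)
      total <- sum(props)
      t_next <- if (total <= 0) Inf else t_now + stats::rexp(1, total)
      while (gi <= n_out && grid[gi] <= min(t_next, t_end)) {
        acc[gi, ] <- acc[gi, ] + x
        gi <- gi + 1L
      }
      if (t_next > t_end || gi > n_out) break
      t_now <- t_next
      j <- sample.int(length(tr), 1, prob = props)
      t_j <- tr[[j]]
      cons <- t_j$in_idx[t_j$consume]
      if (length(cons)) x[cons] <- x[cons] - round(t_j$in_w[t_j$consume])
      if (length(t_j$out_idx))
        x[t_j$out_idx] <- x[t_j$out_idx] + round(t_j$out_w)
      if (any(x < 0)) x[x < 0] <- 0  # guard: firing into an empty place
    }
  }
  out <- as.data.frame(acc / runs)
  names(out) <- model$places$name
  out <- cbind(time = grid, out)
  structure(out, class = c("hpn_trace", "data.frame"),
            engine = "stochastic-avg", model = model$name,
            variant = model$variant, runs = runs, seed = seed)
}

#' Plateau level of a simulated place
#'
#' Mean marking over the trailing window of a trace, with a flatness
#' diagnostic (max - min over the window) attached as attribute
#' `"flatness"`.
#'
#' @param trace an `"hpn_trace"`.
#' @param place place name.
#' @param window trailing fraction of the time grid to average over
#'   (in (0, 1]).
#' @return numeric plateau level.
#' @export
plateau_level <- function(trace, place, window = 0.2) {
  stopifnot(window > 0, window <= 1)
  if (!place %in% names(trace)) stop("unknown place '", place, "'")
  n <- nrow(trace)
  tail_idx <- seq.int(max(1L, ceiling(n * (1 - window))), n)
  v <- trace[[place]][tail_idx]
  structure(mean(v), flatness = max(v) - min(v))
}
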