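#' Computation tree logic over finite state graphs
#'
#' Formulas are parsed from a small text grammar and evaluated by the
#' standard fixpoint labeling algorithm. Atoms compare an entity's level
#' against an integer: `name=INT`, `name>=INT`, `name<=INT`, `name>INT`,
#' `name<INT`. Connectives: `!`, `&`, `|`, `->`, `<->`. Temporal
#' operators: `EX`, `AX`, `EF`, `AF`, `EG`, `AG`, and the until forms
#' `E[phi U psi]`, `A[phi U psi]`.
#'
#' Deadlock convention: `EX phi` is false and `AX phi` is true at states
#' with no successors; a maximal path ending in a deadlock counts as a
#' full path, so e.g. `AG phi` holds on a terminating path whose states
#' all satisfy `phi`, and `AF phi` at a deadlock reduces to `phi`.
#'
#' @param text formula text.
#' @return an abstract syntax tree of class `"ctl_formula"`.
#' @examples
#' parse_ctl("EF(p53=1 & Mdm2=0)")
#' parse_ctl("A[(p53=1) U (Mdm2=1)]")
#' @export
parse_ctl <- function(text) {
  toks <- ctl_lex(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text
  f <- p_iff(st)
  if (peek(st)$type != "eof")
    ctl_syntax_error(st, "unexpected input")
  f
}

ctl_syntax_error <- function(st, msg) {
  t <- peek(st)
  stop("CTL syntax error at position ", t$at, " ('", t$val, "'): ", msg,
       call. = FALSE)
}

ctl_lex <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  toks <- list(); i <- 1L
  namechar <- function(ch) grepl("[A-Za-z0-9_./-]", ch)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    three <- if (i + 2L <= n) paste0(two, chars[i + 2L]) else ""
    if (three == "<->") {
      toks[[length(toks) + 1L]] <- list(type = "iff", val = "<->", at = i)
      i <- i + 3L; next
    }
    if (two %in% c("->", ">=", "<=")) {
      type <- c("->" = "implies", ">=" = "cmp", "<=" = "cmp")[[two]]
      toks[[length(toks) + 1L]] <- list(type = type, val = two, at = i)
      i <- i + 2L; next
    }
    if (ch %in% c("(", ")", "[", "]", "!", "&", "|", "=", "<", ">")) {
      type <- switch(ch, "(" = "lpar", ")" = "rpar", "[" = "lbrk",
                     "]" = "rbrk", "!" = "not", "&" = "and", "|" = "or",
                     "=" = "cmp", "<" = "cmp", ">" = "cmp")
      toks[[length(toks) + 1L]] <- list(type = type, val = ch, at = i)
      i <- i + 1L; next
    }
    if (grepl("[0-9]", ch)) {
      j <- i
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      # digits followed by name characters form a name, not a number
      if (j <= n && namechar(chars[j]) &&
          !(chars[j] == "-" && j < n && chars[j + 1L] == ">")) {
        # fall through to name lexing below
      } else {
        toks[[length(toks) + 1L]] <-
          list(type = "int", val = paste(chars[i:(j - 1L)], collapse = ""),
               at = i)
        i <- j; next
      }
    }
    if (namechar(ch)) {
      j <- i
      while (j <= n && namechar(chars[j])) {
        if (chars[j] == "-" && j < n && chars[j + 1L] == ">") break
        j <- j + 1L
      }
      toks[[length(toks) + 1L]] <-
        list(type = "name", val = paste(chars[i:(j - 1L)], collapse = ""),
             at = i)
      i <- j; next
    }
    stop("CTL syntax error at position ", i, ": unexpected character '",
         ch, "'", call. = FALSE)
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", val = "<end>", at = n + 1L)
  toks
}

peek <- function(st) st$toks[[st$pos]]
advance <- function(st) { t <- st$toks[[st$pos]]; st$pos <- st$pos + 1L; t }
expect <- function(st, type, what) {
  if (peek(st)$type != type) ctl_syntax_error(st, paste("expected", what))
  advance(st)
}

p_iff <- function(st) {
  f <- p_implies(st)
  while (peek(st)$type == "iff") {
    advance(st)
    f <- ctl_node("iff", a = f, b = p_implies(st))
  }
  f
}
p_implies <- function(st) {
  f <- p_or(st)
  if (peek(st)$type == "implies") {
    advance(st)
    f <- ctl_node("implies", a = f, b = p_implies(st))  # right-assoc
  }
  f
}
p_or <- function(st) {
  f <- p_and(st)
  while (peek(st)$type == "or") {
    advance(st)
    f <- ctl_node("or", a = f, b = p_and(st))
  }
  f
}
p_and <- function(st) {
  f <- p_unary(st)
  while (peek(st)$type == "and") {
    advance(st)
    f <- ctl_node("and", a = f, b = p_unary(st))
  }
  f
}
p_unary <- function(st) {
  t <- peek(st)
  if (t$type == "not") {
    advance(st)
    return(ctl_node("not", a = p_unary(st)))
  }
  if (t$type == "name") {
    if (t$val %in% c("EX", "AX", "EF", "AF", "EG", "AG")) {
      advance(st)
      return(ctl_node(t$val, a = p_unary(st)))
    }
    if (t$val %in% c("E", "A") && st$toks[[st$pos + 1L]]$type == "lbrk") {
      advance(st); advance(st)  # quantifier and '['
      a <- p_iff(st)
      u <- expect(st, "name", "'U'")
      if (u$val != "U") ctl_syntax_error(st, "expected 'U' in until form")
      b <- p_iff(st)
      expect(st, "rbrk", "']'")
      return(ctl_node(paste0(t$val, "U"), a = a, b = b))
    }
  }
  p_primary(st)
}
p_primary <- function(st) {
  t <- peek(st)
  if (t$type == "lpar") {
    advance(st)
    f <- p_iff(st)
    expect(st, "rpar", "')'")
    return(f)
  }
  if (t$type %in% c("name", "int")) {
    nm <- advance(st)
    cmp <- peek(st)
    if (cmp$type != "cmp")
      ctl_syntax_error(st, "expected comparator after entity name")
    advance(st)
    lv <- expect(st, "int", "integer level")
    return(ctl_node("atom", entity = nm$val, cmp = cmp$val,
                    level = as.integer(lv$val)))
  }
  ctl_syntax_error(st, "expected formula")
}

ctl_node <- function(op, ...) {
  structure(c(list(op = op), list(...)), class = "ctl_formula")
}

#' Atom constructor
#'
#' Programmatic alternative to [parse_ctl()] for a single comparison.
#'
#' @param entity entity name.
#' @param cmp one of `"="`, `">="`, `"<="`, `">"`, `"<"`.
#' @param level integer level.
#' @export
ctl_atom <- function(entity, cmp = "=", level = 1L) {
  stopifnot(cmp %in% c("=", ">=", "<=", ">", "<"))
  ctl_node("atom", entity = entity, cmp = cmp, level = as.integer(level))
}

#' Atom conjunction pinning one full state
#'
#' Builds the formula `e1=v1 & e2=v2 & ...` identifying a single state.
#'
#' @param entities character vector of entity names.
#' @param state integer vector of levels.
#' @export
ctl_state_atom <- function(entities, state) {
  f <- ctl_atom(entities[1], "=", state[1])
  for (j in seq_along(entities)[-1])
    f <- ctl_node("and", a = f, b = ctl_atom(entities[j], "=", state[j]))
  f
}

#' @export
format.ctl_formula <- function(x, ...) {
  switch(x$op,
    atom = paste0(x$entity, x$cmp, x$level),
    not = paste0("!(", format(x$a), ")"),
    and = paste0("(", format(x$a), " & ", format(x$b), ")"),
    or = paste0("(", format(x$a), " | ", format(x$b), ")"),
    implies = paste0("(", format(x$a), " -> ", format(x$b), ")"),
    iff = paste0("(", format(x$a), " <-> ", format(x$b), ")"),
    EU = paste0("E[(", format(x$a), ") U (", format(x$b), ")]"),
    AU = paste0("A[(", format(x$a), ") U (", format(x$b), ")]"),
    paste0(x$op, "(", format(x$a), ")"))
}

#' @export
print.ctl_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- fixpoint evaluation ----

# core evaluator on raw edge vectors; returns logical over states
ctl_eval <- function(f, states, from, to, entities) {
  n <- nrow(states)
  ex_step <- function(sat) {
    out <- logical(n)
    out[from[sat[to]]] <- TRUE
    out
  }
  has_succ <- logical(n)
  has_succ[from] <- TRUE
  rec <- function(f) {
    switch(f$op,
      atom = {
        j <- match(f$entity, entities)
        if (is.na(j)) stop("CTL atom references unknown entity '",
                           f$entity, "'", call. = FALSE)
        lev <- states[, j]
        switch(f$cmp,
               "=" = lev == f$level, ">=" = lev >= f$level,
               "<=" = lev <= f$level, ">" = lev > f$level,
               "<" = lev < f$level)
      },
      not = !rec(f$a),
      and = rec(f$a) & rec(f$b),
      or = rec(f$a) | rec(f$b),
      implies = !rec(f$a) | rec(f$b),
      iff = rec(f$a) == rec(f$b),
      EX = ex_step(rec(f$a)),
      AX = !ex_step(!rec(f$a)),
      EF = {  # least fixpoint of  Z = phi | EX Z
        sat <- rec(f$a)
        repeat {
          nxt <- sat | ex_step(sat)
          if (identical(nxt, sat)) break
          sat <- nxt
        }
        sat
      },
      EU = {
        a <- rec(f$a); sat <- rec(f$b)
        repeat {
          nxt <- sat | (a & ex_step(sat))
          if (identical(nxt, sat)) break
          sat <- nxt
        }
        sat
      },
      AF = {  # on maximal paths: deadlocks satisfy AF phi iff phi
        phi <- rec(f$a); sat <- phi
        repeat {
          nxt <- phi | (has_succ & !ex_step(!sat))
          if (identical(nxt, sat)) break
          sat <- nxt
        }
        sat
      },
      AU = {
        a <- rec(f$a); b <- rec(f$b); sat <- b
        repeat {
          nxt <- b | (a & has_succ & !ex_step(!sat))
          if (identical(nxt, sat)) break
          sat <- nxt
        }
        sat
      },
      EG = {  # greatest fixpoint; a path stuck in a deadlock counts
        phi <- rec(f$a); sat <- phi
        repeat {
          nxt <- phi & (!has_succ | ex_step(sat))
          if (identical(nxt, sat)) break
          sat <- nxt
        }
        sat
      },
      AG = {
        phi <- rec(f$a); sat <- phi
        repeat {
          nxt <- phi & !ex_step(!sat)
          if (identical(nxt, sat)) break
          sat <- nxt
        }
        sat
      },
      stop("unknown CTL operator '", f$op, "'"))
  }
  rec(f)
}

#' States satisfying a CTL formula
#'
#' @param graph a [build_state_graph()] result.
#' @param formula a [parse_ctl()] formula (or formula text).
#' @return character vector of state labels satisfying the formula.
#' @export
satisfying_states <- function(graph, formula) {
  if (is.character(formula)) formula <- parse_ctl(formula)
  sat <- ctl_eval(formula, graph$states, graph$edges[, 1], graph$edges[, 2],
                  graph$entities)
  graph$labels[sat]
}

#' Does a formula hold at a state?
#'
#' @inheritParams satisfying_states
#' @param state an integer state vector or canonical label.
#' @return logical scalar.
#' @export
holds_at <- function(graph, formula, state) {
  if (is.character(state)) state <- parse_state(state)
  lab <- state_label(state)
  i <- match(lab, graph$labels)
  if (is.na(i)) stop("state ", lab, " not in graph")
  if (is.character(formula)) formula <- parse_ctl(formula)
  sat <- ctl_eval(formula, graph$states, graph$edges[, 1], graph$edges[, 2],
                  graph$entities)
  sat[i]
}
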