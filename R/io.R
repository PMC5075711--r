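#' Read a BRN configuration file
#'
#' The configuration is YAML with fields `schema_version`, `type:
#' brn`, `entities` (list of `{name, max_level}`), `interactions` (list
#' of `{source, target, sign, threshold}`) and `parameters` (list of
#' `{entity, resources, value}`). The parameter table must be total; a
#' missing row is a load-time error listing every missing (entity,
#' resource set) pair.
#'
#' @param path file path.
#' @return list with elements `brn` and `parameterization`.
#' @export
read_brn_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$type) || cfg$type != "brn")
    stop("config '", path, "' is not a BRN config (type: ", cfg$type, ")")
  ents <- data.frame(
    name = vapply(cfg$entities, `[[`, "", "name"),
    max_level = vapply(cfg$entities, function(e)
      as.integer(e$max_level %||% 1L), integer(1)),
    stringsAsFactors = FALSE)
  ints <- if (length(cfg$interactions)) data.frame(
    source = vapply(cfg$interactions, `[[`, "", "source"),
    target = vapply(cfg$interactions, `[[`, "", "target"),
    sign = vapply(cfg$interactions, `[[`, "", "sign"),
    threshold = vapply(cfg$interactions, function(e)
      as.integer(e$threshold %||% 1L), integer(1)),
    stringsAsFactors = FALSE) else NULL
  x <- brn(ents, ints)
  tab <- list()
  for (row in cfg$parameters) {
    e <- row$entity
    members <- as.character(unlist(row$resources))
    tab[[e]] <- c(tab[[e]],
                  stats::setNames(as.integer(row$value),
                                  resource_key(members)))
  }
  k <- tryCatch(parameterization(x, tab), error = function(e)
    stop("in '", path, "': ", conditionMessage(e), call. = FALSE))
  list(brn = x, parameterization = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a BRN configuration file
#'
#' Canonical ordering (entities in declaration order, parameters in
#' subset order) makes write/read a lossless round trip.
#'
#' @param x a [brn()].
#' @param k a [parameterization()].
#' @param path output path.
#' @export
write_brn_config <- function(x, k, path) {
  ents <- lapply(seq_len(nrow(x$entities)), function(i)
    list(name = x$entities$name[i],
         max_level = x$entities$max_level[i]))
  ints <- lapply(seq_len(nrow(x$interactions)), function(i)
    list(source = x$interactions$source[i],
         target = x$interactions$target[i],
         sign = x$interactions$sign[i],
         threshold = x$interactions$threshold[i]))
  pars <- list()
  for (e in x$entities$name) {
    for (key in resource_subset_keys(x, e)) {
      members <- strsplit(gsub("[{}]", "", key), ",")[[1]]
      members <- members[nzchar(members)]
      pars[[length(pars) + 1L]] <-
        list(entity = e, resources = as.list(members),
             value = unname(k[[e]][key]))
    }
  }
  yaml::write_yaml(list(schema_version = 1L, type = "brn",
                        entities = ents, interactions = ints,
                        parameters = pars), path)
  invisible(path)
}

#' Read / write continuous Petri-net configurations
#'
#' YAML with fields `schema_version`, `type: hpn`, `name`, `variant`,
#' `places` (`{name, kind, marking}`), `transitions` (`{name, rate}`)
#' and `arcs` (`{from, to, kind, weight}`).
#'
#' @param path file path.
#' @return an [hpn_model()].
#' @export
read_hpn_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$type) || cfg$type != "hpn")
    stop("config '", path, "' is not an HPN config")
  hpn_model(
    places = data.frame(
      name = vapply(cfg$places, `[[`, "", "name"),
      kind = vapply(cfg$places, function(p)
        p$kind %||% "continuous", ""),
      marking = vapply(cfg$places, function(p)
        as.numeric(p$marking %||% 0), numeric(1)),
      stringsAsFactors = FALSE),
    transitions = data.frame(
      name = vapply(cfg$transitions, `[[`, "", "name"),
      rate = vapply(cfg$transitions, function(t)
        as.numeric(t$rate %||% 1), numeric(1)),
      stringsAsFactors = FALSE),
    arcs = data.frame(
      from = vapply(cfg$arcs, `[[`, "", "from"),
      to = vapply(cfg$arcs, `[[`, "", "to"),
      kind = vapply(cfg$arcs, function(a) a$kind %||% "normal", ""),
      weight = vapply(cfg$arcs, function(a)
        as.numeric(a$weight %||% 1), numeric(1)),
      stringsAsFactors = FALSE),
    name = cfg$name %||% "hpn", variant = cfg$variant)
}

#' @rdname read_hpn_config
#' @param model an [hpn_model()].
#' @export
write_hpn_config <- function(model, path) {
  yaml::write_yaml(list(
    schema_version = 1L, type = "hpn", name = model$name,
    variant = model$variant,
    places = lapply(seq_len(nrow(model$places)), function(i)
      list(name = model$places$name[i], kind = model$places$kind[i],
           marking = model$places$marking[i])),
    transitions = lapply(seq_len(nrow(model$transitions)), function(i)
      list(name = model$transitions$name[i],
           rate = model$transitions$rate[i])),
    arcs = lapply(seq_len(nrow(model$arcs)), function(i)
      list(from = model$arcs$from[i], to = model$arcs$to[i],
           kind = model$arcs$kind[i], weight = model$arcs$weight[i]))),
    path)
  invisible(path)
}

#' Export a state graph to DOT or GraphML
#'
#' Node labels are the canonical state tuples; node order is the
#' deterministic state-space order, so output is byte-stable for fixed
#' inputs.
#'
#' @param graph a [build_state_graph()] result.
#' @param path output path.
#' @param format `"dot"` or `"graphml"`.
#' @export
write_state_graph <- function(graph, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  ig <- as_igraph(graph)
  ig <- igraph::set_vertex_attr(ig, "label",
                                value = igraph::V(ig)$name)
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}

#' Write / read a simulation trace as CSV
#'
#' Column 1 is `time`; remaining columns are place markings. Values are
#' printed with enough digits that a round trip is lossless to 1e-9.
#'
#' @param trace an `"hpn_trace"` (or any data.frame with a time column).
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(lapply(trace, function(col)
    formatC(col, digits = 12, format = "g")))
  names(df) <- names(trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(df, class = c("hpn_trace", "data.frame"), engine = "csv")
}

#' Write an analysis report as JSON
#'
#' @param report a named list (e.g. from [analyze_state_graph()] or
#'   [run_discrete_analysis()]).
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
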