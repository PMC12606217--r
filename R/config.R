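#' Parse a pipeline configuration
#'
#' Pipelines are declared in a small YAML dialect with two top-level
#' sections: `actors:` maps each actor name to `{impl, params}`, and
#' `connections:` lists edges as `"src.port -> dst.port"` strings (ports
#' default to `out` / `in` when omitted). Cycles are permitted -- closed-loop
#' designs are the point -- but every weakly connected component must contain
#' at least one source (a node with no inbound edge).
#'
#' @param text Configuration document as a single string, or a character
#'   vector of lines.
#' @param file Alternatively, a path to a YAML file.
#' @return A `pipeline_graph`: list with `nodes` (named list of actor specs:
#'   `name`, `impl`, `params`) and `edges` (tibble with `from`, `from_port`,
#'   `to`, `to_port`).
#' @examples
#' g <- parse_config("
#' actors:
#'   src:  {impl: count_source, params: {n_frames: 5}}
#'   sink: {impl: collect_sink}
#' connections:
#'   - src.out -> sink.in
#' ")
#' length(g$nodes)
#' @export
parse_config <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file not found: %s", file))
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  } else if (length(text) > 1L) {
    text <- paste(text, collapse = "\n")
  }
  doc <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      stop(sprintf("config parse error: %s", conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (!is.list(doc) || is.null(doc$actors)) {
    stop("config parse error: missing `actors` section", call. = FALSE)
  }
  nodes <- lapply(names(doc$actors), function(nm) {
    spec <- doc$actors[[nm]]
    if (is.character(spec)) spec <- list(impl = spec)
    list(name = nm,
         impl = spec$impl %||% stop(sprintf("actor '%s' has no impl", nm)),
         params = spec$params %||% list())
  })
  names(nodes) <- names(doc$actors)
  if (anyDuplicated(names(nodes))) {
    stop("config validation error: duplicate actor names", call. = FALSE)
  }

  conns <- doc$connections %||% list()
  edges <- lapply(conns, parse_edge_string)
  graph <- structure(
    list(
      nodes = nodes,
      edges = tibble::tibble(
        from = vapply(edges, `[[`, character(1), "from"),
        from_port = vapply(edges, `[[`, character(1), "from_port"),
        to = vapply(edges, `[[`, character(1), "to"),
        to_port = vapply(edges, `[[`, character(1), "to_port")
      )
    ),
    class = "pipeline_graph"
  )
  validate_graph(graph)
  graph
}

parse_edge_string <- function(s) {
  if (!is.character(s) || length(s) != 1L) {
    stop("config parse error: connection entries must be strings", call. = FALSE)
  }
  parts <- strsplit(s, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop(sprintf("config parse error: bad connection '%s' (expected 'src -> dst')", s),
         call. = FALSE)
  }
  split_ep <- function(ep, default_port) {
    ep <- trimws(ep)
    bits <- strsplit(ep, ".", fixed = TRUE)[[1]]
    if (length(bits) == 1L) c(bits, default_port) else c(bits[1], bits[2])
  }
  src <- split_ep(parts[1], "out")
  dst <- split_ep(parts[2], "in")
  list(from = src[1], from_port = src[2], to = dst[1], to_port = dst[2])
}

#' Validate a pipeline graph
#'
#' Checks that every edge endpoint names a declared actor, that actor
#' implementations resolve in the registry, and that every weakly connected
#' component has at least one source node.
#'
#' @param graph A `pipeline_graph`.
#' @param check_impls If `TRUE`, require every `impl` to be registered
#'   (see [register_actor()]).
#' @return `graph`, invisibly; errors describe the first problem found.
#' @export
validate_graph <- function(graph, check_impls = FALSE) {
  nms <- names(graph$nodes)
  eps <- unique(c(graph$edges$from, graph$edges$to))
  unknown <- setdiff(eps, nms)
  if (length(unknown) > 0L) {
    stop(sprintf("config validation error: connection references undeclared actor(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (check_impls) {
    for (nd in graph$nodes) {
      if (!actor_registered(nd$impl)) {
        stop(sprintf("config validation error: actor '%s' impl '%s' is not registered",
                     nd$name, nd$impl), call. = FALSE)
      }
    }
  }
  # every weakly connected component needs a source
  if (length(nms) > 0L) {
    comp <- weak_components(nms, graph$edges)
    has_in <- nms %in% graph$edges$to
    names(has_in) <- nms
    for (cid in unique(comp)) {
      members <- nms[comp == cid]
      if (all(has_in[members])) {
        stop(sprintf(
          "config validation error: component {%s} has no source (every node has inbound edges)",
          paste(members, collapse = ", ")), call. = FALSE)
      }
    }
  }
  invisible(graph)
}

weak_components <- function(nms, edges) {
  comp <- seq_along(nms)
  names(comp) <- nms
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- find(match(edges$from[r], nms))
      b <- find(match(edges$to[r], nms))
      if (a != b) comp[b] <- a
    }
  }
  vapply(seq_along(nms), function(i) find(i), numeric(1))
}

#' @export
print.pipeline_graph <- function(x, ...) {
  cat(sprintf("<pipeline_graph: %d actors, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
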