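#' Create an empty run log
#'
#' A run log is an append-only record of pipeline events: actor lifecycle
#' transitions, faults, queue drops, and store evictions. Events carry a
#' monotonic timestamp (for ordering) and a wall-clock timestamp (for humans).
#'
#' @return An object of class `run_log`.
#' @export
run_log <- function() {
  env <- new.env(parent = emptyenv())
  env$events <- vector("list", 256L)
  env$n <- 0L
  structure(list(env = env), class = "run_log")
}

#' Append an event to a run log
#'
#' @param log A [run_log()].
#' @param actor Actor name (or `"<run>"` for framework events).
#' @param kind Event kind, e.g. `"start"`, `"stop"`, `"fault"`, `"drop"`,
#'   `"evict"`, `"warning"`.
#' @param detail Free-text detail string.
#' @return The log, invisibly.
#' @export
log_event <- function(log, actor, kind, detail = "") {
  env <- log$env
  n <- env$n + 1L
  if (n > length(env$events)) {
    length(env$events) <- 2L * length(env$events)
  }
  env$events[[n]] <- list(
    t_mono = mono_time(),
    wall = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    actor = actor,
    kind = kind,
    detail = detail
  )
  env$n <- n
  invisible(log)
}

#' Run-log events as a tibble
#'
#' @param x A `run_log`.
#' @param ... Unused.
#' @return A tibble with columns `t_mono`, `wall`, `actor`, `kind`, `detail`,
#'   ordered by monotonic timestamp.
#' @method as_tibble run_log
#' @export
as_tibble.run_log <- function(x, ...) {
  ev <- x$env$events[seq_len(x$env$n)]
  tibble::tibble(
    t_mono = vapply(ev, function(e) e$t_mono, numeric(1)),
    wall = vapply(ev, function(e) e$wall, character(1)),
    actor = vapply(ev, function(e) e$actor, character(1)),
    kind = vapply(ev, function(e) e$kind, character(1)),
    detail = vapply(ev, function(e) e$detail, character(1))
  )
}

#' @export
print.run_log <- function(x, ...) {
  tb <- as_tibble.run_log(x)
  cat(sprintf("<run_log: %d events, %d faults, %d drops>\n",
              nrow(tb), sum(tb$kind == "fault"), sum(tb$kind == "drop")))
  invisible(x)
}

#' Count run-log events of a given kind
#' @param log A `run_log`.
#' @param kind Event kind to count.
#' @return Integer count.
#' @export
log_count <- function(log, kind) {
  ev <- log$env$events[seq_len(log$env$n)]
  sum(vapply(ev, function(e) identical(e$kind, kind), logical(1)))
}

#' Serialize a run log to JSON-lines
#'
#' One JSON record per event, in order.
#'
#' @param log A `run_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_runlog <- function(log, path) {
  ev <- log$env$events[seq_len(log$env$n)]
  lines <- vapply(ev, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
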