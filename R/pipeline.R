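# Bounded FIFO message queue for one edge. Drop-oldest on overflow keeps the
# consumer current at the cost of completeness; control messages
# (end-of-stream) are never dropped.
new_queue <- function(capacity = 256L, label = "") {
  q <- new.env(parent = emptyenv())
  q$items <- vector("list", 0L)
  q$capacity <- as.integer(capacity)
  q$sealed <- FALSE
  q$eos_seen <- FALSE
  q$dropped <- 0L
  q$max_occ <- 0L
  q$label <- label
  q
}

queue_push <- function(q, msg, log = NULL) {
  if (q$sealed) {
    q$dropped <- q$dropped + 1L
    if (!is.null(log)) {
      log_event(log, "<queue>", "drop",
                sprintf("edge %s: message dropped (queue sealed)", q$label))
    }
    return(invisible(FALSE))
  }
  if (msg$kind != "data") {
    # control messages are never dropped and may exceed capacity
    q$items[[length(q$items) + 1L]] <- msg
    return(invisible(TRUE))
  }
  if (length(q$items) >= q$capacity) {
    # drop the oldest *data* message; control messages survive
    idx <- which(vapply(q$items, function(m) m$kind == "data", logical(1)))[1]
    if (!is.na(idx)) {
      q$items[[idx]] <- NULL
      q$dropped <- q$dropped + 1L
      if (!is.null(log)) {
        log_event(log, "<queue>", "drop",
                  sprintf("edge %s: oldest message dropped (overflow)", q$label))
      }
    }
  }
  q$items[[length(q$items) + 1L]] <- msg
  if (length(q$items) > q$max_occ) q$max_occ <- length(q$items)
  invisible(TRUE)
}

queue_pop <- function(q) {
  if (length(q$items) == 0L) return(NULL)
  msg <- q$items[[1L]]
  q$items[[1L]] <- NULL
  msg
}

#' Run a pipeline to completion
#'
#' Executes every actor of a validated graph under a cooperative scheduler:
#' actors are stepped round-robin, communicate only via bounded per-edge
#' FIFO queues carrying store keys, and share no mutable state apart from
#' the key-addressed store. A fault inside one actor's step seals that
#' actor's queues and propagates end-of-stream downstream while every other
#' actor keeps running -- faults are isolated, never fatal to the run.
#'
#' Sources (nodes without inbound edges) are stepped until `stop` frames
#' have been emitted (or the actor declares itself done), then emit
#' end-of-stream, which downstream actors forward after draining their
#' queues.
#'
#' @param graph A `pipeline_graph` from [parse_config()].
#' @param stop Number of frames each source emits.
#' @param store Optional [data_store()]; created if missing.
#' @param queue_capacity Per-edge queue capacity (default 256).
#' @param log Optional [run_log()]; created if missing.
#' @param seed Optional integer seed set once before the run.
#' @return A `pipeline_run`: list with `log` (the run log), `states`
#'   (named character vector of final actor states), `actor_state` (named
#'   list of each actor's private state environment), `store`, and
#'   `queue_stats` (tibble: edge, max occupancy, dropped count).
#' @export
run_pipeline <- function(graph, stop = 100L, store = NULL,
                         queue_capacity = 256L, log = NULL, seed = NULL) {
  validate_graph(graph, check_impls = TRUE)
  if (!is.null(seed)) set.seed(seed)
  log <- log %||% run_log()
  store <- store %||% data_store(log = log)
  if (is.null(store$env$log)) store$env$log <- log
  nms <- names(graph$nodes)
  log_event(log, "<run>", "run-start", sprintf("%d actors", length(nms)))

  edges <- graph$edges
  queues <- list()
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      lab <- sprintf("%s.%s->%s.%s", edges$from[r], edges$from_port[r],
                     edges$to[r], edges$to_port[r])
      queues[[r]] <- new_queue(queue_capacity, lab)
    }
  }
  in_edges <- lapply(nms, function(nm) which(edges$to == nm))
  out_edges <- lapply(nms, function(nm) which(edges$from == nm))
  names(in_edges) <- names(out_edges) <- nms

  actors <- list()
  states <- stats::setNames(rep("created", length(nms)), nms)
  for (nm in nms) {
    node <- graph$nodes[[nm]]
    impl <- resolve_actor(node$impl)
    state_env <- new.env(parent = emptyenv())
    ctx <- local({
      nm_ <- nm
      list(
        name = nm_,
        params = node$params,
        state = state_env,
        store = store,
        put = function(topic, payload) store_put(store, topic, payload),
        get = function(key) store_get(store, key),
        emit = function(keys, port = "out", kind = "data") {
          msg <- new_message(keys, kind)
          for (ei in out_edges[[nm_]]) {
            if (edges$from_port[ei] == port || port == "*") {
              queue_push(queues[[ei]], msg, log)
            }
          }
          invisible(NULL)
        },
        log = function(kind, detail = "") log_event(log, nm_, kind, detail)
      )
    })
    actors[[nm]] <- list(impl = impl, ctx = ctx, emitted = 0L,
                         rr = 1L, done_early = FALSE)
  }

  # setup phase: a setup failure aborts the whole run, naming the actor
  for (nm in nms) {
    a <- actors[[nm]]
    states[nm] <- "setup"
    if (!is.null(a$impl$setup)) {
      ok <- tryCatch({ a$impl$setup(a$ctx); TRUE }, error = function(e) e)
      if (!isTRUE(ok)) {
        log_event(log, nm, "fault", conditionMessage(ok))
        stop(sprintf("actor '%s' failed during setup: %s", nm,
                     conditionMessage(ok)), call. = FALSE)
      }
    }
    states[nm] <- "running"
    log_event(log, nm, "start")
  }

  is_source <- vapply(nms, function(nm) length(in_edges[[nm]]) == 0L,
                      logical(1))

  finish_actor <- function(nm, failed = FALSE) {
    a <- actors[[nm]]
    if (!failed && !is.null(a$impl$teardown)) {
      tryCatch(a$impl$teardown(a$ctx), error = function(e) {
        log_event(log, nm, "warning",
                  sprintf("teardown error: %s", conditionMessage(e)))
      })
    }
    for (ei in out_edges[[nm]]) {
      queue_push(queues[[ei]], new_message(list(), "end-of-stream"), log)
    }
    for (ei in in_edges[[nm]]) queues[[ei]]$sealed <- TRUE
    states[nm] <<- if (failed) "failed" else "stopped"
    log_event(log, nm, if (failed) "failed" else "stop")
  }

  step_actor <- function(nm, msg) {
    a <- actors[[nm]]
    out <- tryCatch(a$impl$step(a$ctx, msg), error = function(e) e)
    if (inherits(out, "error")) {
      calls <- paste(utils::head(deparse(conditionCall(out)), 2), collapse = " ")
      log_event(log, nm, "fault",
                sprintf("%s [in %s]", conditionMessage(out), calls))
      finish_actor(nm, failed = TRUE)
      return(NA)
    }
    out
  }

  guard <- 0L
  max_guard <- 1e7
  repeat {
    progressed <- FALSE
    for (nm in nms) {
      if (states[nm] != "running") next
      a <- actors[[nm]]
      if (is_source[nm]) {
        if (a$emitted < stop && !a$done_early) {
          out <- step_actor(nm, NULL)
          if (identical(out, FALSE)) actors[[nm]]$done_early <- TRUE
          actors[[nm]]$emitted <- a$emitted + 1L
          progressed <- TRUE
        } else {
          finish_actor(nm)
          progressed <- TRUE
        }
      } else {
        eis <- in_edges[[nm]]
        msg <- NULL
        for (off in seq_along(eis)) {
          ei <- eis[((a$rr - 1L + off - 1L) %% length(eis)) + 1L]
          msg <- queue_pop(queues[[ei]])
          if (!is.null(msg)) {
            actors[[nm]]$rr <- ((a$rr + off - 1L) %% length(eis)) + 1L
            if (msg$kind == "end-of-stream") queues[[ei]]$eos_seen <- TRUE
            break
          }
        }
        if (!is.null(msg)) {
          progressed <- TRUE
          if (msg$kind == "end-of-stream") {
            all_done <- all(vapply(in_edges[[nm]], function(ei) {
              queues[[ei]]$eos_seen && length(queues[[ei]]$items) == 0L
            }, logical(1)))
            if (all_done) finish_actor(nm)
          } else {
            step_actor(nm, msg)
          }
        }
      }
    }
    guard <- guard + 1L
    if (guard > max_guard) {
      log_event(log, "<run>", "warning", "scheduler guard tripped")
      break
    }
    if (!progressed) {
      if (all(states != "running")) break
      # no progress means every source is done and nothing is in flight:
      # running actors with empty inputs (including those waiting on each
      # other around a cycle) can never receive another message
      changed <- FALSE
      for (nm in nms[states == "running"]) {
        if (is_source[nm]) next
        starved <- all(vapply(in_edges[[nm]], function(ei) {
          length(queues[[ei]]$items) == 0L
        }, logical(1)))
        if (starved) {
          finish_actor(nm)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  log_event(log, "<run>", "run-end")

  qs <- tibble::tibble(
    edge = vapply(queues, function(q) q$label, character(1)),
    max_occupancy = vapply(queues, function(q) q$max_occ, integer(1)),
    dropped = vapply(queues, function(q) q$dropped, integer(1))
  )
  structure(
    list(
      log = log,
      states = states,
      actor_state = lapply(actors, function(a) a$ctx$state),
      store = store,
      queue_stats = qs
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d actors (%s), %d log events>\n",
              length(x$states),
              paste(sprintf("%d %s", table(x$states),
                            names(table(x$states))), collapse = ", "),
              x$log$env$n))
  invisible(x)
}
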