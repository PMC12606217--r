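#' Shared in-memory data store
#'
#' The store is the single place pipeline payloads live. Actors exchange
#' *keys* (small address records), never payloads, so a frame consumed by
#' many downstream actors is held exactly once in memory. Entries are
#' immutable after write and are retained per topic up to a configurable
#' count, newest first; older entries are evicted in batches.
#'
#' @param retention Default per-topic retention (number of newest entries
#'   kept). The single newest entry of a topic is never evicted.
#' @param auto_evict If `TRUE` (default), eviction runs automatically after
#'   each write that pushes a topic over its retention.
#' @param log Optional [run_log()] receiving eviction events.
#' @return An object of class `data_store`.
#' @export
data_store <- function(retention = 200L, auto_evict = TRUE, log = NULL) {
  stopifnot(retention >= 1L)
  env <- new.env(parent = emptyenv())
  env$entries <- new.env(parent = emptyenv())   # id -> entry
  env$topics <- new.env(parent = emptyenv())    # topic -> list(next_seq, ids)
  env$retention <- as.integer(retention)
  env$auto_evict <- isTRUE(auto_evict)
  env$log <- log
  env$n_live <- 0L
  structure(list(env = env), class = "data_store")
}

new_data_key <- function(topic, seq) {
  structure(
    list(
      id = sprintf("%s#%09d", topic, seq),
      topic = topic,
      seq = as.integer(seq),
      timestamp = mono_time()
    ),
    class = "data_key"
  )
}

#' @export
format.data_key <- function(x, ...) {
  sprintf("<key %s seq=%d>", x$topic, x$seq)
}

#' @export
print.data_key <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Put a payload into the store
#'
#' Assigns the next sequence number on `topic` (first entry gets seq 0) and
#' returns the key under which any actor can retrieve the payload.
#'
#' @param store A [data_store()].
#' @param topic Stream name.
#' @param payload Any R value; treated as immutable once stored.
#' @return A `data_key` with fields `id`, `topic`, `seq`, `timestamp`.
#' @export
store_put <- function(store, topic, payload) {
  env <- store$env
  stopifnot(is.character(topic), length(topic) == 1L, nzchar(topic))
  info <- env$topics[[topic]]
  if (is.null(info)) info <- list(next_seq = 0L, ids = character(0))
  key <- new_data_key(topic, info$next_seq)
  entry <- list(key = key, payload = payload,
                size_bytes = as.numeric(utils::object.size(payload)))
  assign(key$id, entry, envir = env$entries)
  info$next_seq <- info$next_seq + 1L
  info$ids <- c(info$ids, key$id)
  env$topics[[topic]] <- info
  env$n_live <- env$n_live + 1L
  if (env$auto_evict && length(info$ids) > env$retention) {
    store_evict(store, retention = env$retention, topic = topic)
  }
  key
}

#' Get a payload from the store
#'
#' @param store A [data_store()].
#' @param key A `data_key` previously returned by [store_put()].
#' @return The stored payload, unchanged.
#' @export
store_get <- function(store, key) {
  stopifnot(inherits(key, "data_key"))
  entry <- store$env$entries[[key$id]]
  if (is.null(entry)) {
    stop(sprintf("missing key: topic '%s' seq %d (evicted or unknown)",
                 key$topic, key$seq), call. = FALSE)
  }
  entry$payload
}

#' Evict old entries from the store
#'
#' Removes, per topic, the oldest entries beyond the retention count. The
#' newest entry of a topic is never evicted, even under a byte budget smaller
#' than a single entry (a warning event is logged instead). Each batch
#' eviction produces exactly one run-log event.
#'
#' @param store A [data_store()].
#' @param retention Keep this many newest entries per topic.
#' @param topic Restrict to one topic (default: all topics).
#' @param byte_budget Optional per-topic byte budget applied after the count
#'   rule; oldest entries are dropped until the topic fits.
#' @return Number of entries removed (integer).
#' @export
store_evict <- function(store, retention = NULL, topic = NULL,
                        byte_budget = NULL) {
  env <- store$env
  retention <- as.integer(retention %||% env$retention)
  topics <- topic %||% ls(env$topics)
  removed_total <- 0L
  for (tp in topics) {
    info <- env$topics[[tp]]
    if (is.null(info)) next
    ids <- info$ids
    drop <- character(0)
    if (length(ids) > retention) {
      drop <- ids[seq_len(length(ids) - retention)]
      ids <- ids[(length(drop) + 1L):length(ids)]
    }
    if (!is.null(byte_budget) && length(ids) > 0L) {
      sizes <- vapply(ids, function(id) env$entries[[id]]$size_bytes,
                      numeric(1))
      while (length(ids) > 1L && sum(sizes) > byte_budget) {
        drop <- c(drop, ids[1L])
        ids <- ids[-1L]
        sizes <- sizes[-1L]
      }
      # the single newest entry survives even an impossible budget
      if (length(ids) == 1L && sizes[1L] > byte_budget &&
          !is.null(env$log)) {
        log_event(env$log, "<store>", "warning",
                  sprintf("topic '%s': newest entry exceeds byte budget; retained", tp))
      }
    }
    if (length(drop) > 0L) {
      rm(list = drop, envir = env$entries)
      info$ids <- ids
      env$topics[[tp]] <- info
      env$n_live <- env$n_live - length(drop)
      removed_total <- removed_total + length(drop)
      if (!is.null(env$log)) {
        log_event(env$log, "<store>", "evict",
                  sprintf("topic '%s': evicted %d entries", tp, length(drop)))
      }
    }
  }
  removed_total
}

#' Number of live entries in the store
#' @param store A [data_store()].
#' @param topic Optional topic restriction.
#' @return Integer count.
#' @export
store_count <- function(store, topic = NULL) {
  if (is.null(topic)) return(store$env$n_live)
  info <- store$env$topics[[topic]]
  if (is.null(info)) 0L else length(info$ids)
}

#' Live sequence numbers for a topic
#' @param store A [data_store()].
#' @param topic Topic name.
#' @return Integer vector of live seqs, ascending.
#' @export
store_seqs <- function(store, topic) {
  info <- store$env$topics[[topic]]
  if (is.null(info)) return(integer(0))
  vapply(info$ids, function(id) store$env$entries[[id]]$key$seq, integer(1),
         USE.NAMES = FALSE)
}

#' @export
print.data_store <- function(x, ...) {
  cat(sprintf("<data_store: %d live entries, %d topics, retention %d>\n",
              x$env$n_live, length(ls(x$env$topics)), x$env$retention))
  invisible(x)
}
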