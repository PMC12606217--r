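#' Define an actor implementation
#'
#' An actor owns one independent function of a pipeline. Its behaviour is
#' three callbacks, each receiving a context object `ctx`:
#' \describe{
#'   \item{setup(ctx)}{one-time initialization before the run starts;}
#'   \item{step(ctx, msg)}{called once per scheduled step. Source actors
#'     (no inbound edges) receive `msg = NULL` and may return `FALSE` to
#'     declare themselves finished early; other actors receive one inbound
#'     message per step;}
#'   \item{teardown(ctx)}{called once when the actor stops.}
#' }
#' The context exposes `ctx$name`, `ctx$params` (from the config),
#' `ctx$state` (a private environment persisting across steps),
#' `ctx$put(topic, payload)` and `ctx$get(key)` for store access,
#' `ctx$emit(keys, port, kind)` to send messages downstream, and
#' `ctx$log(kind, detail)`.
#'
#' @param step Step function `function(ctx, msg)`.
#' @param setup,teardown Optional lifecycle functions `function(ctx)`.
#' @return An object of class `actor_impl`.
#' @export
actor_impl <- function(step, setup = NULL, teardown = NULL) {
  stopifnot(is.function(step))
  structure(list(setup = setup, step = step, teardown = teardown),
            class = "actor_impl")
}

the_registry <- new.env(parent = emptyenv())

#' Register an actor implementation under a name
#'
#' Registered names are what the `impl:` field of a pipeline config refers
#' to. Built-in implementations (sources, sinks, model actors) are
#' registered when the package loads.
#'
#' @param name Implementation name.
#' @param impl An [actor_impl()].
#' @return `name`, invisibly.
#' @export
register_actor <- function(name, impl) {
  stopifnot(is.character(name), inherits(impl, "actor_impl"))
  assign(name, impl, envir = the_registry)
  invisible(name)
}

#' @rdname register_actor
#' @export
actor_registered <- function(name) {
  exists(name, envir = the_registry, inherits = FALSE)
}

resolve_actor <- function(name) {
  if (!actor_registered(name)) {
    stop(sprintf("unknown actor implementation '%s'", name), call. = FALSE)
  }
  get(name, envir = the_registry, inherits = FALSE)
}

#' List registered actor implementations
#' @return Character vector of names.
#' @export
list_actors <- function() sort(ls(the_registry))

new_message <- function(keys, kind = "data") {
  if (kind == "data" && length(keys) < 1L) {
    stop("data messages must carry at least one key")
  }
  structure(list(keys = keys, kind = kind), class = "pipe_message")
}

register_builtin_actors <- function() {
  # emits one integer payload per step on topic <name>
  register_actor("count_source", actor_impl(
    setup = function(ctx) ctx$state$i <- 0L,
    step = function(ctx, msg) {
      key <- ctx$put(ctx$params$topic %||% ctx$name, ctx$state$i)
      ctx$state$i <- ctx$state$i + 1L
      ctx$emit(list(key))
      TRUE
    }
  ))

  # emits small synthetic image frames (h x w gaussian noise + frame index)
  register_actor("frame_source", actor_impl(
    setup = function(ctx) {
      ctx$state$i <- 0L
      ctx$state$h <- ctx$params$h %||% 16L
      ctx$state$w <- ctx$params$w %||% 16L
    },
    step = function(ctx, msg) {
      fr <- matrix(ctx$state$i + stats::rnorm(ctx$state$h * ctx$state$w, sd = 0.1),
                   ctx$state$h, ctx$state$w)
      key <- ctx$put(ctx$params$topic %||% "frames", fr)
      ctx$state$i <- ctx$state$i + 1L
      ctx$emit(list(key))
      TRUE
    }
  ))

  # forwards inbound keys untouched
  register_actor("passthrough", actor_impl(
    step = function(ctx, msg) ctx$emit(msg$keys)
  ))

  # numeric payload doubler: re-puts 2*x on its own topic
  register_actor("doubler", actor_impl(
    step = function(ctx, msg) {
      for (k in msg$keys) {
        key <- ctx$put(ctx$name, 2 * ctx$get(k))
        ctx$emit(list(key))
      }
    }
  ))

  # collects every payload it receives (for tests/demos)
  register_actor("collect_sink", actor_impl(
    setup = function(ctx) {
      ctx$state$received <- list()
      ctx$state$seqs <- integer(0)
    },
    step = function(ctx, msg) {
      for (k in msg$keys) {
        ctx$state$received[[length(ctx$state$received) + 1L]] <- ctx$get(k)
        ctx$state$seqs <- c(ctx$state$seqs, k$seq)
      }
    }
  ))

  # counts messages only; never touches payloads
  register_actor("count_sink", actor_impl(
    setup = function(ctx) ctx$state$n <- 0L,
    step = function(ctx, msg) ctx$state$n <- ctx$state$n + length(msg$keys)
  ))

  # emits params$burst messages in a single step (overflow testing)
  register_actor("burst_source", actor_impl(
    step = function(ctx, msg) {
      for (i in seq_len(ctx$params$burst %||% 150L)) {
        key <- ctx$put(ctx$name, i)
        ctx$emit(list(key))
      }
      FALSE
    }
  ))

  # passthrough that raises at a configured message index (fault injection)
  register_actor("fault_injector", actor_impl(
    setup = function(ctx) ctx$state$n <- 0L,
    step = function(ctx, msg) {
      ctx$state$n <- ctx$state$n + 1L
      if (ctx$state$n == (ctx$params$fail_at %||% 50L)) {
        stop(sprintf("injected fault at message %d", ctx$state$n))
      }
      ctx$emit(msg$keys)
    }
  ))
}
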