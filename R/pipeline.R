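# Composable lazy pipelines. A pipeline is an ordered list of stages:
#   stage_map      one input -> one output
#   stage_flatten  one input -> a finite stream of outputs
#   parallel_marker()  elements after this point may be processed
#                      concurrently (batched; see run_parallel)
#   prefetch_stage     a suspendable two-phase computation scheduled by
#                      run_prefetch over M slots to overlap index
#                      latencies (advisory prefetch, then the load)
# Pipelines never materialize the stream: results are pulled on demand.

#' Pipeline stage constructors
#'
#' `stage_map(fn)` applies `fn` to each element. `stage_flatten(fn)`
#' expects `fn` to return a stream, list or vector, whose items are
#' spliced into the output in order (depth-first). `parallel_marker()`
#' marks the point after which [run_parallel()] may process elements
#' concurrently; it is semantically transparent under serial
#' execution. `prefetch_stage(prefetch, load)` declares a suspendable
#' computation with exactly one suspend point: `prefetch(x)` issues an
#' advisory hint, the task then suspends, and on resumption `load(x)`
#' performs the actual access and produces the result. Under serial
#' execution the two phases run back to back; [run_prefetch()]
#' interleaves them across tasks.
#'
#' @param fn Stage function of one argument.
#' @param prefetch,load The two phases of a suspendable stage.
#' @param label Optional stage label used in error messages.
#' @return A pipeline stage object.
#' @name stages
NULL

#' @rdname stages
#' @export
stage_map <- function(fn, label = NULL) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, label = label),
            class = c("stage_map", "pipeline_stage"))
}

#' @rdname stages
#' @export
stage_flatten <- function(fn, label = NULL) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, label = label),
            class = c("stage_flatten", "pipeline_stage"))
}

#' @rdname stages
#' @export
parallel_marker <- function() {
  structure(list(), class = c("parallel_marker", "pipeline_stage"))
}

#' @rdname stages
#' @export
prefetch_stage <- function(prefetch, load, label = NULL) {
  stopifnot(is.function(prefetch), is.function(load))
  start <- function(x) {
    force(x)  # pin the element before it escapes into the resume closure
    prefetch(x)
    list(done = FALSE, resume = function() list(done = TRUE, value = load(x)))
  }
  structure(list(start = start, label = label),
            class = c("prefetch_stage", "pipeline_stage"))
}

#' Assemble a pipeline
#'
#' @param ... Pipeline stages (see [stages]).
#' @return An object of class `"pipeline"`.
#' @examples
#' p <- pipeline(
#'   stage_flatten(partial(split_seq, ph, 3, 2)),
#'   stage_map(revcomp_seq)
#' )
#' unlist(stream_collect(run_pipeline(p, list("ACGTACG"))))
#' @export
pipeline <- function(...) {
  stages <- list(...)
  ok <- vapply(stages, inherits, logical(1), what = "pipeline_stage")
  if (!all(ok)) stop("all arguments to pipeline() must be stages")
  structure(list(stages = stages), class = "pipeline")
}

#' Placeholder for partial application
#'
#' @seealso [partial()]
#' @export
ph <- structure(list(), class = "seqops_placeholder")

#' Partially apply a function, leaving one open slot
#'
#' Binds all arguments of `fn` except the single one marked with the
#' placeholder [ph]; the result is a one-argument function suitable as
#' a [stage_map()]/[stage_flatten()] stage.
#'
#' @param fn Function to bind.
#' @param ... Arguments, exactly one of which must be `ph`.
#' @return A function of one argument.
#' @examples
#' f <- partial(split_seq, ph, 3, 2)
#' unlist(stream_collect(f("ACGTACG")))  # "ACG" "GTA" "ACG"
#' @export
partial <- function(fn, ...) {
  stopifnot(is.function(fn))
  args <- list(...)
  open <- which(vapply(args, inherits, logical(1),
                       what = "seqops_placeholder"))
  if (length(open) != 1L) {
    seqops_error(sprintf(
      "partial() requires exactly one placeholder slot (got %d)",
      length(open)), "seqops_arity")
  }
  force(fn)
  function(x) {
    args[[open]] <- x
    do.call(fn, args)
  }
}

stage_call <- function(fn, x, i, label) {
  tryCatch(fn(x), error = function(e) {
    stop(sprintf("pipeline stage %d%s failed: %s", i,
                 if (is.null(label)) "" else paste0(" (", label, ")"),
                 conditionMessage(e)), call. = FALSE)
  })
}

apply_stage <- function(src, st, i) {
  force(src); force(st); force(i)
  if (inherits(st, "parallel_marker")) return(src)
  if (inherits(st, "stage_map")) {
    return(new_stream(function() {
      v <- stream_next(src)
      if (is_stream_done(v)) return(stream_done())
      stage_call(st$fn, v, i, st$label)
    }))
  }
  if (inherits(st, "stage_flatten")) {
    inner <- NULL
    return(new_stream(function() {
      repeat {
        if (!is.null(inner)) {
          v <- stream_next(inner)
          if (!is_stream_done(v)) return(v)
          inner <<- NULL
        }
        x <- stream_next(src)
        if (is_stream_done(x)) return(stream_done())
        inner <<- as_stream(stage_call(st$fn, x, i, st$label))
      }
    }))
  }
  if (inherits(st, "prefetch_stage")) {
    # serial semantics: the two phases run back to back per element
    return(new_stream(function() {
      v <- stream_next(src)
      if (is_stream_done(v)) return(stream_done())
      h <- stage_call(st$start, v, i, st$label)
      r <- h$resume()
      r$value
    }))
  }
  stop("unknown pipeline stage class")
}

#' Run a pipeline serially
#'
#' Serial depth-first semantics: mappers apply one to one, flatteners
#' expand each input into its yielded items in order, and the output
#' stream pulls the minimal prefix of the source needed for the values
#' consumed. An empty pipeline is the identity.
#'
#' @param p A [pipeline()].
#' @param source Source stream (or list/vector/generator).
#' @return A lazy output stream.
#' @export
run_pipeline <- function(p, source) {
  stopifnot(inherits(p, "pipeline"))
  out <- as_stream(source)
  for (i in seq_along(p$stages)) out <- apply_stage(out, p$stages[[i]], i)
  out
}

#' Run a pipeline with a parallel tail
#'
#' Stages before the [parallel_marker()] run serially; elements are
#' then blocked into batches of `batch_size` and the remaining stages
#' are applied per element, optionally on forked workers
#' (`parallel::mclapply`). The output multiset always equals the
#' serial run's; ordering across workers is unspecified, but with
#' `workers = 1` the output sequence is exactly the serial one. Stages
#' after the marker must not rely on shared mutable state.
#'
#' @param p A pipeline containing exactly one [parallel_marker()].
#' @param source Source stream.
#' @param workers Number of worker processes (1 = in-process).
#' @param batch_size Elements per dispatch block (default 100000).
#' @return A lazy output stream (lazy at batch granularity).
#' @export
run_parallel <- function(p, source, workers = 1L, batch_size = 100000L) {
  stopifnot(inherits(p, "pipeline"))
  workers <- max(1L, as.integer(workers))
  batch_size <- as.integer(batch_size)
  stopifnot(batch_size >= 1L)
  is_marker <- vapply(p$stages, inherits, logical(1), what = "parallel_marker")
  if (sum(is_marker) != 1L) {
    stop("run_parallel() needs a pipeline with exactly one parallel_marker()")
  }
  mi <- which(is_marker)
  pre <- structure(list(stages = p$stages[seq_len(mi - 1L)]),
                   class = "pipeline")
  post <- structure(list(stages = p$stages[-seq_len(mi)]),
                    class = "pipeline")
  upstream <- run_pipeline(pre, source)
  process_one <- function(x) stream_collect(run_pipeline(post, list(x)))

  buf <- list()
  bi <- 0L
  new_stream(function() {
    repeat {
      if (bi < length(buf)) {
        bi <<- bi + 1L
        return(buf[[bi]])
      }
      batch <- stream_collect(upstream, batch_size)
      if (!length(batch)) return(stream_done())
      res <- if (workers > 1L) {
        parallel::mclapply(batch, process_one, mc.cores = workers)
      } else {
        lapply(batch, process_one)
      }
      bad <- vapply(res, inherits, logical(1), what = "try-error")
      if (any(bad)) stop(attr(res[[which(bad)[1L]]], "condition"))
      buf <<- do.call(c, res)
      bi <<- 0L
    }
  })
}

#' Run a suspendable stage through the M-slot prefetch scheduler
#'
#' Realizes batched latency hiding for index queries: up to `M` tasks
#' are held in flight in a ring of slots. The scheduler first fills
#' empty slots from the source -- starting a task runs its prefetch
#' phase and suspends it -- then cyclically resumes suspended tasks;
#' each resumption completes the task's load phase, its result is
#' emitted downstream, and a fresh source element takes the freed
#' slot. After the source is exhausted the remaining tasks are drained
#' in slot order. The output multiset equals serial execution's, and
#' with `M = 1` the output order is exactly serial.
#'
#' @param stage A [prefetch_stage()] (or any stage object with a
#'   `start(x)` function returning a handle `list(done, resume)`), or
#'   a [pipeline()] containing exactly one such stage, whose
#'   surrounding stages run serially.
#' @param source Source stream.
#' @param M Number of concurrent task slots (default 16).
#' @return A lazy output stream.
#' @export
run_prefetch <- function(stage, source, M = 16L) {
  M <- as.integer(M)
  stopifnot(M >= 1L)
  if (inherits(stage, "pipeline")) {
    is_pf <- vapply(stage$stages, inherits, logical(1),
                    what = "prefetch_stage")
    if (sum(is_pf) != 1L) {
      stop("run_prefetch() needs exactly one prefetch stage in the pipeline")
    }
    pi <- which(is_pf)
    pre <- structure(list(stages = stage$stages[seq_len(pi - 1L)]),
                     class = "pipeline")
    post <- structure(list(stages = stage$stages[-seq_len(pi)]),
                      class = "pipeline")
    core <- run_prefetch(stage$stages[[pi]], run_pipeline(pre, source), M)
    return(run_pipeline(post, core))
  }
  if (!is.list(stage) || !is.function(stage$start)) {
    stop("run_prefetch() needs a prefetch stage or a pipeline containing one")
  }
  src <- as_stream(source)
  slots <- vector("list", M)
  n_filled <- 0L   # how many of the M slots hold a suspended task
  kpos <- 1L       # next slot to resume, cyclic
  src_done <- FALSE

  start_task <- function(x) {
    force(x)  # the admission loop reuses its variable; fix this task's input
    h <- stage$start(x)
    if (!is.list(h) || !is.function(h$resume)) {
      seqops_error("prefetch stage start() must return a task handle",
                   "seqops_prefetch_misuse")
    }
    if (isTRUE(h$done)) {
      seqops_error("prefetch stage completed without suspending",
                   "seqops_prefetch_misuse")
    }
    h
  }

  new_stream(function() {
    repeat {
      while (!src_done && n_filled < M) {
        x <- stream_next(src)
        if (is_stream_done(x)) {
          src_done <<- TRUE
          break
        }
        j <- which(vapply(slots, is.null, logical(1)))[1L]
        slots[[j]] <<- start_task(x)
        n_filled <<- n_filled + 1L
      }
      if (n_filled == 0L) return(stream_done())
      j <- kpos
      while (is.null(slots[[j]])) j <- j %% M + 1L
      r <- slots[[j]]$resume()
      if (!is.list(r) || !isTRUE(r$done)) {
        seqops_error("prefetch stage suspended more than once",
                     "seqops_prefetch_misuse")
      }
      slots[j] <<- list(NULL)  # clear the slot without shrinking the ring
      n_filled <<- n_filled - 1L
      kpos <<- j %% M + 1L
      return(r$value)
    }
  })
}
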