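# Pull-based lazy streams: the currency of all pipelines in this package.
# A stream produces one value per call to stream_next() and signals
# exhaustion with the stream_done() sentinel. Streams are single-pass.

.done_sentinel <- structure(list(), class = "stream_done")

#' Stream exhaustion sentinel
#'
#' Streams signal exhaustion by returning this sentinel from
#' [stream_next()]. Use [is_stream_done()] to test for it.
#'
#' @return The unique exhaustion sentinel object.
#' @export
stream_done <- function() .done_sentinel

#' @rdname stream_done
#' @param x Object to test.
#' @export
is_stream_done <- function(x) inherits(x, "stream_done")

#' Create a stream from a generator function
#'
#' @param nextval Function of no arguments returning the next value, or
#'   [stream_done()] when exhausted.
#' @return An object of class `"stream"`.
#' @export
new_stream <- function(nextval) {
  stopifnot(is.function(nextval))
  structure(list(nextval = nextval), class = "stream")
}

#' Coerce to a stream
#'
#' Vectors and lists become finite streams over their elements; a bare
#' function is wrapped as a generator (it must return [stream_done()]
#' when exhausted, or never, for an infinite stream); streams pass
#' through unchanged.
#'
#' @param x A stream, list, vector, or generator function.
#' @return A stream.
#' @export
as_stream <- function(x) {
  if (inherits(x, "stream")) return(x)
  if (is.function(x)) return(new_stream(x))
  xs <- if (is.list(x)) x else as.list(x)
  i <- 0L
  n <- length(xs)
  new_stream(function() {
    if (i >= n) return(.done_sentinel)
    i <<- i + 1L
    xs[[i]]
  })
}

#' Pull the next value from a stream
#'
#' @param s A stream.
#' @return The next value, or [stream_done()] when the stream is
#'   exhausted.
#' @export
stream_next <- function(s) {
  stopifnot(inherits(s, "stream"))
  s$nextval()
}

#' Collect values from a stream
#'
#' Pulls at most `n` values (all values by default). Consuming `m`
#' values touches only the prefix of the underlying source needed to
#' produce them, so `stream_collect(s, m)` is safe on infinite streams.
#'
#' @param s A stream (or anything [as_stream()] accepts).
#' @param n Maximum number of values to pull.
#' @return A list of the collected values.
#' @export
stream_collect <- function(s, n = Inf) {
  s <- as_stream(s)
  out <- vector("list", if (is.finite(n)) n else 64L)
  got <- 0L
  while (got < n) {
    v <- s$nextval()
    if (is_stream_done(v)) break
    got <- got + 1L
    if (got > length(out)) out <- c(out, vector("list", length(out)))
    out[[got]] <- v
  }
  length(out) <- got
  out
}

#' @export
print.stream <- function(x, ...) {
  cat("<stream (lazy; use stream_next()/stream_collect())>\n")
  invisible(x)
}
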