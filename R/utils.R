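#' @useDynLib msseg3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rbinom cor sd
#' @importFrom utils write.table read.table head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. All stochastic entry points funnel through
# this so that a single integer seed pins down an entire run.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# A private, resumable RNG stream: returns a function that evaluates its
# argument-expression under the stream's own state. Used by patch streams so
# that interleaved consumers do not perturb each other.
rngStream <- function(seed) {
  state <- withSeed(seed, get(".Random.seed", envir = globalenv()))
  function(expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", state, envir = globalenv())
    res <- force(expr)
    state <<- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    res
  }
}

# Concatenate two [C,D,H,W] arrays along the channel axis.
catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 4L, all(da[-1] == db[-1]))
  y <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  y[seq_len(da[1]), , , ] <- a
  y[da[1] + seq_len(db[1]), , , ] <- b
  y
}

# Split a channel gradient back into the two concatenated parts.
splitChannels <- function(g, c1) {
  list(g[seq_len(c1), , , , drop = FALSE],
       g[-seq_len(c1), , , , drop = FALSE])
}

# Flip a 4-D [C,D,H,W] array (or 3-D mask) along a spatial axis (1=D,2=H,3=W).
flipAxis <- function(x, axis) {
  d <- dim(x)
  if (length(d) == 4L) {
    switch(axis,
           x[, rev(seq_len(d[2])), , , drop = FALSE],
           x[, , rev(seq_len(d[3])), , drop = FALSE],
           x[, , , rev(seq_len(d[4])), drop = FALSE])
  } else {
    switch(axis,
           x[rev(seq_len(d[1])), , , drop = FALSE],
           x[, rev(seq_len(d[2])), , drop = FALSE],
           x[, , rev(seq_len(d[3])), drop = FALSE])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
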