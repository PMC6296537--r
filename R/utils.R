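# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(...) stop(errorCondition(paste0(...), class = c("octhrombus_config_error", "error")))
abort_format <- function(...) stop(errorCondition(paste0(...), class = c("octhrombus_format_error", "error")))
abort_validation <- function(...) stop(errorCondition(paste0(...), class = c("octhrombus_validation_error", "error")))

#' @keywords internal
#' @noRd
stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    abort_validation(name, " must be a single finite number in [", min, ", ", max, "]")
  invisible(x)
}

# Row-wise reversed cumulative sum: out[i, j] = sum_{k >= j} m[i, k].
row_revcumsum <- function(m) {
  nc <- ncol(m)
  out <- m[, nc:1L, drop = FALSE]
  out <- t(apply(out, 1L, cumsum))
  out[, nc:1L, drop = FALSE]
}

# Boxcar (moving-average) smoothing with edge replication, separable 2-D.
# half = c(row_halfwidth, col_halfwidth); c(0, 0) is the identity.
# A depth-direction boxcar maps c*r^j to (c')*r^j in the interior, so it
# preserves exponential decay rates exactly away from edges.
boxcar2d <- function(m, half = c(2L, 2L)) {
  half <- as.integer(half)
  if (any(half < 0L)) abort_validation("smoothing half-widths must be >= 0")
  sm <- function(x, h) {              # columns of x smoothed along rows
    if (h == 0L) return(x)
    n <- nrow(x)
    pad <- rbind(x[rep(1L, h), , drop = FALSE], x, x[rep(n, h), , drop = FALSE])
    cs <- apply(pad, 2L, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, ncol = ncol(x))
    w <- 2L * h + 1L
    (cs[(w):(w + n - 1L), , drop = FALSE] -
       rbind(0, cs[seq_len(n - 1L), , drop = FALSE])) / w
  }
  m <- sm(m, half[1L])                 # along A-lines (rows vary)
  t(sm(t(m), half[2L]))                # along depth
}

# Weighted mean that ignores NA values (weights dropped pairwise).
wmean_na <- function(v, w) {
  ok <- is.finite(v) & is.finite(w)
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w[ok]) / sum(w[ok])
}

# Stable content hash of an arbitrary R object via its canonical JSON form.
config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(txt), tmp)
  unname(tools::md5sum(tmp))
}

# Run code with a private RNG stream seeded by `seed`, restoring global state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
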