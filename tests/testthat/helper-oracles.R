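# Independent oracles and fixture builders used across the suite.

# Brute-force 8-connectivity flood fill (stack-based), used as the labelling
# oracle on small masks. Deliberately naive and independent of the run-based
# implementation in the package.
flood_fill_labels <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!member[i0, j0] || lab[i0, j0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1L] + di; j <- p[2L] + dj
        if (i >= 1L && i <= nr && j >= 1L && j <= nc &&
            member[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- nxt
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# Exhaustive Mann-Whitney AUC: count all (positive, negative) pairs, ties 0.5.
auc_pair_count <- function(values, labels, positive = "red") {
  x <- values[labels == positive]
  y <- values[labels != positive]
  total <- 0
  for (a in x) for (b in y) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(x) * length(y))
}

# Brute-force Youden scan over all midpoint thresholds of the oriented values
# (red above threshold), J ties broken toward higher specificity then toward
# the larger threshold, mirroring the documented convention.
youden_scan <- function(v, labels, positive = "red") {
  pos <- labels == positive
  sv <- sort(unique(v))
  best <- list(j = -Inf, spec = -Inf, cut = -Inf)
  for (k in seq_len(length(sv) - 1L)) {
    cut <- (sv[k] + sv[k + 1L]) / 2
    sens <- sum(v[pos] > cut) / sum(pos)
    spec <- sum(v[!pos] <= cut) / sum(!pos)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(spec - best$spec) <= 1e-12 && cut > best$cut)) {
      best <- list(j = j, spec = spec, cut = cut, sens = sens)
    }
  }
  best
}

# Beer-Lambert phantom frame: n_alines identical exponential A-lines, optional
# multiplicative exponential speckle.
beer_lambert_frame <- function(mu, n_alines = 32L, n_depth = 4096L,
                               dz = 0.005, i0 = 1000, speckle = FALSE) {
  line <- i0 * exp(-2 * mu * (seq_len(n_depth) - 1L) * dz)
  I <- matrix(rep(line, n_alines), nrow = n_alines, byrow = TRUE)
  if (speckle) I <- I * matrix(stats::rexp(length(I)), nrow = n_alines)
  polar_frame(I, dz, 0L)
}

# Hand-rolled attenuation map for threshold tests: mu values with full
# validity, shaped like the given member matrix.
fake_attenuation_map <- function(mu, valid = NULL, frame_id = "frame1") {
  structure(list(mu = mu, valid = valid %||% is.finite(mu),
                 frame_id = frame_id, noise_floor = 0, method = "exact",
                 axial_pitch_mm = 0.005, internal = NULL),
            class = "attenuation_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
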