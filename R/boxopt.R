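# Extremes of a scalar function over a box [lower, upper].
#
# Expected cost (and delta-cost) is multilinear in the parameters, so its
# extremes over a box lie at vertices; for small k we enumerate all 2^k
# vertices exactly. Beyond max_vertex parameters we fall back to
# coordinate-wise endpoint descent/ascent from several deterministic
# starting patterns. The base point is always evaluated, so the returned
# interval contains the base value by construction. f may return NA for
# infeasible points (e.g. an ICER whose denominator changed sign); such
# points are never selected.
box_extremes <- function(f, lower, upper, base, max_vertex = 13) {
  k <- length(lower)
  stopifnot(length(upper) == k, length(base) == k)
  if (k == 0) {
    v <- f(numeric(0))
    return(list(min = v, max = v, argmin = numeric(0), argmax = numeric(0),
                method = "degenerate", n_infeasible = 0L))
  }
  f_base <- f(base)
  if (is.na(f_base)) {
    abort_stonecea("quantity is undefined at the base parameter values")
  }
  if (k <= max_vertex) {
    grid <- as.matrix(expand.grid(lapply(seq_len(k), function(j) c(lower[j], upper[j])),
                                  KEEP.OUT.ATTRS = FALSE))
    vals <- apply(grid, 1L, f)
    n_inf <- sum(is.na(vals))
    vmin <- vals; vmin[is.na(vmin)] <- Inf
    vmax <- vals; vmax[is.na(vmax)] <- -Inf
    i_min <- which.min(vmin); i_max <- which.max(vmax)
    lo <- min(vmin[i_min], f_base); hi <- max(vmax[i_max], f_base)
    return(list(min = lo, max = hi,
                argmin = if (vmin[i_min] <= f_base) grid[i_min, ] else base,
                argmax = if (vmax[i_max] >= f_base) grid[i_max, ] else base,
                method = "vertex", n_infeasible = n_inf))
  }
  n_inf <- 0L
  fx <- function(x) {
    v <- f(x)
    if (is.na(v)) n_inf <<- n_inf + 1L
    v
  }
  sweep_from <- function(x0, v0, maximize) {
    x <- x0
    best <- v0
    for (pass in seq_len(100)) {
      changed <- FALSE
      for (j in seq_len(k)) {
        for (cand in c(lower[j], upper[j])) {
          if (cand == x[j]) next
          xj <- x; xj[j] <- cand
          v <- fx(xj)
          if (is.na(v)) next
          if ((maximize && v > best + 1e-12) || (!maximize && v < best - 1e-12)) {
            x <- xj; best <- v; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    list(x = x, value = best)
  }
  alt1 <- ifelse(seq_len(k) %% 2 == 1, lower, upper)
  alt2 <- ifelse(seq_len(k) %% 2 == 1, upper, lower)
  starts <- list(base, lower, upper, alt1, alt2)
  lo <- list(x = base, value = f_base); hi <- lo
  for (s in starts) {
    v0 <- if (identical(s, base)) f_base else fx(s)
    if (is.na(v0)) next
    r_min <- sweep_from(s, v0, maximize = FALSE)
    r_max <- sweep_from(s, v0, maximize = TRUE)
    if (r_min$value < lo$value) lo <- r_min
    if (r_max$value > hi$value) hi <- r_max
  }
  list(min = lo$value, max = hi$value, argmin = lo$x, argmax = hi$x,
       method = "coordinate_descent", n_infeasible = n_inf)
}
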