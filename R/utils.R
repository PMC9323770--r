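# Internal helpers.

# Run expr with a local RNG stream seeded by `seed`, restoring the caller's
# .Random.seed afterwards so library code never perturbs user randomness.
with_preserved_rng <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Even-odd ray casting for a simple polygon given as x/y vertex vectors.
# Points exactly on an edge count as inside (ties are then resolved by the
# caller's field order).
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  stopifnot(n >= 3, length(ys) == n)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-edge check
    d <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    if (abs(d) < 1e-12 &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12)
      return(TRUE)
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Rectangle helper: [xmin,xmax] x [ymin,ymax] as polygon vertex lists.
rect_polygon <- function(xr, yr) {
  list(x = c(xr[1], xr[2], xr[2], xr[1]), y = c(yr[1], yr[1], yr[2], yr[2]))
}
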