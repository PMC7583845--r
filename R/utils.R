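# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded package internals
#' never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-stream sub-seed derived from a global seed and a text tag.
# Adding a new program entry (new tag) never perturbs the variates drawn by
# existing entries.
substream_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1987654321
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rotation matrix for a right-handed rotation of `deg` degrees about `axis`
# (Rodrigues formula).
rotation_matrix <- function(axis, deg) {
  a <- unit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Angle (degrees) at vertex b of the triangle a-b-c.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(clamp(cosang, -1, 1)) * 180 / pi
}

# Squared-distance matrix between two coordinate sets (rows are points).
cross_dist2 <- function(a, b) {
  sa <- rowSums(a * a)
  sb <- rowSums(b * b)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Any pair of orthonormal vectors completing `a` to a right-handed basis.
orthobasis <- function(a) {
  a <- unit(a)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(pracma_cross(a, ref))
  e2 <- pracma_cross(a, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# CSV writer used by the pipeline: a '#'-prefixed header block (version, seed,
# thresholds) followed by a regular CSV table. Read back with
# read.csv(comment.char = "#").
write_csv_with_header <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# trajan %s", as.character(utils::packageVersion("trajan"))), con)
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, paste(format(meta[[nm]], trim = TRUE), collapse = ",")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
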