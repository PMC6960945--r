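#' @keywords internal
"_PACKAGE"

# Classed error helper so callers (and the CLI) can distinguish bad input
# from numerical failure.
imu_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "imujoint_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_vec3 <- function(v) is.numeric(v) && length(v) == 3L && all(is.finite(v))

check_vec3 <- function(v, name = deparse(substitute(v))) {
  if (!is_vec3(v)) {
    imu_stop(sprintf("'%s' must be a finite numeric vector of length 3", name),
             "imujoint_bad_input")
  }
  as.numeric(v)
}

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 100) {
    imu_stop("cannot normalize a (near-)zero vector", "imujoint_degenerate")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product of two n x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

symmetrize <- function(M) (M + t(M)) / 2

# Symmetrize and floor eigenvalues so covariance stays PSD despite round-off.
make_psd <- function(M, floor_rel = 1e-12) {
  M <- symmetrize(M)
  e <- eigen(M, symmetric = TRUE)
  lo <- floor_rel * max(sum(pmax(e$values, 0)), .Machine$double.xmin)
  if (min(e$values) < lo) {
    M <- e$vectors %*% (pmax(e$values, lo) * t(e$vectors))
    M <- symmetrize(M)
  }
  M
}

# Evaluate code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
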