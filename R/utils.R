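# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reflect 0-based indices into [0, n-1]
#'
#' Mirror reflection without edge repetition (index -1 maps to 1, index n to
#' n - 2), applied repeatedly so arbitrarily distant indices fold back in.
#' @param i integer vector of 0-based indices (may be out of range).
#' @param n extent of the axis.
#' @return integer vector of in-range 0-based indices.
#' @keywords internal
#' @noRd
mirrorIdx <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  # period of the reflected sequence is 2(n-1)
  p <- 2L * (n - 1L)
  i <- i %% p
  ifelse(i > n - 1L, p - i, i)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Pairwise anisotropy-scaled Euclidean distance between coordinate matrices
# with columns x, y, z (voxel units; z scaled by dz/dx).
scaledDistMat <- function(a, b, voxel_size = c(80, 80, 400)) {
  zf <- voxel_size[3] / voxel_size[1]
  a <- cbind(a[, 1], a[, 2], a[, 3] * zf)
  b <- cbind(b[, 1], b[, 2], b[, 3] * zf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Half-up rounding (base round() rounds half to even).
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Shift a 3D array along one axis (1 = y, 2 = x, 3 = z), filling with `fill`.
shiftArray3d <- function(a, s, axis, fill) {
  d <- dim(a)
  n <- d[axis]
  out <- array(fill, dim = d)
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) seq_len(n - s) else seq(1 - s, n)
  dst <- if (s >= 0) seq(1 + s, n) else seq_len(n + s)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  sx <- ix; sx[[axis]] <- src
  dx <- ix; dx[[axis]] <- dst
  out[dx[[1]], dx[[2]], dx[[3]]] <- a[sx[[1]], sx[[2]], sx[[3]]]
  out
}

# Running maximum over a centered box window, separable per axis.
# `win` is c(wx, wy, wz) (odd); array is indexed [y, x, z].
boxMax3d <- function(a, win, fill = -Inf) {
  stopifnot(all(win %% 2 == 1))
  r <- (win - 1) / 2
  ax <- c(2L, 1L, 3L)  # win order is (x, y, z); array axes are (y, x, z)
  out <- a
  for (k in 1:3) {
    if (r[k] == 0) next
    acc <- out
    for (s in seq_len(r[k])) {
      acc <- pmax(acc, shiftArray3d(out, s, ax[k], fill),
                  shiftArray3d(out, -s, ax[k], fill))
    }
    out <- acc
  }
  out
}

# Binary dilation of a logical 3D mask by a centered box c(wx, wy, wz).
dilateMask3d <- function(mask, box) {
  storage.mode(mask) <- "double"
  boxMax3d(mask, box, fill = 0) > 0
}

# Linear (1-based) index into an array of dim c(Y, X, Z) from 0-based x, y, z.
coordToLinear <- function(dims, x, y, z) {
  1L + as.integer(y) + dims[1] * (as.integer(x) + dims[2] * as.integer(z))
}

linearToCoord <- function(dims, idx) {
  idx0 <- idx - 1L
  y <- idx0 %% dims[1]
  x <- (idx0 %/% dims[1]) %% dims[2]
  z <- idx0 %/% (dims[1] * dims[2])
  cbind(x = x, y = y, z = z)
}

stopIfNotOdd <- function(size, what = "size") {
  if (any(size %% 2 != 1)) {
    stop(sprintf("%s dimensions must be odd, got (%s)", what,
                 paste(size, collapse = ", ")), call. = FALSE)
  }
}
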