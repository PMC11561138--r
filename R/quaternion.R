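# Vectorised unit-quaternion helpers. Quaternions are n x 4 matrices in
# (w, x, y, z) order; vectors are n x 3. Internal.

quat_identity <- function(n) cbind(rep(1, n), 0, 0, 0)

quat_normalize <- function(q) q / sqrt(rowSums(q^2))

quat_conj <- function(q) cbind(q[, 1L], -q[, 2L], -q[, 3L], -q[, 4L])

quat_mult <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = nrow(b), ncol = 4, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, nrow = nrow(a), ncol = 4, byrow = TRUE)
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

# rotate row vectors v by row quaternions q (active rotation, world frame)
quat_rotate <- function(q, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = nrow(q), ncol = 3, byrow = TRUE)
  qv <- cbind(0, v)
  out <- quat_mult(quat_mult(q, qv), quat_conj(q))
  out[, 2:4, drop = FALSE]
}

# rotation about the world z axis by theta (radians)
quat_about_z <- function(theta) {
  cbind(cos(theta / 2), 0, 0, sin(theta / 2))
}

quat_from_rotvec <- function(rv) {
  ang <- sqrt(rowSums(rv^2))
  half <- ang / 2
  s <- ifelse(ang > 1e-12, sin(half) / ang, 0.5)
  cbind(cos(half), rv[, 1] * s, rv[, 2] * s, rv[, 3] * s)
}

# logarithmic map to rotation vectors (axis * angle, radians)
quat_to_rotvec <- function(q) {
  # enforce w >= 0 so angles fall in [0, pi]
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  vn <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, q[, 1])
  s <- ifelse(vn > 1e-12, ang / vn, 2)
  q[, 2:4, drop = FALSE] * s
}
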