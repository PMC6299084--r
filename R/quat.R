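# Internal quaternion helpers (w, x, y, z convention; R(q1 %q% q2) = R(q1) R(q2))

.qmul <- function(a, b) {
  c(a[1]*b[1] - a[2]*b[2] - a[3]*b[3] - a[4]*b[4],
    a[1]*b[2] + a[2]*b[1] + a[3]*b[4] - a[4]*b[3],
    a[1]*b[3] - a[2]*b[4] + a[3]*b[1] + a[4]*b[2],
    a[1]*b[4] + a[2]*b[3] - a[3]*b[2] + a[4]*b[1])
}

.qconj <- function(q) c(q[1], -q[2], -q[3], -q[4])

.qnormalize <- function(q) q / sqrt(sum(q^2))

# rotation matrix with columns e1, e2, e3
.qrotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y + w*z),     2*(x*z - w*y),
           2*(x*y - w*z),     1 - 2*(x^2 + z^2), 2*(y*z + w*x),
           2*(x*z + w*y),     2*(y*z - w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3)
}

# unit quaternion for rotation vector phi
.qexp <- function(phi) {
  th <- sqrt(sum(phi^2))
  if (th < 1e-12) return(c(1, phi / 2))
  c(cos(th / 2), sin(th / 2) * phi / th)
}

# rotation vector of unit quaternion
.qlog <- function(q) {
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) return(2 * q[2:4])
  2 * atan2(s, q[1]) * q[2:4] / s
}

# quaternion from rotation matrix (Shepperd's method)
.matq <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  .qnormalize(q)
}

# minimal rotation taking unit vector a to unit vector b
.qbetween <- function(a, b) {
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 degrees: any axis perpendicular to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(c(0, v))
  }
  v <- c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3], a[1]*b[2] - a[2]*b[1])
  .qnormalize(c(1 + d, v))
}
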