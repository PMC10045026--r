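# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, closed trapezoid on a duplicated
# period) so they share no code path with the package implementations.

# periodic trapezoid of a sampled function over one period: samples on
# t_l = (l-1) T / n; close the period by appending the first sample.
trapz_periodic_oracle <- function(values, period) {
  n <- length(values)
  v <- c(values, values[1])
  dt <- period / n
  s <- 0
  for (l in seq_len(n)) s <- s + (v[l] + v[l + 1]) / 2 * dt
  s
}

# OSI of one face history (n_t x 3 matrix of WSS vectors) by loops
osi_oracle <- function(wss_t, period) {
  n <- nrow(wss_t)
  mean_vec <- numeric(3)
  for (j in 1:3)
    mean_vec[j] <- trapz_periodic_oracle(wss_t[, j], period) / period
  mags <- numeric(n)
  for (l in seq_len(n)) mags[l] <- sqrt(sum(wss_t[l, ]^2))
  mean_mag <- trapz_periodic_oracle(mags, period) / period
  if (mean_mag == 0) return(0)
  0.5 * (1 - sqrt(sum(mean_vec^2)) / mean_mag)
}

# WSF by per-face accumulation in a scalar loop
wsf_oracle <- function(wss, area) {
  f <- c(0, 0, 0)
  for (i in seq_len(nrow(wss)))
    for (j in 1:3) f[j] <- f[j] + wss[i, j] * area[i]
  list(force = f, magnitude = sqrt(sum(f^2)))
}

# random trace-free 3x3 velocity-gradient tensor
random_tracefree_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  diag(A) <- diag(A) - sum(diag(A)) / 3
  A
}

# random orthogonal matrix via QR with sign fix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))))
}

# Q-criterion from the trace identity, valid for trace-free tensors
q_identity_oracle <- function(A) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + A[i, j] * A[j, i]
  -0.5 * s
}

# build a wss_history from a function t -> n_faces x 3 matrix
make_history <- function(fun, n_faces, n_t, period) {
  times <- (seq_len(n_t) - 1) * period / n_t
  w <- array(0, c(n_faces, 3, n_t))
  for (l in seq_len(n_t)) w[, , l] <- fun(times[l])
  wss_history(times, w, period)
}

# random blob mask: union of a few disks with enclosed holes filled
# (the tracer follows outer boundaries only, so test masks are
# simply connected by construction)
random_blob_mask <- function(n = 48, n_disks = 3) {
  m <- matrix(0L, n, n)
  cx <- stats::runif(n_disks, n * 0.3, n * 0.7)
  cy <- stats::runif(n_disks, n * 0.3, n * 0.7)
  r <- stats::runif(n_disks, 3, n * 0.18)
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  for (k in seq_len(n_disks))
    m[(rows - cx[k])^2 + (cols - cy[k])^2 <= r[k]^2] <- 1L
  fill_holes(m)
}

# fill background regions not 4-connected to the frame border
fill_holes <- function(m) {
  n <- nrow(m)
  reach <- matrix(FALSE, n, ncol(m))
  border <- which(m == 0L &
                  (row(m) == 1L | row(m) == n | col(m) == 1L |
                     col(m) == ncol(m)))
  stack <- border
  reach[border] <- TRUE
  nr <- n
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- ((cur - 1L) %% nr) + 1L
    for (off in c(-1L, 1L, -nr, nr)) {
      nb <- cur + off
      if (nb < 1L || nb > length(m)) next
      if (abs(((nb - 1L) %% nr) + 1L - r) > 1L) next
      if (m[nb] == 0L && !reach[nb]) {
        reach[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  m[m == 0L & !reach] <- 1L
  m
}
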