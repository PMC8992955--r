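# Independent oracles: explicit-loop implementations of the attention
# equations and O(n^2) brute-force surface metrics, kept free of any code
# path they are used to check.

ns <- asNamespace("adaunet")

# attention with identity projection by explicit loops over positions m, n
attention_oracle <- function(x, delta) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  N <- H * W
  F <- matrix(0, C, N)
  for (cc in seq_len(C)) F[cc, ] <- as.vector(x[, , cc])
  A <- matrix(0, N, N)
  for (m in seq_len(N)) {
    e <- numeric(N)
    for (n in seq_len(N)) e[n] <- exp(sum(F[, n] * F[, m]))
    A[m, ] <- e / sum(e)
  }
  out <- x
  for (m in seq_len(N)) {
    s <- numeric(C)
    for (n in seq_len(N)) s <- s + A[m, n] * F[, n]
    i <- (m - 1) %% H + 1
    j <- (m - 1) %/% H + 1
    out[i, j, ] <- F[, m] + delta * s
  }
  out
}

dsc_oracle <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(100)
  100 * 2 * sum(a == 1 & b == 1) / (sa + sb)
}

jaccard_oracle <- function(a, b) {
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(100)
  100 * sum(a == 1 & b == 1) / uni
}

border_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  at <- function(i, j) if (i < 1 || i > H || j < 1 || j > W) 0 else m[i, j]
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (m[i, j] == 1 &&
        min(at(i - 1, j), at(i + 1, j), at(i, j - 1), at(i, j + 1)) == 0)
      out[i, j] <- TRUE
  }
  out
}

# directed nearest-border distances by all-pairs search
directed_oracle <- function(a, b) {
  pa <- which(border_oracle(a), arr.ind = TRUE)
  pb <- which(border_oracle(b), arr.ind = TRUE)
  apply(pa, 1, function(p)
    sqrt(min((p[1] - pb[, 1])^2 + (p[2] - pb[, 2])^2)))
}

asd_oracle <- function(a, b, spacing = 1) {
  spacing * (mean(directed_oracle(a, b)) + mean(directed_oracle(b, a))) / 2
}

rmse_oracle <- function(a, b, spacing = 1) {
  d <- c(directed_oracle(a, b), directed_oracle(b, a))
  spacing * sqrt(mean(d^2))
}

# random blobby nonempty binary mask
random_mask <- function(n = 16, k = 2) {
  m <- matrix(0, n, n)
  for (i in seq_len(k)) {
    ci <- sample.int(n, 2)
    r <- runif(1, 1, n / 3)
    ii <- matrix(seq_len(n), n, n)
    jj <- t(ii)
    m[(ii - ci[1])^2 + (jj - ci[2])^2 <= r^2] <- 1
  }
  if (sum(m) == 0) m[sample.int(n, 1), sample.int(n, 1)] <- 1
  m
}

# central-difference gradient of f at x (small objects only)
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

tiny_phantoms <- function(n_cases = 4L, slices = 2L, size = 16L, seed = 3L) {
  generate_dataset(phantom_config(image_size = size, n_cases = n_cases,
                                  slices_per_case = slices, seed = seed))
}
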