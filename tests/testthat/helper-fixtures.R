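# Shared in-code fixtures; everything is generated, nothing is stored.

rand_volume <- function(s = 8L, seed = 1L, spacing = c(1, 1, 1)) {
  withr::with_seed(seed, image_volume(array(rnorm(s^3), c(s, s, s)),
                                      spacing = spacing))
}

rand_field <- function(s = 8L, seed = 1L, scale = 1) {
  withr::with_seed(seed,
    displacement_field(array(rnorm(s^3 * 3) * scale, c(s, s, s, 3L)),
                       cube_grid(s, 1)))
}

neg_vol <- function(v) { v$voxels <- -v$voxels; v }

box_mask <- function(s = 8L, lo = 3L, hi = 6L, spacing = c(1, 1, 1)) {
  m <- array(0, c(s, s, s))
  m[lo:hi, lo:hi, lo:hi] <- 1
  mask_volume(m, spacing = spacing)
}

# brute-force oracles -------------------------------------------------------

# central differences with replicate borders, plain loops
oracle_grad_map <- function(u) {
  s <- dim(u)[1]
  cl <- function(i) pmin(pmax(i, 1L), s)
  out <- array(0, c(s, s, s))
  for (x in 1:s) for (y in 1:s) for (z in 1:s) {
    acc <- 0
    for (c in 1:3) {
      gx <- (u[cl(x + 1), y, z, c] - u[cl(x - 1), y, z, c]) / 2
      gy <- (u[x, cl(y + 1), z, c] - u[x, cl(y - 1), z, c]) / 2
      gz <- (u[x, y, cl(z + 1), c] - u[x, y, cl(z - 1), c]) / 2
      acc <- acc + gx^2 + gy^2 + gz^2
    }
    out[x, y, z] <- acc
  }
  out
}

oracle_loss_grad <- function(u) sum(oracle_grad_map(u)) / (3 * length(u[, , , 1]))

oracle_loss_wgrad <- function(u, W) {
  sum(W^2 * oracle_grad_map(u)) / (3 * length(u[, , , 1]))
}

oracle_loss_cc <- function(w, a) {
  w <- as.vector(w); a <- as.vector(a)
  num <- sum((w - mean(w)) * (a - mean(a)))
  0.5 - num / (2 * sqrt(sum((w - mean(w))^2)) * sqrt(sum((a - mean(a))^2)))
}

oracle_ms <- function(w, A) {
  w <- as.vector(w); A <- as.vector(A)
  wi <- w[A == 1]; we <- w[A == 0]
  list(mu_int = mean(wi), mu_ext = mean(we),
       var_int = sum((wi - mean(wi))^2) / length(wi),
       var_ext = sum((we - mean(we))^2) / length(we))
}

# nearest-foreground search by full enumeration, in mm
oracle_signed_distance <- function(m, spacing) {
  d <- dim(m)
  fg <- which(m == 1, arr.ind = TRUE)
  bg <- which(m == 0, arr.ind = TRUE)
  out <- array(0, d)
  mind <- function(p, set) {
    dd <- sweep(set, 2, p, "-")
    dd <- sweep(dd, 2, spacing, "*")
    sqrt(min(rowSums(dd^2)))
  }
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    p <- c(x, y, z)
    out[x, y, z] <- if (m[x, y, z] == 1) -mind(p, bg) else mind(p, fg)
  }
  out
}

# all-pairs symmetric pooled 95th percentile in mm
oracle_hd95 <- function(va, vb, spacing = 1, pct = 95) {
  d2 <- function(A, B) {
    vapply(seq_len(nrow(A)), function(i)
      sqrt(min(colSums((t(B) - A[i, ])^2))), numeric(1))
  }
  stats::quantile(c(d2(va, vb), d2(vb, va)), pct / 100,
                  names = FALSE, type = 7) * spacing
}
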