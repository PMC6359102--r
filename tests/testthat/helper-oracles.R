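# Independent oracles used across the suite. Each re-derives the quantity
# it checks by a route different from the package implementation.

# brute-force kernel evaluation, one pair at a time
brute_kernel <- function(x, z, kernel) {
  g <- if (is.null(kernel$gamma)) 1 / length(x) else kernel$gamma
  switch(kernel$kind,
    linear = sum(x * z),
    rbf = exp(-g * sum((x - z)^2)),
    polynomial = (g * sum(x * z) + kernel$coef0)^kernel$degree
  )
}

# direct triple-product third-order cumulant sum
brute_c3 <- function(x, t1, t2) {
  xd <- x - mean(x)
  L <- length(x)
  total <- 0
  for (n in seq_len(L)) {
    i1 <- n + t1; i2 <- n + t2
    if (i1 >= 1 && i1 <= L && i2 >= 1 && i2 <= L) {
      total <- total + xd[n] * xd[i1] * xd[i2]
    }
  }
  total / L
}

# exhaustive neighborhood search over all size-N subsets of the candidate
# pool, scoring with pool-level median/MAD (the fixed-statistic convention)
exhaustive_selection <- function(kappa, y, pool, N, rho) {
  med <- median(y[pool])
  mad_raw <- median(abs(y[pool] - med))
  disp <- if (mad_raw == 0) rep(0, length(y)) else abs(y - med) / mad_raw
  subsets <- combn(pool, N)
  vals <- apply(subsets, 2, function(ss) sum(kappa[ss] + rho * disp[ss]))
  list(value = min(vals), subset = sort(subsets[, which.min(vals)]))
}

# dense interior-point reference solution of the weighted eps-SVR dual
ipop_svr_reference <- function(K, y, U, epsilon) {
  L <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * L)
  sol <- kernlab::ipop(c(epsilon - y, epsilon + y), H,
                       matrix(c(rep(1, L), rep(-1, L)), 1),
                       b = 0, l = rep(0, 2 * L), u = rep(U, 2),
                       r = 0, sigf = 9, maxiter = 400)
  a <- kernlab::primal(sol)
  a[1:L] - a[(L + 1):(2 * L)]
}

# one-vs-rest precision/recall/F1 from scratch
brute_f1 <- function(truth, pred, classes = c("LS", "MS", "HS")) {
  sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  })
}

# spectral energy fraction of a band reconstruction below a cutoff (Hz)
energy_below <- function(x, fs, cutoff) {
  sp <- Mod(fft(x))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs) # fold to [0, fs/2]
  sum(sp[freqs <= cutoff]) / sum(sp)
}

# assemble a two-channel windowed segment from the generators
make_segment <- function(stress, duration = 3, seed = 1) {
  bvp <- gen_bvp_signal(stress, duration, 128, seed = seed)
  gsr <- gen_gsr_signal(stress, duration, 4, seed = seed + 1000)
  segment_windows(list(bvp, gsr),
                  window_spec(duration, duration))[[1]]
}
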