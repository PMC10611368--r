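# Independent brute-force oracles. These deliberately use plain double
# loops over template pairs / direct summation, sharing no code with the
# package implementations they check.

oracle_sample_entropy <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  tol <- r * sd(x)
  a <- 0L; b <- 0L
  for (i in 1:(n - m - 1L)) {
    for (j in (i + 1L):(n - m)) {
      dm <- 0
      for (k in 0:(m - 1L)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= tol) b <- b + 1L
      dm1 <- max(dm, abs(x[i + m] - x[j + m]))
      if (dm1 <= tol) a <- a + 1L
    }
  }
  if (a == 0L || b == 0L) return(NA_real_)
  -log(a / b)
}

oracle_approximate_entropy <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  tol <- r * sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1L
    s <- 0
    for (i in 1:nt) {
      cnt <- 0L
      for (j in 1:nt) {
        d <- 0
        for (k in 0:(mm - 1L)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= tol) cnt <- cnt + 1L
      }
      s <- s + log(cnt / nt)
    }
    s / nt
  }
  phi(m) - phi(m + 1L)
}

oracle_fuzzy_entropy <- function(x, m = 2L, r = 0.2, p = 2L) {
  n <- length(x)
  tol <- r * sd(x)
  phi <- function(mm) {
    nt <- n - m
    s <- 0
    for (i in 1:nt) {
      ti <- x[i:(i + mm - 1L)]
      ti <- ti - mean(ti)
      for (j in 1:nt) {
        if (i == j) next
        tj <- x[j:(j + mm - 1L)]
        tj <- tj - mean(tj)
        s <- s + exp(-(max(abs(ti - tj)) / tol)^p)
      }
    }
    s / (nt * (nt - 1L))
  }
  -log(phi(m + 1L) / phi(m))
}

oracle_hrv <- function(rr) {
  n <- length(rr)
  avrr <- 0
  for (v in rr) avrr <- avrr + v
  avrr <- avrr / n
  s2 <- 0; sq <- 0; s3 <- 0; s4 <- 0
  for (i in 1:(n - 1L)) sq <- sq + (rr[i + 1L] - rr[i])^2
  for (v in rr) {
    s2 <- s2 + (v - avrr)^2
    s3 <- s3 + (v - avrr)^3
    s4 <- s4 + (v - avrr)^4
  }
  sdrr <- sqrt(s2 / (n - 1L))
  list(rmssd = sqrt(sq / (n - 1L)), avrr = avrr, sdrr = sdrr,
       skew = s3 / (n * sdrr^3), kurt = s4 / (n * sdrr^4) - 3)
}

# match detected event times to ground truth within a tolerance (seconds)
match_events <- function(detected, truth, tol = 0.05) {
  tp <- sum(vapply(truth, function(tr) any(abs(detected - tr) <= tol), logical(1)))
  list(recall = tp / length(truth),
       precision = sum(vapply(detected, function(d) any(abs(truth - d) <= tol),
                              logical(1))) / length(detected))
}

# the printed 4x5 sliding-window example used by the fusion engine
example_window <- function() {
  label_matrix(rbind(c(0L, 1L, 1L, 1L, 1L),
                     c(2L, 3L, 3L, 2L, 3L),
                     rep(4L, 5L),
                     rep(7L, 5L)))
}
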