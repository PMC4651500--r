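# Shared fixtures for the test suite. Everything is generated in code; the
# default parameter set is the package default unless a test says otherwise.

default_ci_grid <- c(40, 60, 90, 130, 180, 250, 340, 450, 600, 800, 1100,
                     1500)

# brute-force smaller root of theta*J^2 - (aQ+Jmax)*J + aQ*Jmax = 0
bisect_j <- function(par, jmax, alpha, theta, iters = 200) {
  aq <- alpha * par
  f <- function(j) theta * j^2 - (aq + jmax) * j + aq * jmax
  lo <- 0
  hi <- min(aq, jmax)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
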