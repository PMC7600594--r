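# Independent oracles and shared fixtures for the test suite.

# Naive O(n^2) approximate entropy (Pincus convention, self-matches
# included, Chebyshev distance) written as explicit loops, independent of
# the vectorised implementation.
apen_brute <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0L
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        }
        if (dmax <= r) cnt <- cnt + 1L
      }
      cs[i] <- cnt / nt
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1)
}

# Brute-force quantization distortion.
quant_brute <- function(v, x) {
  mean(vapply(v, function(vi) min((vi - x)^2), numeric(1)))
}

# Exact fractional Gaussian noise by circulant embedding of the fGn
# autocovariance (Davies-Harte).
fgn_sim <- function(n, H) {
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g[1:n], g[n + 1], g[n:2])
  m <- length(circ)
  lam <- Re(stats::fft(circ))
  lam[lam < 0] <- 0
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  sqrt(2) * Re(stats::fft(sqrt(lam / (2 * m)) * z))[1:n]
}

# Brute-force Mamdani inference over all 25 cells (don't-cares fire 0),
# with the same documented fallback rule for dead rows, written
# independently of the matrix implementation.
infer_brute <- function(ev, pv, energy_fz, partner_fz, fam) {
  sets <- c("VL", "L", "M", "H", "VH")
  outs <- c("N", "L", "M", "H", "VH")
  me <- fuzzify(ev, energy_fz)
  mp <- fuzzify(pv, partner_fz)
  agg <- stats::setNames(numeric(5), outs)
  for (i in 1:5) {
    for (j in 1:5) {
      fire <- if (is.na(fam[i, j])) 0 else min(me[i], mp[j])
      if (fire > 0) {
        o <- fam[i, j]
        agg[o] <- max(agg[o], fire)
      }
    }
  }
  if (all(agg == 0)) {
    ei <- max(which(me == max(me)))
    pj <- max(which(mp == max(mp)))
    defd <- which(!is.na(fam[ei, ]))
    best <- defd[1]
    for (j in defd) {
      if (abs(j - pj) < abs(best - pj) ||
          (abs(j - pj) == abs(best - pj) && j > best)) best <- j
    }
    return(fam[ei, best])
  }
  top <- which(agg == max(agg))
  outs[max(top)]
}

# Small shared cohort fixture, built once per test run.
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    spec <- synth_spec(n_normal = 4, n_cvd = 6, n_segments = 30, seed = 7)
    .fixture_env$spec <- spec
    .fixture_env$cohort <- generate_cohort(spec)
    .fixture_env$features <- ppg_features(.fixture_env$cohort)
    .fixture_env$words <- fuzzy_encode(.fixture_env$features)
  }
  .fixture_env
}
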