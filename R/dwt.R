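# Orthonormal discrete wavelet transform with periodic boundary handling.
#
# The analysis operator for one level is an orthogonal matrix whose rows are
# even shifts of the low/high-pass filters; synthesis is its transpose, so
# perfect reconstruction holds exactly for even-length inputs.

# sym8 decomposition filters (least-asymmetric Daubechies, 8 vanishing
# moments; standard published coefficients, low-pass then QMF high-pass).
SYM8_DEC_LO <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609
)
SYM8_DEC_HI <- rev(SYM8_DEC_LO) * rep_len(c(-1, 1), length(SYM8_DEC_LO))

# One analysis level: returns list(a, d), each length n/2. n must be even.
dwt_step <- function(x, lo = SYM8_DEC_LO, hi = SYM8_DEC_HI) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  half <- n / 2L
  L <- length(lo)
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L) # 0-based even offsets
  for (m in seq_len(L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    xv <- x[idx]
    a <- a + lo[m] * xv
    d <- d + hi[m] * xv
  }
  list(a = a, d = d)
}

# Adjoint of dwt_step (exact inverse for orthonormal filters).
idwt_step <- function(a, d, lo = SYM8_DEC_LO, hi = SYM8_DEC_HI) {
  half <- length(a)
  n <- 2L * half
  L <- length(lo)
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    contrib <- lo[m] * a + hi[m] * d
    # idx may repeat when n < L; accumulate safely
    if (n >= L) {
      x[idx] <- x[idx] + contrib
    } else {
      for (k in seq_len(half)) x[idx[k]] <- x[idx[k]] + contrib[k]
    }
  }
  x
}

# Multi-level pyramid. Returns list(approx, details = list(d1..dJ)) where
# d1 is the finest scale. Length of x must be divisible by 2^levels.
dwt_forward <- function(x, levels) {
  stopifnot(length(x) %% 2^levels == 0L)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, levels = levels)
}

dwt_inverse <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_len(decomp$levels))) {
    a <- idwt_step(a, decomp$details[[j]])
  }
  a
}
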