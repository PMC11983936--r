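# Independent oracle: bisection on the 1:1 mass-balance polynomial
# c -> Ka (H0 - c)(G0 - c) - c, strictly decreasing on [0, min(H0, G0)].
bisect_1_1 <- function(H0, G0, Ka, iters = 200) {
  lo <- 0
  hi <- min(H0, G0)
  if (hi == 0) return(0)
  f <- function(c) Ka * (H0 - c) * (G0 - c) - c
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
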