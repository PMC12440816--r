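# Shared fixtures and independent oracles for the test suite.

# Coarse-step parameter set used throughout the tests: same kinetics as the
# defaults but at dt = 1 ms so Gaussian stepping fits in seconds.
coarse_params <- function(...) diffusion_params(dt = 1e-3, ...)

# Independent nested-loop PWM scanner: scores every window character by
# character; reverse-strand hits score the PWM against the reverse
# complement of the forward window. Deliberately naive.
brute_force_scan <- function(pwm, sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  w <- pwm$width
  out <- list()
  for (start in 0:(length(chars) - w)) {
    win <- chars[(start + 1):(start + w)]
    win_rc <- rev(unname(comp[win]))
    for (strand in c("+", "-")) {
      v <- if (strand == "+") win else win_rc
      s <- 0
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!v[j] %in% rownames(pwm$mat)) { ok <- FALSE; break }
        s <- s + pwm$mat[v[j], j]
      }
      if (ok) out[[length(out) + 1]] <-
          data.frame(start = start, strand = strand, score = s)
    }
  }
  do.call(rbind, out)
}

# Random A/C/G/T sequence under R's RNG (caller seeds).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Analytic CDF of the gap first-passage time (no killing):
# P(T <= t) = 2 Phi(-x0 / sqrt(2 D_rel t)).
levy_cdf <- function(t, x0, D_rel) {
  2 * stats::pnorm(-x0 / sqrt(2 * D_rel * t))
}
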