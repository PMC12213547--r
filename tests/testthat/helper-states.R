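# random admissible states for property-style checks
random_states <- function(n, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      T = 10^runif(n, 6, 12.2),
      C = 10^runif(n, 0, 9),
      R = runif(n))
  })
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
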