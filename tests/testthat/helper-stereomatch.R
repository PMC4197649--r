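# Shared fixtures and independent oracles, built in code.

# Wrap two ternary matrices as a pair without invariant checks (used to build
# degenerate/edge-case inputs quickly).
pair_of <- function(left, right) {
  structure(list(left = left, right = right), class = "stereo_pair")
}

# All 3^k ternary left/right window fillings for a k-pixel 1-row window.
enumerate_ternary_windows <- function(k) {
  vals <- expand.grid(rep(list(-1:1), 2 * k))
  lapply(seq_len(nrow(vals)), function(i) {
    v <- as.integer(vals[i, ])
    list(left = matrix(v[1:k], 1), right = matrix(v[(k + 1):(2 * k)], 1))
  })
}

# Brute-force oracle: fraction of window pixels whose left/right contrasts
# are equal and nonzero (contrast-matched dotted combinations).
count_matched_fraction <- function(l, r) {
  sum(l != 0 & l == r) / length(l)
}

# Random ternary stereo pair (independent eyes) for operator identities.
random_ternary_pair <- function(h, w, p_dot = 0.5) {
  draw <- function() matrix(sample(-1:1, h * w, replace = TRUE,
                                   prob = c(p_dot / 2, 1 - p_dot, p_dot / 2)),
                            h, w)
  pair_of(draw(), draw())
}

full_window <- function(h, w, d = 0L) {
  match_window(rep(seq_len(w), each = h), rep(seq_len(h), times = w), d)
}
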