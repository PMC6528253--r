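# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# a 2-row layout: tests 0 and 10, two replicates each
tiny_layout <- function() parse_layout(rbind(c(0, 0), c(10, 10)))

tiny_group <- function(name = "a", values = rbind(c(1, 3), c(5, 7))) {
  bind_group(tiny_layout(), name, values)
}

# one replicate set per row of `m`, tests 1..nrow
row_layout <- function(m) parse_layout(matrix(rep(seq_len(nrow(m)), ncol(m)), nrow(m)))

row_group <- function(m, name = "g") bind_group(row_layout(m), name, m)

# standard 8-dose series used across fitting tests
demo_doses <- function() c(0.01, 0.1, 0.3, 1, 3, 10, 30, 100)

demo_truth <- function() list(bottom = 0, top = 100, ec50 = 1, hill = 1.5)

# independent brute-force Grubbs critical value: invert the t CDF by
# root-finding on pt() instead of calling qt()
grubbs_critical_oracle <- function(n, alpha) {
  p <- 1 - alpha / (2 * n)
  tq <- stats::uniroot(
    function(q) stats::pt(q, df = n - 2) - p,
    lower = 0, upper = 1e4, tol = 1e-13
  )$root
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}
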