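# Shared fixtures, built in code at load time. Kept small; heavier data is
# generated inside the tests that need it.

# Tucker congruence between two loading matrices, best column matching
loading_congruence <- function(L_true, L_est) {
  cg <- abs(crossprod(L_true, L_est)) /
    outer(sqrt(colSums(L_true^2)), sqrt(colSums(L_est^2)))
  mean(apply(cg, 1, max))
}

# benchmark suite at moderate n, reused across files
bench5000 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_benchmark_suite(1, n = 5000)
    cache
  }
})

expect_amat_equal <- function(a, b) {
  testthat::expect_identical(unname(a$amat), unname(b$amat))
}
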