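# Shared fixtures: the 3x2 worked example used throughout the documentation
# (every corrected quantity is hand-computable from it), and a generator of
# random small response-matrix/prediction instances.

toy_Y <- function() response_matrix(rbind(c(1, 3), c(2, 4), c(5, 7)))
toy_nu <- function() c(0, 1, 2)

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

random_instance <- function(m = 10, n = 4, sigma = 0.5) {
  mu <- rnorm(m)
  Y <- matrix(rnorm(m * n, mean = mu, sd = sigma), nrow = m)
  list(Y = response_matrix(Y), nu = rnorm(m), mu = mu)
}
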