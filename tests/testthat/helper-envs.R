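# Shared small environments and a memoising cache for expensive solves.

fov <- function(beta = 0.9, k = 3) observation_model(k, beta)

.solve_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .solve_cache)) {
    assign(key, force(expr), envir = .solve_cache)
  }
  get(key, envir = .solve_cache)
}

# Small-grid solves shared across unit-test files.
grid60 <- function() cached("grid60", belief_grid(3, 60))
cdac60 <- function(cs = 0.1) {
  key <- paste0("cdac60_", cs)
  cached(key, solve_cdac(fov(), cost_params(0.1, cs), grid60()))
}

random_beliefs <- function(n, k, seed = 1) {
  set.seed(seed)
  P <- matrix(stats::rexp(n * k), n, k)
  P / rowSums(P)
}

# Map an action code through a location permutation (fixations permute the
# same way for location-indexed fixation sets).
permute_code <- function(code, perm) {
  k <- length(perm)
  out <- code
  dec <- code < k
  out[dec] <- perm[code[dec] + 1L] - 1L
  out[!dec] <- k + perm[code[!dec] - k + 1L] - 1L
  out
}
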