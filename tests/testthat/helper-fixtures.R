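# Shared fixtures built in code.

toy_counts <- function() {
  m <- matrix(c(1, 2, 0, 5, 3, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  count_table(m)
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small deterministic study used by several suites
cached_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(sim_config(seed = 2024))
    cache
  }
})

# log-normal basis + multinomial compositional counts with a known basis
# correlation structure (independent unless `rho` links the first two taxa)
lognormal_counts <- function(D, n, depth = 5000, rho = 0, sdlog = 1,
                             seed = 1) {
  set.seed(seed)
  Sigma <- diag(D)
  Sigma[1, 2] <- Sigma[2, 1] <- rho
  L <- chol(Sigma * sdlog^2)
  Z <- matrix(rnorm(n * D), n, D) %*% L
  basis <- exp(Z)
  frac <- basis / rowSums(basis)
  counts <- t(vapply(seq_len(n), function(i)
    as.numeric(rmultinom(1, depth, frac[i, ])), numeric(D)))
  m <- t(counts)
  dimnames(m) <- list(sprintf("t%02d", seq_len(D)), sprintf("s%03d", seq_len(n)))
  count_table(m)
}
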