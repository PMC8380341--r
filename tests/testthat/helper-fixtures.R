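# Small shared fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_cfg <- function(seed = 42L, n_planted_triads = 4L, ...) {
  sim_config(n_case = 10L, n_control = 10L,
             n_features = c(mRNA = 60L, lncRNA = 25L, circRNA = 12L,
                            miRNA = 20L),
             n_planted_triads = n_planted_triads, seed = seed, ...)
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) .fixture_env$sim <- simulate_dataset(small_cfg())
  .fixture_env$sim
}

# let-7a, the classic seed-site example
LET7 <- "UGAGGUAGUAGGUUGUAUAGUU"

write_tmp_gmt <- function(lines) {
  p <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}
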