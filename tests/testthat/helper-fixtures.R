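# Shared fixtures, built in code. The small library is cached per test run
# so several test files can reuse it without regenerating.

.fixture_env <- new.env(parent = emptyenv())

small_library <- function() {
  if (is.null(.fixture_env$lib)) {
    cfg <- synthetic_config(300, active_rate = 0.10,
                            motif_effects = c(triazine = 8, phenol = 4),
                            seed = 42)
    .fixture_env$lib <- generate_library(cfg)
  }
  .fixture_env$lib
}

small_curated <- function() {
  if (is.null(.fixture_env$cur)) {
    .fixture_env$cur <- curate_library(small_library()$records)
  }
  .fixture_env$cur
}

small_descriptors <- function() {
  if (is.null(.fixture_env$mat)) {
    .fixture_env$mat <- compute_descriptor_matrix(small_curated())
  }
  .fixture_env$mat
}

small_selected_std <- function() {
  if (is.null(.fixture_env$std)) {
    m <- remove_uninformative(small_descriptors())$matrix
    m <- correlation_cluster_select(m, seed = 7)$matrix
    .fixture_env$std <- standardize_descriptors(m)
  }
  .fixture_env$std
}

# brute-force chi-squared on a 2x2 table, written independently of
# stats::chisq.test: explicit observed/expected arithmetic
chisq2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  obs <- c(a, b, c, d)
  exp <- c((a + b) * (a + c), (a + b) * (b + d),
           (c + d) * (a + c), (c + d) * (b + d)) / n
  stat <- sum((obs - exp)^2 / exp)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
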