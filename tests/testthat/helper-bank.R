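# shared fixtures, built once per test run (synthesis and certification are
# deterministic, so caching is safe)
.fixtures <- new.env(parent = emptyenv())

reference_regions <- function() map_regions()

get_design1 <- function() {
  if (is.null(.fixtures$des1)) {
    .fixtures$des1 <- design_controller(operating_region(-9.5, -5.8, 1))
  }
  .fixtures$des1
}

get_bank <- function() {
  if (is.null(.fixtures$bank)) {
    .fixtures$bank <- partition_and_design(c(-9.5, -0.25),
                                           regions = reference_regions())
  }
  .fixtures$bank
}

get_pipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    .fixtures$pipe <- run_pipeline(quiet = TRUE)
  }
  .fixtures$pipe
}

# random stable SISO state-space model with unit-ball H-inf norm scaling
random_stable_siso <- function(n, seed, norm_cap = NULL) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n)
  A <- A - (max(Re(eigen(A, only.values = TRUE)$values)) + stats::runif(1, 0.5, 1.5)) * diag(n)
  sys <- ss_model(A, stats::rnorm(n), stats::rnorm(n), 0)
  if (!is.null(norm_cap)) {
    nrm <- hinf_norm(sys)$norm
    sys <- ss_model(sys$A, sys$B, sys$C * norm_cap / nrm, 0)
  }
  sys
}
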