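# Shared fixtures for the test suite.  Heavy objects (identified model,
# force quadratic, saccade batches) are built once per test run and cached;
# everything is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_plant <- function() cached("plant", eye_plant())

test_model <- function() {
  cached("model", identify_plant(test_plant(), seed = 1))
}

test_HF <- function() {
  cached("HF", suppressWarnings(estimate_force_hessian(test_plant())))
}

# batches used by several acceptance criteria (matched seeds across
# functionals); sizes chosen to keep the default test run desk-scale
test_batch <- function(functional, n = 300, seed = 1) {
  cached(paste("batch", functional, n, seed, sep = "_"), {
    run_batch(test_plant(), test_model(), cost_weights(functional), n = n,
              seed = seed, HF = test_HF())
  })
}

test_sweep <- function() {
  cached("sweep", suppressWarnings(dz_sweep(n = 150, seed = 1)))
}

test_stretch <- function(functional) {
  cached(paste0("stretch_", functional), {
    stretching_experiment(test_plant(), test_model(),
                          cost_weights(functional), HF = test_HF())
  })
}

# an exactly z-mirror-symmetric variant of the muscle table (rod centers on
# the horizontal midplane), for invariants that assume perfect symmetry
symmetric_muscle_table <- function() {
  mus <- saccade3d:::default_muscle_table()
  mus$MR$P0[3] <- 0; mus$LR$P0[3] <- 0
  mus$SR$P0[3] <- -10; mus$IR$P0[3] <- 10
  mus$SO$P0[3] <- 10; mus$IO$P0[3] <- -10
  mus
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# log-log slope of err(s) across scales (order-of-accuracy estimate)
loglog_slope <- function(scales, errs) {
  unname(coef(lm(log(errs) ~ log(scales)))[2])
}
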