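# Run configuration, seeding, and persistence glue.

#' Named sub-stream seeds
#'
#' Fans a single global seed out into named substreams (targets, PRBS
#' channels, fixtures, ...) so that each component of a run is independently
#' reproducible.  The mapping is a small deterministic hash of the name
#' folded into the seed, kept below 2^31.
#'
#' @param seed integer master seed.
#' @param name substream name.
#' @return integer seed for `set.seed`.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((abs(as.numeric(seed)) * 100003 + h) %% 2147483647)
}

#' Assemble a run configuration
#'
#' Bundles everything that determines an experiment: plant settings, weight
#' set, seeds and batch size.  Serialized alongside outputs for provenance.
#'
#' @param functional cost functional name (see [cost_weights()]).
#' @param n_saccades batch size.
#' @param seed master seed.
#' @param dz plant vertical shift, cm.
#' @param sd_deg target component SD, degrees.
#' @param ... further fields stored verbatim.
#' @export
run_config <- function(functional = "AED", n_saccades = 300, seed = 1,
                       dz = 0, sd_deg = 15, ...) {
  structure(list(functional = functional, n_saccades = n_saccades,
                 seed = seed, dz = dz, sd_deg = sd_deg, ...),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run config:", x$functional,
      sprintf("(n = %d, seed = %d, dz = %+.1f cm, target SD = %g deg)\n",
              x$n_saccades, x$seed, x$dz, x$sd_deg))
  invisible(x)
}

# Stable short hash of an R object (provenance stamps in outputs).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)))
}
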