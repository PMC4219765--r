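# Shared fixtures: the partition model with default Chow--Hall densities and
# the four worked-example individuals used across the tests.
default_model <- function(p_kind = "forbes") partition_model(p_kind = p_kind)

fig <- function(which) profile_from_caption(which)

# Random (imbalance, p) pairs for conservation sweeps.
random_steps <- function(n, seed = 1) {
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    code
  }
  with_seed(seed, list(
    imb = stats::runif(n, -2000, 2000),
    p = stats::runif(n, 0, 1)
  ))
}
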