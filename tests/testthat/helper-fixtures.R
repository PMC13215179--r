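# Shared fixtures, built once per test run and memoised.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A small smooth-style ground-truth case used by several suites.
small_case <- function() {
  fixture("small_case", function()
    make_case("smooth", shape = c(16L, 16L, 16L),
              times = seq(3, 90, by = 6), seed = 7L))
}

sharp_case <- function() {
  fixture("sharp_case", function()
    make_case("sharp", shape = c(16L, 16L, 16L),
              times = seq(3, 90, by = 6), seed = 7L))
}

# Random-but-reproducible model state on a toy domain (untrained networks).
toy_model <- function(seed = 5L, jitter = 0.1) {
  g <- box_grid(c(10L, 10L, 10L), 0.1)
  kp <- array(1e-7, dim = g$shape)
  cs <- conc_series(array(with_seed_val(seed, stats::runif(3000)),
                          dim = c(10, 10, 10, 3)),
                    c(5, 10, 15), g)
  sc <- compute_scales(g, material_constants(), kp, cs)
  m <- model_state(g, sc, 1e-10, 1e-6, t_range = c(5, 15),
                   specs = default_network_specs(width_scale = 0.06,
                                                 n_layers = 2L),
                   seed = seed)
  if (jitter > 0) {
    for (nm in names(m$nets)) {
      p <- tracerflow:::net_params(m$nets[[nm]])
      p <- p + with_seed_val(seed + match(nm, names(m$nets)),
                             stats::rnorm(length(p), sd = jitter))
      m$nets[[nm]] <- tracerflow:::net_set_params(m$nets[[nm]], p)
    }
  }
  m
}

with_seed_val <- function(seed, code) tracerflow:::with_seed(seed, code)
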