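# Shared fixtures. Tests render spirals at 2 px/mm (guide radius 150 px,
# ~330 px canvases) so the full suite stays fast; the package default is
# 4 px/mm.
test_a <- 75 * 2 / (2 * pi * 4.5)

test_spec <- function(seed = 1, tremor_amplitude = 0, tremor_frequency = 0,
                      ...) {
  spiral_spec(a = test_a, tremor_amplitude = tremor_amplitude,
              tremor_frequency = tremor_frequency, seed = seed, ...)
}

# cache for expensive shared objects (rendered images, analyses)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

clean_spiral_image <- function() {
  cached("clean_img", render_spiral(test_spec(seed = 1, intensity_jitter = 0)))
}

clean_spiral_analysis <- function() {
  cached("clean_analysis", analyze_spiral(clean_spiral_image()))
}

# two straight ribbons crossing: a drawing whose skeleton has junctions
crossing_image <- function() {
  img <- matrix(255, 120, 120)
  img[58:60, 10:110] <- 80
  img[10:110, 58:60] <- 80
  img
}

# a quick synthetic feature table (no image pipeline): two well-separated
# Gaussian blobs in feature space
blob_table <- function(n_per_class = 20, gap = 20, seed = 42,
                       feature_set = "FP") {
  cols <- spiralpd:::feature_columns(feature_set)
  with_seed_local <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  with_seed_local(seed, {
    n <- 2 * n_per_class
    lab <- rep(c("healthy", "parkinson"), each = n_per_class)
    X <- matrix(rnorm(n * length(cols)), n, length(cols))
    X[lab == "parkinson", ] <- X[lab == "parkinson", ] + gap
    df <- data.frame(id = sprintf("r%03d", seq_len(n)), label = lab,
                     as.data.frame(X))
    names(df)[-(1:2)] <- cols
    attr(df, "feature_set") <- feature_set
    class(df) <- c("feature_table", "data.frame")
    df
  })
}
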