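# small, fast fixtures shared across test files

# coarse-axis params: few bands so covariances stay well conditioned on tiny
# images; no region table is used at this spacing
small_params <- function(...) {
  phantom_params(image_size = c(24, 24), axis_spacing = 12, ...)
}

# default-spacing params on a small image for feature/region tests
feature_params <- function(...) {
  phantom_params(image_size = c(16, 16), ...)
}

# a labeled two-class feature table with `n_info` informative and `n_noise`
# pure-noise metric columns, per-mouse grouping for LOMO helpers
sim_feature_table <- function(n_per_class = 60, n_info = 1, n_noise = 9,
                              effect = 3, n_mice = 4, seed = 1,
                              classes = c("benign", "cancer")) {
  withr_seed <- function(s, code) { set.seed(s); force(code) }
  withr_seed(seed, {
    n <- n_per_class * length(classes)
    lab <- rep(classes, each = n_per_class)
    X <- matrix(rnorm(n * (n_info + n_noise)), n)
    for (k in seq_len(n_info))
      X[, k] <- X[, k] + effect * (lab == classes[2])
    colnames(X) <- c(sprintf("info_%02d", seq_len(n_info)),
                     sprintf("noise_%02d", seq_len(n_noise)))
    tb <- tibble::tibble(
      mouse_id = rep(sprintf("m%02d", seq_len(n_mice)), length.out = n),
      row = seq_len(n), col = 1L, label = lab
    )
    dplyr::bind_cols(tb, tibble::as_tibble(X))
  })
}
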