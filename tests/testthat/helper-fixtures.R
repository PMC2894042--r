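## one noise-free 64-array experiment with a single planted D effect
## (log-FC 0.6 on probe 3), memoized because several files reuse it
noise_free_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tpl <- make_array_template(30, c(unknown = 1))
    truth <- null_truth(tpl)
    truth$D[3] <- 0.3            # log-FC 0.6
    g <- build_loop_design(enumerate_treatments(), 4L)
    X <- build_design_matrix(g)
    arrs <- simulate_arrays(g, tpl, truth, noise = zero_noise_config(),
                            seed = 17)
    prep <- preprocess_arrays(arrs, within_method = "none",
                              between_method = "none")
    cache <<- list(truth = truth, X = X, prep = prep,
                   fit = fit_factorial(prep, X))
    cache
  }
})
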