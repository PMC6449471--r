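# Shared fixtures, generated in code and cached for the duration of the run.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, ...) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- suppressWarnings(simulate_session(...))
  }
  .session_cache[[key]]
}

# A hand-built trace with known analytic channels.
make_trace <- function(df, classes, fs = 20) {
  df <- cbind(data.frame(time_s = (seq_len(nrow(df)) - 1) / fs), df)
  kinematic_trace(df, sample_rate = fs, channel_classes = classes)
}

# Independent pseudo-R2 oracle via the textbook deviance formulas:
# pR2 = 1 - D_model / D_null with D = 2 * sum(y*log(y/mu) - (y - mu)).
pr2_deviance_oracle <- function(y, yhat, ybar) {
  dev <- function(mu) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  1 - dev(yhat) / dev(rep(ybar, length(y)))
}

# A quick training configuration for smoke-level fits.
quick_cfg <- function(...) {
  training_config(max_epochs = 30, ...)
}
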