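# shared builders for small in-memory fixtures

# exact points on a line, optionally replicated
line_series <- function(slope, intercept, x, replicates = 1) {
  x <- rep(x, each = replicates)
  data.frame(concentration = x,
             replicate = rep(seq_len(replicates), times = length(unique(x))),
             response_ratio = slope * x + intercept)
}

addition_line <- function(slope, intercept, spikes = c(0, 0.05, 0.1, 0.25, 0.5)) {
  data.frame(spike_level = spikes,
             replicate = 1L,
             response_ratio = slope * spikes + intercept)
}

# closed-form normal-equations OLS, independent of stats::lm
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

# minimal inventory with controllable tokens / detections
tiny_inventory <- function(tokens,
                           samples = c("AS_01", "AS_02"),
                           detections = NULL) {
  n <- length(tokens)
  df <- data.frame(compound = paste0("cmp", seq_len(n)),
                   cas = paste0("0-00-", seq_len(n)),
                   rt_min = seq_len(n),
                   cramer_class = rep("I", n),
                   sml_token = tokens,
                   stringsAsFactors = FALSE)
  for (s in samples) for (sol in c("ACN", "HEX")) {
    col <- paste0(s, "_", sol)
    df[[col]] <- if (is.null(detections)) FALSE else detections[[col]] %||% FALSE
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
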