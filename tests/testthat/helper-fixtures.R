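# Small fixtures shared across the test files.

# A 4-indicator schema (2 per subsystem, one negative-direction) for
# tests that do not need the full 28-indicator default.
mini_schema <- function(neg = TRUE) {
  tibble::tibble(
    id = c("h_a", "h_b", "e_a", "e_b"),
    name = c("health A", "health B", "economy A", "economy B"),
    system = c("health", "health", "economy", "economy"),
    layer = "test",
    direction = c(1L, 1L, 1L, if (neg) -1L else 1L)
  )
}

# Balanced long panel over mini_schema with deterministic values.
mini_panel <- function(regions = c("north", "south"),
                       years = c(2011L, 2012L),
                       schema = mini_schema()) {
  g <- expand.grid(
    region = regions, year = years, indicator = schema$id,
    stringsAsFactors = FALSE
  )
  g$value <- seq_len(nrow(g)) + as.integer(factor(g$indicator)) * 10
  tibble::as_tibble(g)
}

# Long unit-root test panel: N independent series of length T.
rw_panel <- function(N, T, random_walk = TRUE) {
  do.call(rbind, lapply(seq_len(N), function(i) {
    e <- stats::rnorm(T)
    data.frame(
      region = sprintf("r%02d", i), year = seq_len(T),
      value = if (random_walk) cumsum(e) else e
    )
  }))
}
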