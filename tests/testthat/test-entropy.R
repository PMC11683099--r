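test_that("min-max standardization maps endpoints and reverses cost indicators", {
  s <- mini_schema()
  p <- mini_panel(regions = c("a", "b", "c"), years = 2011L)
  p$value[p$indicator == "h_a"] <- c(2, 4, 6)
  p$value[p$indicator == "e_b"] <- c(100, 102, 104) # direction -1
  eps <- 1e-4
  n <- normalize_indicators(p, s, epsilon = eps)
  expect_equal(
    sort(n$value[n$indicator == "h_a"]),
    c(0, 0.5, 1) + eps
  )
  # reversed: largest raw value maps to the bottom
  e_b <- n[n$indicator == "e_b", ]
  expect_equal(
    e_b$value[order(p$value[p$indicator == "e_b"])],
    c(1, 0.5, 0) + eps
  )
  expect_true(all(n$value > 0 & n$value <= 1 + eps))
})

test_that("a constant indicator column is reported as degenerate", {
  p <- mini_panel()
  p$value[p$indicator == "h_b"] <- 5
  expect_error(
    normalize_indicators(p, mini_schema()),
    "degenerate indicator.*h_b"
  )
})

test_that("entropy weights match a hand-evaluated oracle and basic symmetries", {
  # 3 observations x 2 indicators, evaluated independently through the
  # p -> e -> d -> w chain (values frozen from a scratch evaluation)
  norm <- tibble::tibble(
    region = rep(c("a", "b", "c"), 2),
    year = 2011L,
    indicator = rep(c("h_a", "h_b"), each = 3),
    value = c(0.1, 0.2, 0.9, 0.9, 0.8, 0.1)
  )
  w <- entropy_weights(norm, mini_schema(), systems = "health")
  expect_equal(
    w$weight[match(c("h_a", "h_b"), w$indicator)],
    c(0.620108601922, 0.379891398078),
    tolerance = 1e-10
  )

  # single indicator gets weight 1
  w1 <- entropy_weights(norm[norm$indicator == "h_a", ], mini_schema(),
    systems = "health"
  )
  expect_equal(w1$weight, 1)

  # identical columns share the weight equally
  dup <- norm
  dup$value[dup$indicator == "h_b"] <- dup$value[dup$indicator == "h_a"]
  w2 <- entropy_weights(dup, mini_schema(), systems = "health")
  expect_equal(w2$weight, c(0.5, 0.5))
})

test_that("entropy weights reject non-positive values and uninformative systems", {
  norm <- tibble::tibble(
    region = c("a", "b"), year = 2011L,
    indicator = "h_a", value = c(0, 1)
  )
  expect_error(entropy_weights(norm, mini_schema()), "strictly positive")
  flat <- tibble::tibble(
    region = rep(c("a", "b"), 2), year = 2011L,
    indicator = rep(c("h_a", "h_b"), each = 2),
    value = 0.5
  )
  expect_error(
    entropy_weights(flat, mini_schema(), systems = "health"),
    "no information"
  )
})

test_that("the composite index is the weighted sum, bounded by 1", {
  s <- mini_schema()
  norm <- tibble::tibble(
    region = "a", year = 2011L,
    indicator = c("h_a", "h_b"), value = c(0.4, 0.6)
  )
  w <- tibble::tibble(
    system = "health", indicator = c("h_a", "h_b"), weight = c(0.5, 0.5)
  )
  expect_equal(composite_index(norm, w, s)$index, 0.5)

  w2 <- tibble::tibble(
    system = "health", indicator = c("h_a", "h_b"),
    weight = c(0.25, 0.75)
  )
  norm2 <- norm
  norm2$value <- c(0.2, 0.4)
  expect_equal(composite_index(norm2, w2, s)$index, 0.35)

  norm3 <- norm
  norm3$value <- c(1, 1)
  expect_equal(composite_index(norm3, w, s)$index, 1)

  # weight/indicator mismatch
  w_bad <- w
  w_bad$indicator[2] <- "h_c"
  expect_error(composite_index(norm, w_bad, s), "configuration error")
  w_bad2 <- w
  w_bad2$weight <- c(0.7, 0.6)
  expect_error(composite_index(norm, w_bad2, s), "configuration error")
})

test_that("weights are a simplex, order- and scale-invariant; U is monotone", {
  s <- mini_schema()
  set.seed(7)
  for (rep in 1:5) {
    p <- mini_panel(regions = c("a", "b", "c", "d"), years = 2011:2015)
    p$value <- stats::runif(nrow(p), 1, 100)
    n <- normalize_indicators(p, s)
    w <- entropy_weights(n, s)
    sums <- tapply(w$weight, w$system, sum)
    expect_true(all(abs(sums - 1) < 1e-10))
    expect_true(all(w$weight >= 0))

    # permutation invariance: shuffling rows changes nothing
    p_shuf <- p[sample(nrow(p)), ]
    w_shuf <- entropy_weights(normalize_indicators(p_shuf, s), s)
    expect_equal(dplyr::arrange(w, indicator), dplyr::arrange(w_shuf, indicator))

    # scale invariance: rescaling a raw column leaves its weight alone
    p_scaled <- p
    i <- p_scaled$indicator == "h_a"
    p_scaled$value[i] <- p_scaled$value[i] * 37.5
    w_scaled <- entropy_weights(normalize_indicators(p_scaled, s), s)
    expect_equal(dplyr::arrange(w, indicator), dplyr::arrange(w_scaled, indicator))

    # monotonicity: raising a positive indicator (interior point) raises U,
    # raising a cost indicator lowers U, at fixed weights
    u0 <- composite_index(n, w, s)
    n_up <- n
    j <- which(n_up$indicator == "h_a")[2]
    n_up$value[j] <- n_up$value[j] + 0.01
    u_up <- composite_index(n_up, w, s)
    h0 <- u0[u0$system == "health", ]
    h1 <- u_up[u_up$system == "health", ]
    expect_true(all(h1$index >= h0$index))
    expect_true(any(h1$index > h0$index))
  }
})

test_that("raw direction handling flows through the full pipeline monotonically", {
  s <- mini_schema()
  p <- mini_panel(regions = c("a", "b", "c"), years = 2011:2013)
  set.seed(3)
  p$value <- stats::runif(nrow(p), 10, 20)
  base <- run_coordination(p, s)
  # increase the cost indicator e_b for one region-year (interior)
  p2 <- p
  k <- which(p2$indicator == "e_b")[4]
  p2$value[k] <- p2$value[k] + 0.5
  w <- attr(base, "weights")
  after <- run_coordination(p2, s, weights = w)
  cell <- p2[k, ]
  i <- base$region == cell$region & base$year == cell$year
  expect_lt(after$U_e[i], base$U_e[i])
})
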