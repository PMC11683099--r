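test_that("relative development classifies exactly at the 0.8/1.2 boundaries", {
  rd <- relative_development(
    c(0.8, 0.8 + 1e-9, 1.2 - 1e-9, 1.2, 0.5, 0.5),
    c(1, 1, 1, 1, 1, 0.5)
  )
  expect_equal(
    as.character(rd$category),
    c(
      "health_lagging", "dynamic_equilibrium", "dynamic_equilibrium",
      "economy_lagging", "health_lagging", "dynamic_equilibrium"
    )
  )
  expect_equal(rd$S[6], 1)

  # published-scale examples: S = 0.382 lags in health, 1.319 in economy
  expect_equal(
    as.character(relative_development(0.382, 1)$category),
    "health_lagging"
  )
  expect_equal(
    as.character(relative_development(1.319, 1)$category),
    "economy_lagging"
  )

  expect_error(relative_development(0.5, 0), "undefined ratio")
  expect_error(relative_development(-0.1, 0.5), "domain error")
})

test_that("coupling degree is 1 at equality, 0 at the boundary, and matches the closed form", {
  expect_equal(coupling_degree(0.5, 0.5), 1)
  expect_equal(coupling_degree(0, 0.3), 0)
  expect_equal(coupling_degree(0.0754, 0.1974), 0.8944272, tolerance = 1e-6)
  expect_error(coupling_degree(0, 0), "undefined coupling")
  expect_error(coupling_degree(-0.1, 0.5), "domain error")

  # symmetry, scale invariance, and C = 1 iff equality
  set.seed(11)
  u <- stats::runif(200, 0.01, 1)
  v <- stats::runif(200, 0.01, 1)
  expect_equal(coupling_degree(u, v), coupling_degree(v, u))
  expect_equal(coupling_degree(3.7 * u, 3.7 * v), coupling_degree(u, v))
  c_uv <- coupling_degree(u, v)
  expect_true(all(c_uv >= 0 & c_uv <= 1))
  expect_true(all(c_uv[abs(u - v) > 1e-4] < 1))
  expect_equal(coupling_degree(u, u), rep(1, length(u)), tolerance = 1e-15)
})

test_that("coordination index is the convex combination with validated coefficients", {
  expect_equal(coordination_index(0.0754, 0.1974, 0.5, 0.5), 0.1364)
  expect_equal(coordination_index(1, 1, 0.5, 0.5), 1)
  expect_equal(coordination_index(0.2, 0.6, 0.25, 0.75), 0.5)
  expect_error(coordination_index(1, 1, 0.6, 0.6), "configuration error")
  expect_error(coordination_index(1, 1, -0.2, 1.2), "configuration error")
})

test_that("coupling coordination degree composes to the quartic-mean identity", {
  expect_equal(coupling_coordination(1, 1), 1)
  expect_equal(coupling_coordination(0, 0.5), 0)
  expect_error(coupling_coordination(-0.1, 1), "domain error")
  expect_error(coupling_coordination(1.1, 1), "domain error")

  set.seed(5)
  u <- stats::runif(1000, 1e-6, 1)
  v <- stats::runif(1000, 1e-6, 1)
  d <- coupling_coordination(
    coupling_degree(u, v),
    coordination_index(u, v, 0.5, 0.5)
  )
  expect_equal(d, (u * v)^0.25, tolerance = 1e-12)

  # D increases in each argument when alpha = beta = 0.5
  d_up <- coupling_coordination(
    coupling_degree(u + 1e-3, v),
    coordination_index(u + 1e-3, v, 0.5, 0.5)
  )
  expect_true(all(d_up > d))
})

test_that("grade bins partition [0, 1] and reproduce the published grade labels", {
  g <- classify_grade(c(0.3499, 0.9001, 0, 1))
  expect_equal(g$grade, c("IV", "X", "I", "X"))
  expect_equal(g$type[1], "mild disorder")
  expect_equal(g$type[2], "high-quality coordination")
  expect_equal(g$stage[1], "low-level coordination")
  expect_equal(g$type[3], "extreme disorder")

  # exhaustive sweep: every value classified, boundaries belong upward
  d <- seq(0, 1, by = 1e-4)
  sweep <- classify_grade(d)
  expect_false(anyNA(sweep$grade))
  expect_equal(unique(sweep$grade), grade_scheme()$grade)
  at_bounds <- classify_grade(seq(0, 0.9, by = 0.1))
  expect_equal(at_bounds$grade, grade_scheme()$grade)

  expect_error(classify_grade(-0.01), "domain error")
  expect_error(classify_grade(1.01), "domain error")
})

test_that("indices recovered from gap and ratio invert exactly and flag bad inputs", {
  r <- recover_indices(-0.122, 0.382)
  expect_equal(r$U_h, 0.0754110, tolerance = 1e-6)
  expect_equal(r$U_e, 0.1974110, tolerance = 1e-6)
  r2 <- recover_indices(0.152, 1.207)
  expect_equal(r2$U_h, 0.8863, tolerance = 1e-4)
  expect_equal(r2$U_e, 0.7343, tolerance = 1e-4)

  # round-trip identity over random pairs
  set.seed(21)
  uh <- stats::runif(100, 0.01, 1.4)
  ue <- stats::runif(100, 0.01, 1.4)
  keep <- abs(uh / ue - 1) > 1e-3
  uh <- uh[keep]
  ue <- ue[keep]
  rec <- recover_indices(uh - ue, uh / ue)
  expect_equal(rec$U_h, uh, tolerance = 1e-12)
  expect_equal(rec$U_e, ue, tolerance = 1e-12)

  expect_error(recover_indices(0, 1), "non-invertible")
  expect_warning(recover_indices(0.5, 1.01), "outside")
})

test_that("run_coordination populates every record deterministically", {
  panel <- simulate_indicator_panel(synthetic_config(seed = 42))
  rec <- run_coordination(panel)
  expect_equal(nrow(rec), 50)
  expect_false(anyNA(rec))
  expect_true(all(c(
    "region", "year", "U_h", "U_e", "S", "S_category", "C", "T", "D",
    "stage", "type", "grade"
  ) %in% names(rec)))
  expect_true(all(rec$C >= 0 & rec$C <= 1))
  expect_equal(rec$D^2, rec$C * rec$T, tolerance = 1e-12)

  rec2 <- run_coordination(simulate_indicator_panel(synthetic_config(seed = 42)))
  expect_identical(rec, rec2)
})

test_that("mirrored subsystems couple perfectly", {
  s <- mini_schema(neg = FALSE)
  p <- mini_panel(regions = c("a", "b", "c"), years = 2011:2013, schema = s)
  set.seed(13)
  p$value[p$indicator == "h_a"] <- stats::runif(9, 1, 5)
  p$value[p$indicator == "h_b"] <- stats::runif(9, 2, 9)
  p$value[p$indicator == "e_a"] <- p$value[p$indicator == "h_a"]
  p$value[p$indicator == "e_b"] <- p$value[p$indicator == "h_b"]
  rec <- run_coordination(p, s)
  expect_equal(rec$C, rep(1, nrow(rec)), tolerance = 1e-12)
  expect_equal(rec$U_h, rec$U_e, tolerance = 1e-12)
})
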