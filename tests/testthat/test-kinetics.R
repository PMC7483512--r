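test_that("pH response is zero outside the corners, full on the plateau, linear on the ramps", {
  cs <- ph_corners(5.3, 6.0, 7.0, 7.5)
  expect_equal(ph_growth_factor(5.0, cs), 0)
  expect_equal(ph_growth_factor(5.3, cs), 0)
  expect_equal(ph_growth_factor((6.0 + 7.0) / 2, cs), 1)
  expect_equal(ph_growth_factor((5.3 + 6.0) / 2, cs), 0.5)  # ramp midpoint
  expect_equal(ph_growth_factor(7.5, cs), 0)
  expect_equal(ph_growth_factor(8.0, cs), 0)
  # degenerate ramps: c1 == c2 jumps straight to the plateau boundary
  cs2 <- ph_corners(5.5, 5.5, 6.5, 7.0)
  expect_equal(ph_growth_factor(5.5, cs2), 1)
})

test_that("pH response is continuous and piecewise linear for random corner sets", {
  set.seed(11)
  for (i in 1:50) {
    cc <- sort(runif(4, 4, 8))
    if (any(diff(cc) < 1e-3)) next  # keep ramps non-degenerate
    cs <- ph_corners(cc[1], cc[2], cc[3], cc[4])
    eps <- 1e-9
    for (knot in cc) {
      lo <- ph_growth_factor(knot - eps, cs)
      hi <- ph_growth_factor(knot + eps, cs)
      expect_lt(abs(hi - lo), 1e-6)
    }
    # linear within each segment: midpoint value is mean of endpoint values
    segs <- cbind(c(cc[1], cc[2], cc[3]), c(cc[2], cc[3], cc[4]))
    for (s in seq_len(nrow(segs))) {
      a <- segs[s, 1] + 1e-6; b <- segs[s, 2] - 1e-6
      expect_equal(ph_growth_factor((a + b) / 2, cs),
                   (ph_growth_factor(a, cs) + ph_growth_factor(b, cs)) / 2,
                   tolerance = 1e-8)
    }
    expect_true(all(ph_growth_factor(seq(3, 9, 0.05), cs) >= 0))
    expect_true(all(ph_growth_factor(seq(3, 9, 0.05), cs) <= 1))
  }
})

test_that("invalid corner ordering is rejected", {
  expect_error(ph_corners(6.0, 5.5, 7.0, 7.5), "ordering")
  expect_error(ph_growth_factor(6, c(7, 6, 6.5, 8)), "ordering")
})

test_that("lactate suppression follows Ki/(Ki+L)", {
  expect_equal(lactate_suppression(0, 15), 1)
  expect_equal(lactate_suppression(15, 15), 0.5)   # 50% inhibition at L = Ki
  expect_equal(lactate_suppression(45, 15), 0.25)
  expect_equal(lactate_suppression(5, 5), 0.5)
  expect_error(lactate_suppression(-1, 15), ">= 0")
  expect_error(lactate_suppression(10, 0), "Ki")
})

test_that("lactate suppression is strictly decreasing and bounded in (0, 1]", {
  set.seed(12)
  for (i in 1:20) {
    Ki <- runif(1, 1, 50)
    L <- sort(runif(25, 0, 200))
    f <- lactate_suppression(L, Ki)
    expect_true(all(diff(f) < 0))
    expect_true(all(f > 0 & f <= 1))
  }
})

test_that("Monod term saturates with half-rate at Ks", {
  expect_equal(monod_term(0.001, 0.001), 0.5)
  expect_equal(monod_term(0, 0.001), 0)
  expect_equal(monod_term(0.003, 0.001), 0.75)
  expect_error(monod_term(-0.1, 0.001), ">= 0")
})

test_that("regime membership matches the pH gate", {
  full <- inhibition_regime("full")
  expect_identical(inhibited_mfgs(full, 6.5), "M1")
  expect_setequal(inhibited_mfgs(full, 5.5),
                  paste0("M", c(1, 2, 3, 5, 6, 7, 8, 9, 10)))
  lub <- inhibition_regime("lub_exempt")
  expect_false(any(c("M7", "M8") %in% inhibited_mfgs(lub, 5.5)))
  expect_true("M5" %in% inhibited_mfgs(lub, 5.5))
  expect_length(inhibited_mfgs(inhibition_regime("none"), 5.5), 0)
})

test_that("strain growth rate composes the three factors multiplicatively", {
  strain <- list(
    mfg = "M5", Ki = 15,
    ph_corners = ph_corners(5.0, 5.5, 6.9, 7.5),
    pathways = list(carb = list(mu_max = 6, yield = 0.3, primary = "starch",
                                substrates = c(starch = 1), products = c(butyrate = 1),
                                Ks = c(starch = 0.001))))
  conc <- c(starch = 0.001, lactate = 15)  # S = Ks, L = Ki, pH on plateau
  mu <- strain_growth_rate(strain, conc, inhibition_regime("full"), pH = 5.6)
  expect_equal(unname(mu), 6 * 0.5 * 1 * 0.5)  # 1.5/d

  # factors commute: same value computed in any order of multiplication
  parts <- c(6, monod_term(0.001, 0.001), ph_growth_factor(5.6, strain$ph_corners),
             lactate_suppression(15, 15))
  for (ord in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    expect_equal(unname(mu), prod(parts[ord]))
  }

  # absent substrate -> 0; pH outside corners -> 0
  expect_equal(unname(strain_growth_rate(strain, c(starch = 0, lactate = 0),
                                         inhibition_regime("none"), 5.6)), 0)
  expect_equal(unname(strain_growth_rate(strain, conc,
                                         inhibition_regime("none"), 4.9)), 0)

  # co-substrate pathways are limited by the scarcest substrate
  strain$pathways$carb$substrates <- c(starch = 4, acetate = 2)
  strain$pathways$carb$Ks <- c(starch = 0.001, acetate = 1 / 60)
  conc2 <- c(starch = 1, acetate = 0, lactate = 0)
  expect_equal(unname(strain_growth_rate(strain, conc2,
                                         inhibition_regime("none"), 5.6)), 0)
})
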