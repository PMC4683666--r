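full_2x2 <- function() {
  ncii_design(c("A", "B"), c("C", "D"),
              data.frame(maternal = c("A", "A", "B", "B"),
                         paternal = c("C", "D", "C", "D")))
}

test_that("GCA and SCA match hand arithmetic on a 2 x 2 table", {
  d <- full_2x2()
  # F = [[10,12],[14,16]] is purely additive
  ca <- combining_ability(c(10, 12, 14, 16), d)
  expect_equal(ca$grand_mean, 13)
  expect_equal(unname(ca$gca_maternal), c(-2, 2))
  expect_equal(unname(ca$gca_paternal), c(-1, 1))
  expect_equal(unname(ca$sca), rep(0, 4))
  # an interaction in the last cell shows up only in SCA
  ca2 <- combining_ability(c(10, 12, 14, 20), d)
  s22 <- 20 - ca2$grand_mean - ca2$gca_maternal["B"] - ca2$gca_paternal["D"]
  expect_equal(unname(ca2$sca["B x D"]), unname(s22))
  # row sums of SCA vanish in the complete factorial
  expect_equal(sum(ca2$sca[1:2]), 0, tolerance = 1e-12)
  expect_equal(sum(ca2$sca[3:4]), 0, tolerance = 1e-12)
  # constant tables give zero GCA everywhere
  ca3 <- combining_ability(rep(7, 4), d)
  expect_equal(unname(c(ca3$gca_maternal, ca3$gca_paternal)), rep(0, 4))
})

test_that("GCA equals the least-squares main effects in a balanced factorial", {
  set.seed(21)
  d <- partial_ncii(3, 3, t = 3)
  f <- rnorm(9, mean = 50, sd = 4)
  ca <- combining_ability(f, d)
  fit <- lm(f ~ m + p, data = data.frame(
    m = factor(d$crosses$maternal), p = factor(d$crosses$paternal)),
    contrasts = list(m = "contr.sum", p = "contr.sum"))
  co <- coef(fit)
  expect_equal(unname(ca$gca_maternal),
               unname(c(co["m1"], co["m2"], -co["m1"] - co["m2"])),
               tolerance = 1e-10)
  expect_equal(unname(ca$gca_paternal),
               unname(c(co["p1"], co["p2"], -co["p1"] - co["p2"])),
               tolerance = 1e-10)
})

test_that("zero-sum identities hold in a complete factorial", {
  set.seed(4)
  d <- partial_ncii(8, 8, t = 8)
  f <- rnorm(64)
  ca <- combining_ability(f, d)
  expect_equal(sum(ca$gca_maternal), 0, tolerance = 1e-10)
  expect_equal(sum(ca$gca_paternal), 0, tolerance = 1e-10)
  for (m in d$maternal)
    expect_equal(sum(ca$sca[d$crosses$maternal == m]), 0, tolerance = 1e-10)
  for (p in d$paternal)
    expect_equal(sum(ca$sca[d$crosses$paternal == p]), 0, tolerance = 1e-10)
})

test_that("location and scale behave correctly for GCA/SCA and MPH", {
  set.seed(5)
  d <- partial_ncii(4, 4, t = 4)
  f <- rnorm(16, 100, 3)
  ca <- combining_ability(f, d)
  # adding a constant leaves SCA unchanged, shifts only the grand mean
  ca_shift <- combining_ability(f + 11, d)
  expect_equal(ca_shift$sca, ca$sca, tolerance = 1e-12)
  expect_equal(ca_shift$gca_maternal, ca$gca_maternal, tolerance = 1e-12)
  # scaling scales GCA/SCA by the same factor
  ca_scale <- combining_ability(3 * f, d)
  expect_equal(ca_scale$sca, 3 * ca$sca, tolerance = 1e-10)
  # MPH is scale invariant
  expect_equal(mph(3 * 11, 3 * 8, 3 * 12), mph(11, 8, 12))
})

test_that("MPH matches hand arithmetic and rejects zero mid-parent", {
  expect_equal(mph(11, 8, 12), 10)
  expect_equal(mph(10, 8, 12), 0)
  expect_equal(mph(9, 8, 12), -10)
  expect_error(mph(5, -4, 4), "undefined")
})

test_that("SCA is exactly zero under a purely additive noiseless model", {
  map <- genome_map(1, 60, 4)
  set.seed(8)
  par <- simulate_parents(map, 24, ids = c(paste0("M", 1:12), paste0("P", 1:12)))
  d <- partial_ncii(12, 12, t = 12)
  f1 <- deduce_f1(par, d)
  qtl <- calibrate_effects(
    qtl_model(data.frame(type = "a", marker1 = c("M1", "M3"), marker2 = NA,
                         h2 = c(0.2, 0.2)), mu = 100, sigma2_e = 1e-12), map)
  y <- 100 + genetic_values(f1, qtl)
  ca <- combining_ability(y, d)
  expect_equal(max(abs(ca$sca)), 0, tolerance = 1e-8)
})

test_that("dependent variables map onto the correct population", {
  map <- tiny_map()
  set.seed(12)
  par <- simulate_parents(map, 12, ids = c(paste0("M", 1:6), paste0("P", 1:6)))
  d_full <- partial_ncii(6, 6, t = 6)
  f1 <- deduce_f1(par, d_full)
  qtl <- calibrate_effects(
    qtl_model(data.frame(type = "a", marker1 = "M2", marker2 = NA, h2 = 0.2),
              mu = 100, sigma2_e = 1), map)
  y_f1 <- simulate_phenotypes(f1, qtl)
  y_par <- simulate_phenotypes(par, qtl)

  gca <- dependent_variable("gca", y_f1, d_full)
  expect_equal(gca$population, "parents")
  expect_equal(length(gca$response), 12)
  expect_setequal(names(gca$response), rownames(par$geno))

  tr <- dependent_variable("trait", y_f1, d_full, subset = 1:12)
  expect_equal(tr$population, "f1")
  expect_equal(length(tr$response), 12)

  sc <- dependent_variable("sca", y_f1, d_full)
  expect_equal(length(sc$response), 36)

  mp <- dependent_variable("mph", y_f1, d_full, parent_values = y_par)
  expect_equal(length(mp$response), 36)
  expect_error(dependent_variable("mph", y_f1, d_full), "parental")

  # SCA in a one-cross-per-parent design is degenerate
  d1 <- partial_ncii(6, 6, t = 1)
  expect_error(dependent_variable("sca", y_f1[1:6], d1), "degenerate")
})
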