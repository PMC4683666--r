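test_that("Haldane map function behaves at its limits", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(1e9), 0.5)
  expect_equal(haldane(5), (1 - exp(-0.1)) / 2)
  expect_true(all(diff(haldane(seq(0, 200, by = 5))) > 0))
})

test_that("simulated parents are homozygous with the requested allele frequency", {
  map <- genome_map(2, 50, 6)
  par <- simulate_parents(map, 2000, p = 0.3, seed = 42)
  expect_true(all(par$geno %in% c(0L, 2L)))
  freq <- colMeans(par$geno) / 2
  # binomial tolerance: 4 sd at n = 2000
  expect_true(all(abs(freq - 0.3) < 4 * sqrt(0.3 * 0.7 / 2000)))
  # determinism
  par2 <- simulate_parents(map, 2000, p = 0.3, seed = 42)
  expect_identical(par$geno, par2$geno)
})

test_that("adjacent-marker LD decays according to the map distance", {
  map <- genome_map(1, 10, 3)   # markers 5 cM apart
  par <- simulate_parents(map, 10000, p = 0.5, seed = 7)
  r2 <- cor(par$geno[, 1], par$geno[, 2])^2
  expect_equal(r2, exp(-2 * 5 / 100)^2, tolerance = 0.04)
  # 10 cM apart: correlation is the product across intervals
  r2_far <- cor(par$geno[, 1], par$geno[, 3])^2
  expect_equal(r2_far, exp(-2 * 10 / 100)^2, tolerance = 0.05)
})

test_that("invalid parent simulation inputs are rejected", {
  map <- tiny_map()
  expect_error(simulate_parents(map, 0), "positive")
  expect_error(simulate_parents(map, 5, p = 0), "between")
  expect_error(simulate_parents(map, 5, p = 1), "between")
})

test_that("F1 genotypes are the union of the parental alleles", {
  map <- tiny_map()
  par <- tiny_parents(map)
  d <- ncii_design(c("M1", "M2"), c("P1", "P2"),
                   expand.grid(maternal = c("M1", "M2"),
                               paternal = c("P1", "P2"),
                               stringsAsFactors = FALSE))
  f1 <- deduce_f1(par, d)
  # M1 x P1 at marker 2: QQ x qq -> Qq
  expect_equal(unname(f1$geno["M1 x P1", 2]), 1L)
  # M1 x P1 at marker 1: QQ x QQ -> QQ
  expect_equal(unname(f1$geno["M1 x P1", 1]), 2L)
  # M2 x P2 at marker 1: qq x qq -> qq
  expect_equal(unname(f1$geno["M2 x P2", 1]), 0L)
  expect_true(all(f1$role == "F1"))
  # deterministic given parents and design
  expect_identical(f1$geno, deduce_f1(par, d)$geno)
})

test_that("F1 genotype frequencies approach 1/4, 1/2, 1/4 at p = 0.5", {
  map <- genome_map(1, 400, 5)   # far-apart markers, nearly independent
  par <- simulate_parents(map, 160, p = 0.5, seed = 3,
                          ids = c(paste0("M", 1:80), paste0("P", 1:80)))
  d <- partial_ncii(80, 80, t = 80)
  f1 <- deduce_f1(par, d)
  frq <- table(factor(f1$geno, levels = 0:2)) / length(f1$geno)
  expect_equal(as.numeric(frq), c(0.25, 0.5, 0.25), tolerance = 0.12)
})

test_that("heterozygous parents are rejected", {
  map <- tiny_map()
  geno <- matrix(1L, 1, 5, dimnames = list("X", map$marker))
  expect_error(genotype_table(geno, map, role = "parent"), "homozygous")
  expect_silent(genotype_table(geno, map, role = "F1"))
})

test_that("effect calibration matches the closed-form coded-column variances", {
  map <- tiny_map()
  s2P <- 1 / (1 - 0.25)   # sigma2_e = 1, total h2 = 0.25
  m <- qtl_model(data.frame(type = c("a", "d"),
                            marker1 = c("M1", "M3"),
                            marker2 = NA, h2 = c(0.1, 0.15)),
                 mu = 0, sigma2_e = 1)
  cal <- calibrate_effects(m, map)
  expect_equal(cal$sigma2_P, s2P)
  expect_equal(cal$effects$effect[1], sqrt(2 * 0.1 * s2P))   # Var(w) = 1/2
  expect_equal(cal$effects$effect[2], 2 * sqrt(0.15 * s2P))  # Var(v) = 1/4
  # epistatic, unlinked (different chromosomes)
  map2 <- genome_map(2, 40, 3)
  for (ty in c("aa", "ad", "da", "dd")) {
    v <- switch(ty, aa = 1 / 4, ad = 1 / 4, da = 1 / 4, dd = 3 / 16)
    mm <- calibrate_effects(
      qtl_model(data.frame(type = ty, marker1 = "M1", marker2 = "M4",
                           h2 = 0.1), mu = 0, sigma2_e = 1), map2)
    expect_equal(mm$effects$effect, sqrt(0.1 * (1 / 0.9) / v), tolerance = 1e-12)
  }
  # zero heritability gives zero effect
  m0 <- calibrate_effects(
    qtl_model(data.frame(type = "a", marker1 = "M1", marker2 = NA, h2 = 0),
              mu = 0, sigma2_e = 1), map)
  expect_equal(m0$effects$effect, 0)
  # QTL must sit on a marker
  bad <- qtl_model(data.frame(type = "a", marker1 = "M99", marker2 = NA,
                              h2 = 0.1))
  expect_error(calibrate_effects(bad, map), "no marker")
})

test_that("calibrated QTL reproduce their nominal heritability in a large F1 population", {
  pre <- preset_experiment(1)
  set.seed(5)
  ids <- c(pre$design$maternal, pre$design$paternal)
  par <- simulate_parents(pre$map, length(ids), ids = ids)
  f1 <- deduce_f1(par, pre$full_design)
  eff <- pre$qtl$effects
  s2P <- pre$qtl$sigma2_P
  for (k in seq_len(nrow(eff))) {
    w <- as.numeric(f1$geno[, eff$marker1[k]]) - 1
    realized <- eff$effect[k]^2 * var(w)
    expect_equal(realized / s2P, eff$h2[k], tolerance = 0.1)
  }
})

test_that("phenotypes follow the generative model", {
  map <- tiny_map()
  par <- simulate_parents(map, 800, seed = 9)
  null <- calibrate_effects(
    qtl_model(data.frame(type = "a", marker1 = "M1", marker2 = NA, h2 = 0),
              mu = 50, sigma2_e = 4), map)
  y <- simulate_phenotypes(par, null, seed = 10)
  expect_equal(mean(y), 50, tolerance = 0.3)
  expect_equal(var(y), 4, tolerance = 0.6)
  # vanishing noise with a single additive QTL: three distinct values
  # (calibrate the effect at unit residual variance, then shrink the noise:
  # calibrated effects scale with the residual sd by construction)
  det <- calibrate_effects(
    qtl_model(data.frame(type = "a", marker1 = "M1", marker2 = NA, h2 = 0.2),
              mu = 0, sigma2_e = 1), map)
  det$sigma2_e <- 1e-16
  f1 <- deduce_f1(par, partial_ncii(400, 400, t = 1,
                                    maternal = rownames(par$geno)[1:400],
                                    paternal = rownames(par$geno)[401:800]))
  yd <- simulate_phenotypes(f1, det, seed = 11)
  expect_equal(length(unique(round(yd, 3))), 3)
  expect_equal(sort(unique(round(yd, 6))),
               round(c(-det$effects$effect, 0, det$effects$effect), 6))
})

test_that("experiment presets encode the published layouts", {
  p1 <- preset_experiment(1)
  expect_equal(nrow(p1$map), 60)
  expect_equal(unname(table(p1$map$chrom)), rep(20L, 3), ignore_attr = TRUE)
  expect_equal(nrow(p1$design$crosses), 240)
  expect_equal(p1$qtl$effects$type, rep("a", 6))
  expect_equal(p1$qtl$effects$h2, c(0.05, 0.05, 0.10, 0.10, 0.15, 0.15))
  # main-effect positions 25, 75, 135, 175, 220, 270 cM on the concatenated axis
  idx <- match(p1$qtl$effects$marker1, p1$map$marker)
  offs <- c(0, 95, 190)
  expect_equal(p1$map$pos[idx] + offs[p1$map$chrom[idx]],
               c(25, 75, 135, 175, 220, 270))
  p3 <- preset_experiment(3)
  expect_equal(p3$qtl$effects$type, rep("aa", 6))
  pd <- preset_experiment("over-dominance")
  expect_equal(unique(pd$qtl$effects$degree), 2)
  expect_equal(pd$qtl$effects$effect_d / pd$qtl$effects$effect, rep(2, 6))
  mp <- preset_experiment("mating-proportion", t = 1)
  expect_equal(nrow(mp$map), 21)
  expect_equal(max(mp$map$pos), 100)
  expect_equal(sort(mp$qtl$effects$type), sort(c("a", "d", "aa", "ad", "da", "dd")))
  expect_true(all(mp$qtl$effects$h2 == 0.05))
  expect_error(preset_experiment("nope"), "unknown preset")
})
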