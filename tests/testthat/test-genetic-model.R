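test_that("marker coding follows the F-infinity convention", {
  expect_equal(unname(encode_marker(2L)), cbind(1, 0), ignore_attr = TRUE)
  expect_equal(unname(encode_marker(1L)), cbind(0, 1), ignore_attr = TRUE)
  expect_equal(unname(encode_marker(0L)), cbind(-1, 0), ignore_attr = TRUE)
  expect_equal(encode_marker(c("QQ", "Qq", "qq"))[, "w"], c(1, 0, -1),
               ignore_attr = TRUE)
  expect_error(encode_marker("QX"), "unknown")
  expect_error(encode_marker(3), "dosage")
})

test_that("model dimensions match the published accounting", {
  # rapeseed: 205 markers, one environment
  expect_equal(count_effects(205, 1)$total, 84050)
  # cotton: 15 markers, two environments
  ce <- count_effects(15, 2)
  expect_equal(ce$main, 30)
  expect_equal(ce$epistatic, 420)
  expect_equal(ce$env, 1)
  expect_equal(ce$main_env, 30)
  expect_equal(ce$epistatic_env, 420)
  expect_equal(ce$total, 901)
  expect_equal(count_effects(1, 1)$total, 2)
  expect_error(count_effects(0), ">= 1")
})

test_that("the design matrix carries exactly the labelled effect columns", {
  map <- genome_map(1, 10, 2)
  geno <- matrix(c(2L, 1L, 0L, 1L, 2L, 0L, 0L, 2L), 4, 2,
                 dimnames = list(paste0("I", 1:4), map$marker))
  gt <- genotype_table(geno, map, role = "F1")
  des <- build_design(gt, rnorm(4))
  expect_equal(ncol(des$X), 8)   # 2m main + 4 pairs
  expect_setequal(des$labels$type, c("a", "d", "aa", "ad", "da", "dd"))
  w1 <- geno[, 1] - 1; v1 <- as.numeric(geno[, 1] == 1)
  w2 <- geno[, 2] - 1; v2 <- as.numeric(geno[, 2] == 1)
  expect_equal(unname(des$X[, "aa@M1:M2"]), unname(w1 * w2))
  expect_equal(unname(des$X[, "ad@M1:M2"]), unname(w1 * v2))
  expect_equal(unname(des$X[, "da@M1:M2"]), unname(v1 * w2))
  expect_equal(unname(des$X[, "dd@M1:M2"]), unname(v1 * v2))
  expect_equal(unname(des$X[, "a@M1"]), unname(w1))
  expect_equal(unname(des$X[, "d@M2"]), unname(v2))
})

test_that("epistatic columns are exact products of the main columns", {
  set.seed(31)
  map <- genome_map(1, 50, 6)
  par <- simulate_parents(map, 30)
  d <- partial_ncii(15, 15, t = 2, maternal = rownames(par$geno)[1:15],
                    paternal = rownames(par$geno)[16:30])
  f1 <- deduce_f1(par, d)
  des <- build_design(f1, rnorm(30))
  for (i in which(des$labels$type %in% c("aa", "ad", "da", "dd"))) {
    lab <- des$labels[i, ]
    left <- if (substr(lab$type, 1, 1) == "a") paste0("a@", lab$marker1)
            else paste0("d@", lab$marker1)
    right <- if (substr(lab$type, 2, 2) == "a") paste0("a@", lab$marker2)
             else paste0("d@", lab$marker2)
    expect_identical(des$X[, i], des$X[, left] * des$X[, right])
  }
})

test_that("inbred-parent designs flag every dominance-bearing column constant", {
  map <- genome_map(1, 40, 4)
  par <- simulate_parents(map, 40, seed = 13)
  des <- build_design(par, rnorm(40))
  dom <- des$labels$type %in% c("d", "ad", "da", "dd")
  expect_true(all(des$constant[dom]))
  expect_true(all(colSums(abs(des$X[, dom, drop = FALSE])) == 0))
  # so dominance and dd effects can never be retained from GCA-type designs
  fit <- eblasso(des)
  expect_false(any(test_effects(fit)$type %in% c("d", "ad", "da", "dd")))
})

test_that("two-environment designs add one covariate and one interaction block", {
  map <- genome_map(1, 30, 3)
  set.seed(17)
  par <- simulate_parents(map, 10)
  d <- partial_ncii(5, 5, t = 2, maternal = rownames(par$geno)[1:5],
                    paternal = rownames(par$geno)[6:10])
  f1 <- deduce_f1(par, d)
  # stack the same individuals over two environments
  g2 <- genotype_table(rbind(f1$geno, f1$geno), map, role = "F1")
  rownames(g2$geno) <- make.unique(rownames(g2$geno))
  env <- rep(c("E1", "E2"), each = 10)
  des <- build_design(g2, rnorm(20), env = env)
  base <- count_effects(3, 1)$total
  expect_equal(ncol(des$X), 2 * base)             # genetic + xE copies
  expect_equal(sum(des$labels$env_int), base)
  expect_true("E" %in% colnames(des$U))           # env main effect, unpenalized
  expect_equal(sort(unique(des$U[, "E"])), c(-1, 1))
  expect_error(build_design(g2, rnorm(20), env = rep("E1", 20)), "two environments")
  # Q covariates join the unpenalized block
  desq <- build_design(g2, rnorm(20), env = env, Q = matrix(runif(40), 20, 2))
  expect_equal(ncol(desq$U), 4)
})

test_that("missing genotypes are mean-imputed or dropped as configured", {
  map <- genome_map(1, 20, 2)
  geno <- matrix(c(2L, NA, 0L, 2L, 1L, 0L, NA, 2L), 4, 2,
                 dimnames = list(paste0("I", 1:4), map$marker))
  gt <- genotype_table(geno, map, role = "F1")
  des <- build_design(gt, rnorm(4), missing = "mean")
  expect_true(all(is.finite(des$X)))
  expect_equal(des$n, 4)
  des2 <- build_design(gt, rnorm(4), missing = "drop")
  expect_equal(des2$n, 2)
})

test_that("relabelling markers permutes columns but leaves the fit invariant", {
  sim <- sim_additive_pop(n = 80, markers = 5, h2 = 0.4, seed = 44)
  des <- build_design(sim$parents, sim$y)
  perm <- c(4, 2, 5, 1, 3)
  map_p <- sim$map
  geno_p <- sim$parents$geno[, perm]
  colnames(geno_p) <- map_p$marker   # same labels, markers physically permuted
  # fit original and fit with candidate columns permuted
  fit1 <- eblasso(des)
  Xp <- des$X[, sample(ncol(des$X))]
  fit2 <- eblasso(Xp, des$y)
  t1 <- test_effects(fit1); t2 <- test_effects(fit2)
  expect_setequal(t1$label, t2$label)
  expect_equal(t1$estimate[order(t1$label)], t2$estimate[order(t2$label)],
               tolerance = 1e-6)
})
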