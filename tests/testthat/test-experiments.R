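test_that("mid-parent heterosis ranking behaves under the generative identities", {
  r <- run_mph_ranking(replicates = 1, seed = 99)
  expect_s3_class(r, "mph_summary")
  expect_true(all(r$mean_abs_mph >= 0))
  expect_equal(unique(r$hybrids), 14400)
  v <- setNames(r$mean_abs_mph, r$model)
  # additive loci contribute nothing to heterosis: the F1 equals the
  # mid-parent at every locus, so |MPH| is pure noise and is the minimum
  expect_equal(unname(which.min(v)), unname(which(names(v) == "additive")))
  # pure dominance is the largest contributor
  expect_equal(names(v)[which.max(v)], "dominance")
  # dominance-degree models are ordered by their dominance effect
  expect_true(v["over-dom"] > v["complete-dom"])
  expect_true(v["complete-dom"] > v["partial-dom"])
})

test_that("doubling the baseline mean halves the heterosis percentage", {
  r1 <- run_mph_ranking(replicates = 1, seed = 7, mu = 100)
  r2 <- run_mph_ranking(replicates = 1, seed = 7, mu = 200)
  v1 <- setNames(r1$mean_abs_mph, r1$model)
  v2 <- setNames(r2$mean_abs_mph, r2$model)
  expect_equal(unname(v2[names(v1)] / v1), rep(0.5, 9), tolerance = 0.03)
})

test_that("power studies return a coherent report", {
  r <- run_power_study("mating-proportion", kind = "trait", replicates = 2,
                       seed = 5, t = 15)
  expect_s3_class(r, "power_report")
  expect_equal(nrow(r), 6)
  expect_true(all(r$power >= 0 & r$power <= 1))
  expect_true(all(r$power_relaxed >= r$power))
  expect_true(all(r$detections <= attr(r, "replicates")))
  expect_equal(attr(r, "kind"), "trait")
  expect_output(print(r), "Power report")
})

test_that("type I error of the true-term test is controlled under the null", {
  # phenotypes independent of genotypes: the six QTL terms are all null
  pre <- preset_experiment("mating-proportion", t = 2)
  eff <- pre$qtl$effects
  set.seed(42)
  hits <- 0L; total <- 0L
  for (rep in 1:25) {
    ids <- c(pre$design$maternal, pre$design$paternal)
    parents <- simulate_parents(pre$map, length(ids), ids = ids)
    f1 <- deduce_f1(parents, pre$design)
    pop <- genotype_table(rbind(parents$geno, f1$geno), pre$map,
                          role = c(parents$role, f1$role))
    y <- rnorm(nrow(pop$geno), 100, 1)    # no genetic signal at all
    fit <- eblasso(build_design(pop, y))
    tab <- test_effects(fit)
    for (q in seq_len(nrow(eff))) {
      hit <- nrow(tab[tab$type == eff$type[q] & tab$marker1 == eff$marker1[q] &
                        (is.na(eff$marker2[q]) | tab$marker2 %in% eff$marker2[q]) &
                        tab$significant, , drop = FALSE]) > 0
      hits <- hits + hit; total <- total + 1L
    }
  }
  # selection makes the per-term null rate conservative; allow binomial slack
  expect_lt(hits / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("the mating-proportion study reports the published F1 proportions", {
  r <- run_proportion_study(t_values = c(1, 15), replicates = 2, seed = 31)
  expect_s3_class(r, "proportion_report")
  expect_equal(sort(unique(round(r$f1_proportion, 1))), c(33.3, 88.2))
  expect_equal(nrow(r), 12)   # 2 designs x 6 effect types
  expect_true(all(r$power >= 0 & r$power <= 1))
  expect_true(all(is.finite(r$mean_abs_deviation)))
})
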