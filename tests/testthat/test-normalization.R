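test_that("fixed-slope refit matches the constrained least-squares oracle", {
  # exact line at the common exponent
  x <- seq(0, 4, length.out = 8)
  r <- refit_fixed_slope(x, 0.7248 * x + 0.5, 0.7248)
  expect_equal(r$intercept_log10, 0.5, tolerance = 1e-12)
  expect_equal(r$r2_at_common_b, 1, tolerance = 1e-12)
  expect_equal(r$a_common, 10^0.5)

  set.seed(301)
  for (rep in 1:8) {
    x <- runif(15, 0, 5)
    y <- 0.4 + 0.7 * x + rnorm(15, 0, 0.3)
    b0 <- runif(1, 0.5, 1)
    r <- refit_fixed_slope(x, y, b0)
    expect_lt(abs(r$intercept_log10 - fixed_slope_grid_oracle(x, y, b0)),
              1e-8)
    # consistency: at the group's own OLS slope the intercepts coincide
    f <- fit_ols(x, y)
    r2 <- refit_fixed_slope(x, y, f$b)
    expect_equal(r2$intercept_log10, f$intercept_log10, tolerance = 1e-10)
    expect_equal(r2$r2_at_common_b, f$r2, tolerance = 1e-10)
  }

  expect_error(refit_fixed_slope(1, 1, 0.7), "insufficient")
})

test_that("the ratio table is anchored at the reference and scale invariant", {
  fits <- data.frame(group = names(table3_a_common),
                     a_common = unname(table3_a_common))
  rt <- bmr_ratio_table(fits)
  expect_identical(rt$ratio[rt$group == "Passeriformes"], 1)
  # ratio order mirrors coefficient order
  expect_equal(order(rt$ratio), order(rt$a_common))
  # multiplying every coefficient by a constant changes nothing
  fits2 <- fits; fits2$a_common <- fits2$a_common * 37.2
  expect_equal(bmr_ratio_table(fits2)$ratio, rt$ratio, tolerance = 1e-12)
  # alternative reference
  rt2 <- bmr_ratio_table(fits, reference_group = "Eutheria")
  expect_identical(rt2$ratio[rt2$group == "Eutheria"], 1)
  expect_equal(rt2$ratio[rt2$group == "Monotremata"], 1.63 / 3.53,
               tolerance = 1e-12)

  expect_error(bmr_ratio_table(fits, reference_group = "Aves"),
               "Passeriformes")
})

test_that("ratios are invariant to the BMR measurement unit", {
  set.seed(311)
  sim <- generate_dataset(default_simulation_config(n_per_group = 20,
                                                    seed = 17))
  ratios_of <- function(tab) {
    cs <- common_slope(tab)
    refits <- lapply(split(tab, tab$group), function(sub) {
      tl <- log10_transform(sub)
      refit_fixed_slope(tl$x, tl$y, cs$slope, group = sub$group[1])
    })
    bmr_ratio_table(refits)$ratio
  }
  tab <- sim$species
  scaled <- tab
  scaled$bmr_mlO2_h <- tab$bmr_mlO2_h * 4.8  # e.g. a different gas unit
  expect_equal(ratios_of(scaled), ratios_of(tab), tolerance = 1e-10)
})

test_that("the coefficient decreases in the imposed exponent when mean mass is positive", {
  set.seed(321)
  x <- runif(30, 0.5, 5)  # mean(x) > 0
  y <- 0.5 + 0.7 * x + rnorm(30, 0, 0.2)
  bs <- seq(0.5, 1, by = 0.05)
  a <- vapply(bs, function(b) refit_fixed_slope(x, y, b)$a_common, numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("the pipeline recovers realized clade ratios and orders separated clades", {
  # single-realization identifiability: estimates track the clade intercepts
  # actually realized on the simulated tree (nominal + clade mean residual)
  sim <- generate_dataset(default_simulation_config(seed = 42))
  cs <- common_slope(sim$species)
  refits <- lapply(split(sim$species, sim$species$group), function(sub) {
    tl <- log10_transform(sub)
    refit_fixed_slope(tl$x, tl$y, cs$slope, group = sub$group[1])
  })
  rt <- bmr_ratio_table(refits)
  res <- sim$truth$residuals
  grp <- sim$species$group[match(names(res), sim$species$species)]
  shift <- tapply(res, grp, mean)
  g <- sim$truth$groups
  la <- setNames(g$log10_a, g$label)[rt$group] + shift[rt$group]
  realized <- 10^(la - la["Passeriformes"])
  expect_lt(max(abs(rt$ratio - unname(realized))), 0.05)

  # across replicates, clade pairs separated by more than twice the
  # clade-shift noise floor (0.14 log10 units) keep their generating order
  nrep <- 60
  gl <- sort(endotherm_groups())
  conc <- matrix(NA, nrep, 15)
  gap <- numeric(15)
  for (r in 1:nrep) {
    simr <- generate_dataset(default_simulation_config(seed = 5000 + r))
    csr <- common_slope(simr$species)
    refr <- lapply(split(simr$species, simr$species$group), function(sub) {
      tl <- log10_transform(sub)
      refit_fixed_slope(tl$x, tl$y, csr$slope, group = sub$group[1])
    })
    est <- setNames(bmr_ratio_table(refr)$ratio,
                    bmr_ratio_table(refr)$group)[gl]
    tru <- simr$truth$true_ratio[gl]
    k <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      k <- k + 1
      gap[k] <- abs(log10(tru[i] / tru[j]))
      conc[r, k] <- sign(est[i] - est[j]) == sign(tru[i] - tru[j])
    }
  }
  rates <- colMeans(conc)
  expect_true(all(rates[gap > 0.14] >= 0.95))
})
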