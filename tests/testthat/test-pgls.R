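test_that("Brownian covariance matches hand-worked path lengths", {
  # two tips, no shared path
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(vcv_from_tree(t2)), diag(2))

  # ((A:1,B:1):1,C:2): shared path of A,B is the unit stem
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- vcv_from_tree(t3)
  expect_equal(diag(C), c(A = 2, B = 2, C = 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["B", "C"], 0)

  # star-like tree (zero-length internal edges): identity times depth
  st <- ape::read.tree(text = "((A:3,B:3):0,(C:3,D:3):0);")
  expect_equal(unname(vcv_from_tree(st)), 3 * diag(4))

  # an unrooted tree is refused with rooting advice
  un <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_false(ape::is.rooted(un))
  expect_error(vcv_from_tree(un), "root")
})

test_that("lambda transform scales only the off-diagonal", {
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- vcv_from_tree(t3)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(unname(lambda_transform(C, 0)), diag(diag(C)))
  half <- lambda_transform(C, 0.5)
  expect_equal(half["A", "B"], 0.5)
  expect_equal(diag(half), diag(C))
  expect_error(lambda_transform(C, 1.5), "\\[0, 1\\]")
  expect_error(lambda_transform(C, -0.1), "\\[0, 1\\]")
})

test_that("GLS equals OLS under identity covariance and the whitening oracle otherwise", {
  set.seed(101)
  x <- runif(20, 0, 4)
  y <- 1 + 0.7 * x + rnorm(20, 0, 0.3)
  g <- gls_fit(x, y, diag(20))
  f <- fit_ols(x, y)
  expect_equal(g$slope, f$b, tolerance = 1e-10)
  expect_equal(g$intercept, f$intercept_log10, tolerance = 1e-10)
  expect_equal(g$se_slope, f$se_b, tolerance = 1e-10)
  expect_equal(g$r2, f$r2, tolerance = 1e-10)

  for (rep in 1:10) {
    tr <- simulate_yule_tree(15)
    C <- lambda_transform(vcv_from_tree(tr), runif(1))
    x <- runif(15, 0, 4)
    y <- 0.5 + 0.8 * x + rnorm(15, 0, 0.3)
    g <- gls_fit(x, y, C)
    o <- gls_whitening_oracle(x, y, C)
    expect_equal(g$intercept, unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(g$slope, unname(o["slope"]), tolerance = 1e-10)
  }

  # exact line is interpolated whatever the covariance
  tr <- simulate_yule_tree(12, seed = 5)
  C <- vcv_from_tree(tr)
  x <- runif(12, 0, 4)
  g <- gls_fit(x, 2 * x + 1, C)
  expect_equal(g$slope, 2, tolerance = 1e-8)
  expect_equal(g$intercept, 1, tolerance = 1e-8)
  expect_equal(g$rss_whitened, 0, tolerance = 1e-12)
})

test_that("GLS is invariant to consistent tip permutations", {
  set.seed(111)
  tr <- simulate_yule_tree(18)
  C <- vcv_from_tree(tr)
  x <- runif(18, 0, 4)
  y <- 0.3 + 0.7 * x + simulate_bm_lambda(tr, 0.04, 0.8)
  g1 <- gls_fit(x, unname(y), C)
  p <- sample(18)
  g2 <- gls_fit(x[p], unname(y)[p], C[p, p])
  expect_equal(g2$slope, g1$slope, tolerance = 1e-10)
  expect_equal(g2$intercept, g1$intercept, tolerance = 1e-10)
  expect_equal(g2$loglik, g1$loglik, tolerance = 1e-8)
})

test_that("the lambda profile maximizes the likelihood and matches nlme's corPagel", {
  skip_if_not_installed("nlme")
  set.seed(121)
  tr <- simulate_yule_tree(40)
  x <- runif(40, 0, 4)
  y <- unname(1 + 0.7 * x + simulate_bm_lambda(tr, 0.04, 0.7))
  C <- vcv_from_tree(tr)
  prof <- profile_lambda_ml(x, y, C)
  # argmax property: no grid point beats the returned lambda
  expect_true(all(prof$loglik >= prof$profile$loglik))

  d <- data.frame(x = x, y = y, sp = tr$tip.label)
  for (lam in c(0.3, 1)) {
    mine <- gls_fit(x, y, lambda_transform(C, lam))
    ref <- nlme::gls(y ~ x, data = d, method = "ML",
                     correlation = ape::corPagel(lam, phy = tr, form = ~sp,
                                                 fixed = TRUE))
    expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
    expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-8)
    expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
    expect_equal(mine$se_slope, sqrt(diag(vcov(ref)))[[2]], tolerance = 1e-6)
  }
  free <- nlme::gls(y ~ x, data = d, method = "ML",
                    correlation = ape::corPagel(0.5, phy = tr, form = ~sp))
  lam_nlme <- coef(free$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(prof$lambda, unname(lam_nlme), tolerance = 1e-3)
})

test_that("maximum-likelihood lambda recovers boundary truths in simulation", {
  recover_mean <- function(lambda_true, seed0) {
    lh <- vapply(1:60, function(r) {
      set.seed(seed0 + r)
      tr <- simulate_yule_tree(80)
      x <- runif(80, 0, 4)
      y <- unname(1 + 0.7 * x + simulate_bm_lambda(tr, 0.01, lambda_true))
      profile_lambda_ml(x, y, vcv_from_tree(tr))$lambda
    }, numeric(1))
    mean(lh)
  }
  expect_lt(recover_mean(0, 100), 0.05)
  expect_gt(recover_mean(1, 200), 0.95)
})

test_that("PGLS allometry reduces to OLS at lambda zero and covers the true exponent", {
  # lambda = 0 on an ultrametric tree leaves a scaled identity: OLS exactly
  tr <- simulate_yule_tree(25, seed = 9)
  set.seed(131)
  x <- runif(25, 0, 4)
  y <- 0.4 + 0.72 * x + rnorm(25, 0, 0.1)
  g0 <- gls_fit(x, y, lambda_transform(vcv_from_tree(tr), 0))
  f <- fit_ols(x, y)
  expect_equal(g0$slope, f$b, tolerance = 1e-10)
  expect_equal(g0$intercept, f$intercept_log10, tolerance = 1e-10)

  # refusal below 4 matched species
  small <- make_species(c(3.1, 3.5, 4.0), c(3.0, 3.3, 3.6),
                        group = "Monotremata")
  tr3 <- ape::read.tree(text = "((spMonotremata1:1,spMonotremata2:1):1,spMonotremata3:2);")
  expect_error(pgls_allometry(small, tr3), "insufficient")

  # coverage: b-hat within 3 SE of the generating exponent nearly always
  hits <- vapply(1:60, function(r) {
    set.seed(300 + r)
    tr <- simulate_yule_tree(100)
    x <- runif(100, 0, 4)
    y <- unname(1 + 0.72 * x + simulate_bm_lambda(tr, 0.01, 0.7))
    tab <- make_species(x, y, group = "Sim")
    tab$species <- tr$tip.label
    fit <- pgls_allometry(tab, tr)
    abs(fit$b - 0.72) <= 3 * fit$se_b
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("species-tree matching prunes both sides and reports drops", {
  tr <- ape::read.tree(text = "((A_x:1,B_x:1):1,(C_x:1,D_x:1):1);")
  tab <- make_species(1:4, 1:4)
  tab$species <- c("A x", "B x", "C x", "E x")  # spaces match underscores

  pm <- prune_and_match(tab, tr)
  expect_equal(ape::Ntip(pm$tree), 3L)
  expect_equal(pm$dropped_species, "E x")
  expect_equal(pm$dropped_tips, "D_x")
  expect_equal(gsub("_", " ", pm$tree$tip.label), pm$records$species)

  # identical sets: nothing dropped
  tab2 <- tab[1:4, ]; tab2$species <- c("A_x", "B_x", "C_x", "D_x")
  pm2 <- prune_and_match(tab2, tr)
  expect_length(pm2$dropped_species, 0)
  expect_length(pm2$dropped_tips, 0)

  # random subsets: matched count is the intersection size
  set.seed(141)
  big <- simulate_yule_tree(30)
  for (rep in 1:5) {
    keep <- sample(30, sample(5:25, 1))
    tabr <- make_species(seq_along(keep), seq_along(keep))
    tabr$species <- big$tip.label[keep]
    pmr <- prune_and_match(tabr, big)
    expect_equal(nrow(pmr$records), length(keep))
  }

  tab3 <- tab; tab3$species <- paste0("Z", 1:4)
  expect_error(prune_and_match(tab3, tr), "no species in common")
})

test_that("stronger phylogenetic signal widens the OLS-PGLS intercept gap", {
  gap <- function(lambda_true, seed0) {
    mean(vapply(1:20, function(r) {
      set.seed(seed0 + r)
      tr <- simulate_yule_tree(80)
      x <- runif(80, 0, 4)
      y <- unname(0.5 + 0.72 * x + simulate_bm_lambda(tr, 0.09, lambda_true))
      tab <- make_species(x, y, group = "Sim")
      tab$species <- tr$tip.label
      abs(fit_ols(x, y)$a - pgls_allometry(tab, tr)$a)
    }, numeric(1)))
  }
  expect_gt(gap(0.9, 7000), gap(0.1, 7000))
})
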