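test_that("adjacency is the soft-thresholded |correlation| with zero diagonal", {
  x <- rand_expr(6, 12, seed = 4)
  A <- adjacency(x, beta = 6)
  C <- abs(cor(t(x)))
  expect_equal(unname(A), unname(C^6 - diag(diag(C^6))))
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0 & A <= 1))
  expect_error(adjacency(x, beta = 0.5), ">= 1")
  # beta = 1 on a duplicated gene gives adjacency 1
  y <- rbind(x, dup = x[1, ])
  expect_equal(adjacency(y, beta = 1)["dup", rownames(x)[1]], 1)
})

test_that("scale_free_fit scores power laws high and flat/rising degrees low", {
  set.seed(10)
  # discrete power law p(k) ~ k^-2 on bounded support (keeps every
  # equal-width bin populated at n = 1000)
  kk <- 1:100
  pk <- kk^-2 / sum(kk^-2)
  k_pl <- sample(kk, 1000, replace = TRUE, prob = pk)
  r2_pl <- scale_free_fit(k_pl)
  expect_gte(r2_pl, 0.9)
  # binomial (Erdos-Renyi-like) degrees fit much worse
  k_er <- rbinom(1000, 100, 0.2)
  r2_er <- scale_free_fit(k_er)
  expect_lt(r2_er, r2_pl - 0.2)
  # rising frequency over two distinct values: positive slope, negative index
  expect_lt(scale_free_fit(c(rep(1, 20), rep(10, 80))), 0)
  expect_warning(r0 <- scale_free_fit(rep(3, 20)), "equal")
  expect_equal(r0, 0)
  expect_error(scale_free_fit(1:5), ">= 10")
})

test_that("pick_power selects the smallest adequate power", {
  scan <- data.frame(power = 1:10,
                     r2 = c(0.2, 0.4, 0.5, 0.7, 0.85, 0.92, 0.95, 0.93, 0.96, 0.97),
                     mean_k = 10 / (1:10))
  expect_equal(pick_power(scan, target_r2 = 0.90), 6)
  expect_equal(pick_power(scan, target_r2 = 0.1), 1)
  expect_warning(b <- pick_power(scan, target_r2 = 0.99), "falling back")
  expect_equal(b, 10)
  # monotone: raising the target never lowers the chosen power
  targets <- seq(0.1, 0.99, by = 0.05)
  betas <- vapply(targets, function(t)
    suppressWarnings(pick_power(scan, target_r2 = t)), numeric(1))
  expect_true(all(diff(betas) >= 0))
})

test_that("tom matches the brute-force triple loop", {
  # complete graph with unit adjacency: all overlaps are 1
  a1 <- matrix(1, 3, 3); diag(a1) <- 0
  expect_equal(unname(tom(a1)), matrix(1, 3, 3))
  # empty adjacency: zero off-diagonal
  a0 <- matrix(0, 4, 4)
  expect_equal(unname(tom(a0)), diag(4))
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(letters[1:6], letters[1:6])
    expect_equal(tom(a), oracle_tom(a), tolerance = 1e-12)
  }
  expect_error(tom(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("cluster_modules recovers planted blocks and ignores noise", {
  set.seed(20)
  n_samp <- 60
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  x <- rbind(
    t(sapply(1:15, function(i) 3 * f1 + rnorm(n_samp))),
    t(sapply(1:15, function(i) 3 * f2 + rnorm(n_samp))),
    t(sapply(1:20, function(i) rnorm(n_samp))))
  rownames(x) <- sprintf("g%02d", 1:50)
  colnames(x) <- sprintf("s%02d", 1:n_samp)
  cm <- cluster_modules(tom(adjacency(x, beta = 6)), min_module_size = 5)
  lab <- cm$labels
  # the two planted blocks land in two distinct modules
  expect_equal(length(unique(lab[1:15])), 1)
  expect_equal(length(unique(lab[16:30])), 1)
  expect_false(lab[1] == lab[16])
  expect_false(any(c(lab[1], lab[16]) == "grey"))
  # noise genes stay overwhelmingly unassigned
  expect_gt(mean(lab[31:50] == "grey"), 0.7)
  # single perfectly correlated block: one module holding it
  x1 <- rbind(t(sapply(1:8, function(i) 2 * f1 + 0.01 * rnorm(n_samp))),
              t(sapply(1:10, function(i) rnorm(n_samp))))
  rownames(x1) <- sprintf("h%02d", 1:18); colnames(x1) <- colnames(x)
  cm1 <- cluster_modules(tom(adjacency(x1, beta = 6)), min_module_size = 5)
  expect_true(all(sprintf("h%02d", 1:8) %in% cm1$modules[[1]]))
  expect_error(cluster_modules(diag(5), min_module_size = 2), ">= 3")
})

test_that("module eigengene is the oriented unit-variance first PC", {
  set.seed(30)
  n_samp <- 40
  f <- rnorm(n_samp)
  x <- rbind(t(sapply(1:6, function(i) 5 * f + 0.3 * rnorm(n_samp))),
             t(sapply(1:4, function(i) rnorm(n_samp))))
  rownames(x) <- sprintf("g%02d", 1:10); colnames(x) <- sprintf("s%02d", 1:n_samp)
  e <- module_eigengene(x, sprintf("g%02d", 1:6))
  expect_equal(sd(e), 1)
  expect_gte(abs(cor(e, f)), 0.95)
  expect_gt(mean(cor(e, t(x[1:6, ]))), 0)         # orientation rule
  # identical genes: eigengene reproduces the common profile
  xx <- rbind(a = f, b = f, c = f); colnames(xx) <- colnames(x)
  expect_equal(abs(cor(module_eigengene(xx, c("a", "b", "c")), f)), 1)
  # flipping the sign of every gene leaves the oriented eigengene usable:
  # it simply tracks the flipped profiles
  e_flip <- module_eigengene(-x, sprintf("g%02d", 1:6))
  expect_equal(abs(cor(e_flip, e)), 1)
  expect_error(module_eigengene(x, c("g01", "g02")), ">= 3")
  x0 <- x; x0["g01", ] <- 5
  expect_error(module_eigengene(x0, sprintf("g%02d", 1:6)), "zero-variance")
})

test_that("eigengene explains at least as much as any member profile (PC1 optimality)", {
  set.seed(31)
  x <- rand_expr(8, 25, seed = 31)
  genes <- rownames(x)
  e <- module_eigengene(x, genes)
  xs <- t(scale(t(x)))
  expl_e <- sum(cor(e, t(xs))^2)
  for (g in genes) {
    expect_gte(expl_e + 1e-9, sum(cor(xs[g, ], t(xs))^2))
  }
})

test_that("module_trait_cor ranks modules by eigengene-trait correlation", {
  set.seed(40)
  n_samp <- 50
  trait <- rep(1:5, each = 10) + 0
  names(trait) <- sprintf("s%02d", 1:n_samp)
  z <- scale(trait)[, 1]
  x <- rbind(t(sapply(1:6, function(i) 2 * z + 0.5 * rnorm(n_samp))),
             t(sapply(1:6, function(i) rnorm(n_samp))))
  rownames(x) <- sprintf("g%02d", 1:12); colnames(x) <- names(trait)
  mods <- list(planted = sprintf("g%02d", 1:6), noise = sprintf("g%02d", 7:12))
  mtc <- module_trait_cor(x, mods, trait)
  expect_identical(mtc$module[1], "planted")
  expect_gt(abs(mtc$cor[1]), 0.9)
  expect_lt(mtc$p[1], 1e-10)
  # an eigengene equal to the trait correlates perfectly
  xt <- rbind(a = trait, b = trait, c = trait) + 0
  colnames(xt) <- names(trait)
  mtc2 <- module_trait_cor(xt, list(m = c("a", "b", "c")), trait)
  expect_equal(abs(mtc2$cor), 1)
  expect_error(module_trait_cor(x, mods, setNames(rep(1, n_samp), names(trait))),
               "constant")
})
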