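test_that("pcc matches the direct sum formula and its conventions", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  expect_equal(pcc(x, y), 11 / sqrt(130))          # hand evaluation
  expect_equal(pcc(x, y), oracle_pcc(x, y))
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_error(pcc(x, y[1:3]), "equal length")
  expect_error(pcc(1:2, 1:2), "at least 3")
  expect_warning(r <- pcc(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_equal(r, 0)
})

test_that("sd_in is the mean absolute deviation from reference means", {
  expr <- rbind(gA = c(5, 5, 5, 7),
                gB = c(2, 4, 3, 3))
  colnames(expr) <- c("r1", "r2", "r3", "c1")
  design <- make_design_unchecked(c("r1", "r2", "r3"), list(I = "c1"))
  # single gene, single case: |7 - 5| = 2
  expect_equal(sd_in(expr, design, "gA", "I"), 2)
  # gene constant at its reference mean contributes 0
  expect_equal(sd_in(expr, design, "gB", "I"), 0)
  expect_error(sd_in(expr, design, "nope", "I"), "nope")

  # 2 genes x 3 case samples, against exhaustive enumeration
  x <- rand_expr(2, 6, seed = 7)
  d2 <- make_design(c("s01", "s02", "s03"), list(I = c("s04", "s05", "s06")))
  expect_equal(sd_in(x, d2, rownames(x), "I"),
               oracle_sd_in(x, c("s01", "s02", "s03"),
                            c("s04", "s05", "s06"), rownames(x)))
})

test_that("sd_in optionally normalizes by the reference standard deviation", {
  x <- rand_expr(3, 10, seed = 8)
  d <- make_design(sprintf("s%02d", 1:6), list(I = sprintf("s%02d", 7:10)))
  refs <- sprintf("s%02d", 1:6)
  manual <- mean(abs(x[, 7:10] - rowMeans(x[, refs])) /
                   apply(x[, refs], 1, sd))
  expect_equal(sd_in(x, d, rownames(x), "I", normalize = TRUE), manual)
})

test_that("pcc_in and pcc_out equal pairwise enumeration", {
  x <- rand_expr(6, 9, seed = 11)
  d <- make_design(c("s01", "s02", "s03"),
                   list(I = sprintf("s%02d", 4:9)))
  cases <- sprintf("s%02d", 4:9)
  mod <- c("g01", "g02", "g03")
  bg <- c("g04", "g05")
  expect_equal(pcc_in(x, d, mod, "I"), oracle_pcc_in(x, cases, mod))
  expect_equal(pcc_out(x, d, mod, "I", background = bg),
               oracle_pcc_out(x, cases, mod, bg))
  # default background is every non-module gene
  expect_equal(pcc_out(x, d, mod, "I"),
               oracle_pcc_out(x, cases, mod, c("g04", "g05", "g06")))
  expect_error(pcc_in(x, d, "g01", "I"), ">= 2 genes")
  expect_error(pcc_out(x, d, mod, "I", background = c("g03", "g04")),
               "overlap")
  # two identical genes correlate perfectly
  y <- rbind(x, g07 = x["g01", ])
  expect_equal(pcc_in(y, d, c("g01", "g07"), "I"), 1)
  expect_equal(pcc_out(y, d, "g07", "I", background = "g01"), 1)
})

test_that("pcc_in of independent genes matches the independence baseline", {
  n_cases <- 12
  baseline <- local({
    set.seed(123)
    mean(replicate(400, abs(cor(rnorm(n_cases), rnorm(n_cases)))))
  })
  vals <- vapply(1:50, function(s) {
    x <- rand_expr(5, n_cases + 3, seed = 1000 + s)
    d <- make_design(sprintf("s%02d", 1:3),
                     list(I = sprintf("s%02d", 4:(n_cases + 3))))
    pcc_in(x, d, rownames(x), "I")
  }, numeric(1))
  expect_lt(abs(mean(vals) - baseline), 0.03)
})

test_that("composite_index follows CI = SD_in * PCC_in / PCC_out", {
  expect_equal(composite_index(2, 0.5, 0.25), 4)
  expect_equal(composite_index(0, 0.9, 0.3), 0)
  expect_warning(v <- composite_index(1, 0.9, 0), "floor")
  expect_equal(v, 0.9 / 1e-6)
  expect_error(composite_index(-1, 0.5, 0.5), "nonnegative")
  expect_error(composite_index(Inf, 0.5, 0.5), "finite")
  # homogeneity: degree 1 in sd_in and pcc_in, inverse in pcc_out
  base <- composite_index(1.3, 0.4, 0.2)
  for (a in c(0.5, 2, 7)) {
    expect_equal(composite_index(1.3 * a, 0.4, 0.2), a * base)
    expect_equal(composite_index(1.3, 0.4 * a / 10, 0.2), a / 10 * base)
    expect_equal(composite_index(1.3, 0.4, 0.2 * a), base / a)
  }
})

test_that("score_module produces one consistent row per stage", {
  x <- rand_expr(8, 12, seed = 21)
  d <- make_design(sprintf("s%02d", 1:4),
                   list(I = sprintf("s%02d", 5:8), II = sprintf("s%02d", 9:12)))
  sc <- score_module(x, d, c("g01", "g02", "g03"))
  expect_identical(sc$stage, c("I", "II"))
  expect_equal(sc$ci, sc$sd_in * sc$pcc_in / sc$pcc_out)
  expect_equal(sc$sd_in[1], sd_in(x, d, c("g01", "g02", "g03"), "I"))
  # degenerate single-stage design still yields one score
  d1 <- make_design(sprintf("s%02d", 1:4), list(I = sprintf("s%02d", 5:12)))
  expect_equal(nrow(score_module(x, d1, c("g01", "g02"))), 1)
})

test_that("detect_critical_stage finds where the sharp rise begins", {
  # printed four-stage trajectory: rise begins at stage III, peak at IV
  traj <- c(I = 0.42378583, II = 0.14771798, III = 0.09225563, IV = 0.647891324)
  crit <- detect_critical_stage(traj)
  expect_equal(as.integer(crit), 3)
  expect_identical(names(crit), "III")
  expect_false(attr(crit, "no_transition"))
  expect_equal(which.max(traj), c(IV = 4L))
  # single jump
  expect_equal(as.integer(detect_critical_stage(c(0, 0, 0, 1))), 3)
  # strictly decreasing: least-negative difference, flagged
  crit2 <- detect_critical_stage(c(5, 3, 2.5, 1))
  expect_equal(as.integer(crit2), 2)
  expect_true(attr(crit2, "no_transition"))
  # ties break to the earliest stage
  expect_equal(as.integer(detect_critical_stage(c(0, 1, 2, 3))), 1)
  expect_error(detect_critical_stage(1), ">= 2 stages")
})

test_that("candidate_modules respects size bounds and the pre-filter", {
  x <- rand_expr(3, 9, seed = 31)
  d <- make_design(c("s01", "s02", "s03"), list(I = sprintf("s%02d", 4:9)))
  cands <- candidate_modules(x, d, "I", min_size = 2, max_size = 2, top_k = 3)
  expect_lte(length(cands), 3)
  expect_true(all(lengths(cands) == 2))
  expect_error(candidate_modules(x, d, "I", min_size = 5, top_k = 3),
               "top_k")
  # larger example: all candidates are within the top-k deviation universe
  x2 <- rand_expr(40, 15, seed = 32)
  d2 <- make_design(sprintf("s%02d", 1:5), list(I = sprintf("s%02d", 6:15)))
  cands2 <- candidate_modules(x2, d2, "I", min_size = 3, max_size = 10,
                              top_k = 20)
  refs <- sprintf("s%02d", 1:5)
  devs <- rowMeans(abs(x2[, 6:15] - rowMeans(x2[, refs])))
  top20 <- names(sort(devs, decreasing = TRUE))[1:20]
  expect_true(all(unlist(cands2) %in% top20))
})

test_that("dnb fit is deterministic and recovers a strongly planted module", {
  sim <- simulate_dnb_data(dnb_spec(n_genes = 120, module_size = 12,
                                    n_de = 10, trait_module_size = 6,
                                    seed = 77))
  f1 <- dnb(sim$expr, sim$design, top_k = 120)
  f2 <- dnb(sim$expr, sim$design, top_k = 120)
  expect_identical(f1$module, f2$module)
  expect_identical(f1$scores, f2$scores)
  expect_gte(jaccard(f1$module, sim$truth$dnb_genes), 0.7)
  expect_equal(f1$critical_stage, sim$truth$tipping_stage)
  expect_identical(f1$peak_label, "IV")
  expect_s3_class(f1, "dnb")
  expect_equal(unname(coef(f1)), f1$scores$ci)
  expect_output(print(f1), "critical transition stage: III")
  expect_output(print(summary(f1)), "Per-stage scores")
})

test_that("on null data the fitted maximum CI is not above the permutation null", {
  sim <- simulate_dnb_data(dnb_spec(n_genes = 100, module_size = 10,
                                    n_de = 0, trait_module_size = 3,
                                    gamma = 0, lambda = rep(0, 4), seed = 13))
  fit <- dnb(sim$expr, sim$design, top_k = 100)
  obs <- max(fit$scores$ci)
  null_max <- vapply(1:19, function(b) {
    d <- sim$design
    case_rows <- d$group == "case"
    set.seed(500 + b)
    d$stage[case_rows] <- sample(d$stage[case_rows])
    max(dnb(sim$expr, d, top_k = 100)$scores$ci)
  }, numeric(1))
  # observed score behaves like one more draw from the permutation null
  expect_lte(obs, max(null_max) * 1.1)
})
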