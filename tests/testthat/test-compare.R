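test_that("mock subtraction floors at zero and handles missing groups", {
  trt <- tibble::tibble(group = c("gA", "gB"), n_TR = c(10, 2),
                        n_FL = c(50, 40))
  ctl <- tibble::tibble(group = c("gA", "gB", "gC"), n_TR = c(3, 5, 7),
                        n_FL = c(10, 0, 2))
  expect_message(adj <- mock_subtract(trt, ctl), "gC")
  expect_equal(adj$n_TR[adj$group == "gA"], 7)
  expect_equal(adj$n_TR[adj$group == "gB"], 0) # floored
  expect_equal(adj$n_TR[adj$group == "gC"], 0) # absent from treatment
  # zero control is the identity
  zero <- ctl; zero$n_TR <- 0; zero$n_FL <- 0
  ident <- mock_subtract(trt, zero[1:2, ])
  expect_equal(ident$n_TR, trt$n_TR)
  expect_equal(ident$n_FL, trt$n_FL)
})

test_that("mock subtraction is monotone and bounded by the treatment", {
  withr::local_seed(11)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    trt <- tibble::tibble(group = paste0("g", 1:n),
                          v = runif(n, 0, 20))
    ctl <- tibble::tibble(group = paste0("g", 1:n),
                          v = runif(n, 0, 20))
    adj <- mock_subtract(trt, ctl, cols = "v")
    expect_true(all(adj$v <= trt$v[match(adj$group, trt$group)] + 1e-12))
    expect_true(all(adj$v >= 0))
    # increasing one treatment entry never decreases its adjusted value
    j <- sample(n, 1)
    trt2 <- trt; trt2$v[j] <- trt2$v[j] + 5
    adj2 <- mock_subtract(trt2, ctl, cols = "v")
    expect_gte(adj2$v[adj2$group == trt$group[j]],
               adj$v[adj$group == trt$group[j]])
  }
})

test_that("TR/FL ratio is undefined without FL signal", {
  comp <- tibble::tibble(group = c("a", "b", "c"),
                         n_TR = c(5, 0, 4), n_FL = c(50, 30, 0))
  expect_message(r <- tr_vs_fl_ratio(comp), "c")
  expect_equal(r, c(0.1, 0, NA))
})

test_that("replicates pool at the count level, not as mean of ratios", {
  rep1 <- tibble::tibble(library = "r1", group = "g", tr = c(0L, 1L),
                         ta = c(0L, 0L), tail_seq = c("", ""),
                         category = c("FL", "TR_ONLY"), count = c(10, 1))
  rep2 <- rep1; rep2$library <- "r2"; rep2$count <- c(60, 30)
  pooled <- pool_replicates(list(rep1, rep2))
  expect_equal(sum(pooled$count), 101)
  comp <- compose(pooled, library_total = sum(pooled$count))
  ratio <- tr_vs_fl_ratio(comp)
  expect_equal(ratio, 31 / 70)
  # mean-of-ratios would give (1/10 + 30/60) / 2 = 0.3: a different number
  expect_false(isTRUE(all.equal(ratio, 0.3)))
  # single replicate is the identity on counts
  solo <- pool_replicates(list(rep1))
  expect_equal(sum(solo$count), sum(rep1$count))
})

test_that("Welch test matches the closed-form t statistic", {
  a <- c(0.4, 0.5); b <- c(0.1, 0.2)
  res <- two_group_test(a, b)
  # closed form: t = (mA - mB) / sqrt(sA^2/nA + sB^2/nB), Welch df
  sA2 <- var(a); sB2 <- var(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(sA2 / 2 + sB2 / 2)
  df <- (sA2 / 2 + sB2 / 2)^2 /
    ((sA2 / 2)^2 / 1 + (sB2 / 2)^2 / 1)
  p_expected <- 2 * pt(-abs(t_stat), df)
  expect_equal(t_stat, 4.2426, tolerance = 1e-4)
  expect_equal(df, 2)
  expect_equal(res$p_value, p_expected, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0513, tolerance = 1e-3)
  expect_equal(res$stars, "")
  expect_equal(res$direction, -1)
  expect_equal(res$mean_A, 0.45)
  expect_equal(res$sd_A, sd(a))
})

test_that("two-group test degenerate and edge contracts", {
  expect_equal(two_group_test(c(0.3, 0.4), c(0.3, 0.4))$p_value, 1)
  expect_equal(two_group_test(c(0.5), c(0.1, 0.2))$p_value, NA_real_)
  expect_equal(two_group_test(c(0.5), c(0.1, 0.2))$stars, "")
  # constant but different groups: infinitely strong evidence
  res0 <- two_group_test(c(0.2, 0.2), c(0.5, 0.5))
  expect_equal(res0$p_value, 0)
  expect_equal(res0$stars, "***")
  # symmetry up to direction
  a <- c(0.31, 0.35, 0.29); b <- c(0.12, 0.18, 0.15)
  r1 <- two_group_test(a, b)
  r2 <- two_group_test(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$direction, -r2$direction)
  # star thresholds
  expect_equal(isotrim:::star_for_p(c(0.2, 0.04, 0.009, 5e-4, NA)),
               c("", "*", "**", "***", ""))
})

test_that("summed truncation signal can be significant when parts are not", {
  # per-replicate components noisy, sum cleanly separated
  a <- tibble::tibble(p_TR = c(0.16, 0.12, 0.14), p_TRTA = c(0.14, 0.20, 0.17))
  b <- tibble::tibble(p_TR = c(0.08, 0.04, 0.06), p_TRTA = c(0.03, 0.07, 0.05))
  res <- sum_truncation_test(a, b, group_name = "g")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, -1)
  # the summed metric equals the per-replicate truncation ratio
  expect_equal(a$p_TR + a$p_TRTA, c(0.30, 0.32, 0.31))
  same <- sum_truncation_test(a, a)
  expect_equal(same$p_value, 1)
})

test_that("library distances follow log2(RPM + 1) Euclidean geometry", {
  # libraries with log2 profiles (0,0) and (3,4) sit at distance 5
  m <- cbind(L1 = c(0, 0), L2 = c(7, 15))
  rownames(m) <- c("gA", "gB")
  cl <- cluster_libraries(m)
  expect_equal(cl$dist["L1", "L2"], 5)
  # a duplicated library sits at distance 0 from its copy
  m3 <- cbind(m, L3 = m[, "L2"])
  cl3 <- cluster_libraries(m3)
  expect_equal(cl3$dist["L2", "L3"], 0)
  expect_match(cl3$newick, "L1")
  expect_error(cluster_libraries(m[, 1, drop = FALSE]), "at least 2")
})

test_that("replicate libraries cluster together before crossing profiles", {
  rs <- synthetic_refset(6, seed = 42)
  presets <- preset_profiles(library_size = 4000)
  libs <- list()
  for (p in c("wildtype_like", "hen1_like", "hen1_heso1_like")) {
    for (r in 1:2) {
      id <- paste0(p, "_r", r)
      syn <- generate_library(presets[[p]], rs,
                              seed = isotrim:::derive_seed(7, p, r),
                              library_id = id)
      libs[[id]] <- classify_library(syn$reads, rs, library_id = id)
    }
  }
  cl <- cluster_libraries(species_rpm_table(libs))
  coph <- as.matrix(stats::cophenetic(cl$hclust))
  for (p in c("wildtype_like", "hen1_like", "hen1_heso1_like")) {
    ids <- paste0(p, "_r", 1:2)
    within <- coph[ids[1], ids[2]]
    cross <- min(coph[ids, setdiff(colnames(coph), ids)])
    expect_lt(within, cross)
  }
})
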