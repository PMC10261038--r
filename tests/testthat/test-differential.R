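test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(61)
  for (i in 1:200) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_fdr(p), bh_brute_force(p), tolerance = 1e-14)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("lowering a single p-value never raises any q-value", {
  set.seed(67)
  for (i in 1:30) {
    p <- runif(6)
    q <- bh_fdr(p)
    j <- sample(6, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    q2 <- bh_fdr(p2)
    expect_true(all(q2 <= q + 1e-14))
  }
  # q >= p always
  set.seed(68)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("per-peak tests match the shared t oracle and rank true shifts first", {
  # identical groups: all p = 1
  v <- matrix(rep(c(1, 2, 3), 8), nrow = 3, byrow = FALSE)
  m <- tiny_matrix(rbind(v[, 1:8] * 0 + c(1, 2, 3), rep(1, 8)), n_is = 1,
                   log2 = TRUE)
  p <- per_peak_tests(m, "F1", "parent1")
  expect_true(all(p$p == 1))

  # the worked numeric example: means 11 vs 8, sd 1, n 3 -> p ~ 0.021
  v2 <- rbind(c(7, 8, 9, 0, 0, 0, 10, 11, 12, 0, 0, 0),
              c(1, 2, 1, 1, 2, 1, 1, 2, 1, 1, 2, 1))
  m2 <- tiny_matrix(v2, n_is = 1, log2 = TRUE)
  p2 <- per_peak_tests(m2, "F1", "parent1")
  expect_equal(p2$p[1], pooled_t_p_beta(c(10, 11, 12), c(7, 8, 9)),
               tolerance = 1e-12)
  expect_equal(p2$direction[1], "up")

  # a 10-sd shift on one peak makes it the smallest p
  set.seed(71)
  v3 <- matrix(rnorm(10 * 12), nrow = 10)
  v3[4, 7:9] <- v3[4, 7:9] + 10
  m3 <- tiny_matrix(rbind(v3, rep(1, 12)), n_is = 1, log2 = TRUE)
  p3 <- per_peak_tests(m3, "F1", "parent1")
  expect_equal(unname(which.min(p3$p)), 4)
})

test_that("t-test p-values agree with the incomplete-beta oracle on random draws", {
  set.seed(73)
  for (i in 1:100) {
    x <- rnorm(sample(3:8, 1), runif(1, -2, 2))
    y <- rnorm(sample(3:8, 1), runif(1, -2, 2))
    expect_equal(test_vs_bpv(x, y)$p, pooled_t_p_beta(x, y),
                 tolerance = 1e-10)
  }
})

test_that("log2 fold change vs MPV follows its definition and antisymmetry", {
  expect_equal(log2fc_vs_mpv(8, 4, 4), 1)
  expect_equal(log2fc_vs_mpv(6, 4, 8), 0)
  expect_equal(log2fc_vs_mpv(3, 4, 8), -1)
  expect_error(log2fc_vs_mpv(-1, 4, 8), "> 0")
  # swapping hybrid and MPV roles negates the fold
  set.seed(79)
  for (i in 1:20) {
    h <- runif(1, 0.5, 10)
    p1 <- runif(1, 0.5, 10)
    p2 <- runif(1, 0.5, 10)
    mpv <- (p1 + p2) / 2
    expect_equal(log2fc_vs_mpv(h, p1, p2),
                 -log2fc_vs_mpv(mpv, h, h))
  }
})

test_that("both-parent calls need concordant significant directions", {
  expect_equal(call_vs_both_parents(0.01, "up", 0.02, "up"), "up")
  expect_equal(call_vs_both_parents(0.01, "down", 0.02, "down"), "down")
  expect_equal(call_vs_both_parents(0.01, "up", 0.02, "down"), "ns")
  expect_equal(call_vs_both_parents(0.01, "up", 0.20, "up"), "ns")
  expect_equal(call_vs_both_parents(c(0.01, 0.3), c("up", "up"),
                                    c(0.02, 0.01), c("up", "up")),
               c("up", "ns"))
})

test_that("differential tables recover the injected TCA signature", {
  sim <- simulate_metabolome(metabolome_config(seed = 83))
  logm <- impute_and_log2(is_normalize(sim$matrix))
  d <- differential_table(logm, "F1")
  expect_equal(nrow(d), 178) # IS rows excluded
  expect_true(all(d$q_vs_p1 >= d$p_vs_p1 - 1e-14))
  expect_true(all(d$q_vs_p1 >= 0 & d$q_vs_p1 <= 1))
  # direction flags are ns whenever q misses the threshold
  expect_true(all(d$dir_vs_p1[d$q_vs_p1 >= 0.05] == "ns"))
  sig <- d[d$call != "ns", ]
  truth <- sim$ground_truth$effects
  up_true <- truth$annotation[truth$role == "F1" & truth$multiplier > 1]
  down_true <- truth$annotation[truth$role == "F1" & truth$multiplier < 1]
  expect_true(all(up_true %in% sig$annotation[sig$call == "up"]))
  expect_true(all(down_true %in% sig$annotation[sig$call == "down"]))
  # fold signs match the injected multipliers
  expect_gt(d$log2fc_vs_mpv[d$annotation == "fumarate"], 0.8)
  expect_lt(d$log2fc_vs_mpv[d$annotation == "citrate"], -0.3)
})

test_that("the heatmap table formats folds, asterisks, and ND cells", {
  sim <- simulate_metabolome(metabolome_config(seed = 89))
  logm <- impute_and_log2(is_normalize(sim$matrix))
  tabs <- list(`Col x C24` = differential_table(logm, "F1"),
               `C24 x Col` = differential_table(logm, "F1rec"))
  hm <- heatmap_table(tabs)
  expect_equal(nrow(hm), 178)
  fum <- hm[hm$annotation == "fumarate", ]
  expect_match(fum$`Col x C24`, "\\*$")
  # a peak missing from one combination shows as ND
  tabs$`C24 x Col` <- tabs$`C24 x Col`[-1, ]
  hm2 <- heatmap_table(tabs)
  expect_equal(hm2$`C24 x Col`[hm2$peak_id == hm$peak_id[1]], "ND")
})

test_that("null data keeps the both-parent false-call rate near alpha squared", {
  # no injected effects: calls against both parents compound two
  # independent 5% tests, so the expected call rate is about 0.25%
  set.seed(97)
  rates <- purrr::map_dbl(1:10, function(i) {
    sim <- simulate_metabolome(metabolome_config(
      line_effects = list(), seed = 9000 + i))
    logm <- impute_and_log2(is_normalize(sim$matrix))
    d <- differential_table(logm, "F1")
    mean(d$call != "ns")
  })
  expect_lt(mean(rates), 0.05 * 0.05 + 0.01)
})
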