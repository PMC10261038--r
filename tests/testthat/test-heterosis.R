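test_that("MPV and BPV follow their definitions", {
  expect_equal(compute_mpv(c(10, 12, 14), c(6, 8, 10)), 10)
  expect_equal(compute_mpv(5, 5), 5)
  bp <- compute_bpv(c(10, 12, 14), c(6, 8, 10))
  expect_equal(bp$bpv, 12)
  expect_equal(bp$better_parent, "parent1")
  expect_false(bp$tie)
  bp2 <- compute_bpv(c(6, 8, 10), c(10, 12, 14))
  expect_equal(bp2$better_parent, "parent2")
  # exact tie: parent1 designated better, tie flag set
  tie <- compute_bpv(c(4, 6), c(5, 5))
  expect_equal(tie$better_parent, "parent1")
  expect_true(tie$tie)
  expect_error(compute_mpv(numeric(0), 1), "nonempty")
})

test_that("percent heterosis is the relative excess over the reference", {
  expect_equal(heterosis_percent(13.2, 12), 10)
  expect_equal(heterosis_percent(10, 10), 0)
  expect_equal(heterosis_percent(14.4, 10), 44)
  expect_error(heterosis_percent(5, 0), "> 0")
})

test_that("the hybrid-vs-better-parent t-test matches the beta-function oracle", {
  res <- test_vs_bpv(c(10, 11, 12), c(7, 8, 9))
  expect_equal(res$p, pooled_t_p_beta(c(10, 11, 12), c(7, 8, 9)),
               tolerance = 1e-12)
  expect_equal(res$p, 0.021, tolerance = 0.05)
  expect_true(res$significant_above)
  expect_false(res$significant_below)
  # two-sided symmetry: swapping groups keeps p, flips the direction
  flip <- test_vs_bpv(c(7, 8, 9), c(10, 11, 12))
  expect_equal(flip$p, res$p)
  expect_true(flip$significant_below)
  # identical samples: p = 1, no flags
  same <- test_vs_bpv(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)
  expect_false(same$significant_above || same$significant_below)
  # zero variance with unequal means: machine-limit significance, flagged
  deg <- test_vs_bpv(c(5, 5), c(4, 4))
  expect_true(deg$degenerate)
  expect_true(deg$significant_above)
})

test_that("the four-class rule follows the decision tree in order", {
  h <- function(bph, above = FALSE, below = FALSE) {
    list(bph_pct = bph, significant_above = above,
         significant_below = below)
  }
  # high: both significant, max BPH >= 10 (the strongly heterotic pattern)
  expect_equal(classify_combination(h(32.9, above = TRUE),
                                    h(11.6, above = TRUE)), "high")
  # one reciprocal may sit below 10% as long as the other clears it
  expect_equal(classify_combination(h(15, above = TRUE),
                                    h(4, above = TRUE)), "high")
  # weak: significance without a 10% excess on either side
  expect_equal(classify_combination(h(8.9, above = TRUE), h(1.8)), "weak")
  # both significant but both under 10% is still weak, not high
  expect_equal(classify_combination(h(6, above = TRUE),
                                    h(9, above = TRUE)), "weak")
  # none: no significant increase anywhere
  expect_equal(classify_combination(h(3), h(-2)), "none")
  # opposite significant trends are unclassifiable
  expect_equal(classify_combination(h(12, above = TRUE),
                                    h(-8, below = TRUE)), "unclassifiable")
  # mixed leftover: one significantly above by >= 10, other negative
  expect_equal(classify_combination(h(15, above = TRUE), h(-3)),
               "unclassifiable")
  expect_error(classify_combination(h(1), list()), "reciprocal")
})

test_that("every combination gets exactly one label and counts partition", {
  set.seed(21)
  labels <- replicate(60, {
    cfg <- cross_config(heterosis_bph_pct = runif(2, -30, 40),
                        cv = 0.1, seed = sample.int(1e6, 1))
    evaluate_combination(simulate_trait_table(cfg))$class_label
  })
  expect_true(all(labels %in% c("high", "weak", "none", "unclassifiable")))
  tab <- simulate_trait_table(cross_config(seed = 1))
  summary <- summarize_population(evaluate_combination(tab))
  expect_equal(sum(summary$n), 1)
  expect_equal(sum(summary$pct_of_total), 100)
})

test_that("heterosis statistics are invariant to a common rescaling", {
  cfg <- cross_config(heterosis_bph_pct = c(18, 7), cv = 0.08, seed = 31)
  tab <- simulate_trait_table(cfg)
  res <- evaluate_combination(tab)
  scaled <- tab
  scaled$value <- scaled$value * 37.5
  res2 <- evaluate_combination(scaled)
  for (col in c("f1_bph_pct", "f1_mph_pct", "f1_p", "f1rec_bph_pct",
                "f1rec_mph_pct", "f1rec_p")) {
    expect_equal(res2[[col]], res[[col]])
  }
  expect_equal(res2$class_label, res$class_label)
  expect_equal(res2$mpv, res$mpv * 37.5)
})

test_that("MPV never exceeds BPV and BPH never exceeds MPH", {
  set.seed(41)
  for (i in 1:25) {
    p1 <- rnorm(5, runif(1, 50, 150), 5)
    p2 <- rnorm(5, runif(1, 50, 150), 5)
    f1 <- abs(rnorm(1, 100, 30))
    mpv <- compute_mpv(p1, p2)
    bpv <- compute_bpv(p1, p2)$bpv
    expect_lte(mpv, bpv)
    expect_lte(heterosis_percent(f1, bpv), heterosis_percent(f1, mpv))
  }
})

test_that("population summaries report class shares like 9 high of 28", {
  set.seed(51)
  bph_by_class <- list(high = c(25, 15), weak = c(6, 3),
                       none = c(-5, -10))
  counts <- c(high = 9, weak = 2, none = 11, unclassifiable = 6)
  tabs <- purrr::imap(counts, function(n, cls) {
    purrr::map(seq_len(n), function(i) {
      bph <- if (cls == "unclassifiable") c(25, -25) else bph_by_class[[cls]]
      cfg <- cross_config(heterosis_bph_pct = bph, cv = 0.02,
                          seed = sample.int(1e6, 1),
                          combination_id = paste0(cls, "_", i))
      simulate_trait_table(cfg)
    })
  })
  pop <- dplyr::bind_rows(unlist(tabs, recursive = FALSE))
  res <- evaluate_population(pop)
  summ <- summarize_population(res)
  expect_equal(sum(summ$n), 28)
  high_pct <- summ$pct_of_total[summ$class_label == "high"]
  # 9 of 28 -> 32.1%; tight noise keeps every simulated class recoverable
  expect_equal(high_pct, 100 * 9 / 28, tolerance = 0.15)
})
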