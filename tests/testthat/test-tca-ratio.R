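test_that("per-sample ratios and folds follow their arithmetic", {
  expect_equal(sample_ratio(2, 1), 2)
  expect_equal(sample_ratio(1, 1), 1)
  expect_equal(sample_ratio(0.5, 2), 0.25)
  expect_error(sample_ratio(1, 0), "malate")
  expect_warning(r <- sample_ratio(NA, 2), "missing")
  expect_true(is.na(r))

  expect_equal(fold_vs_mpv_ratio(c(4.3, 4.5), c(2.4, 2.6), c(1.4, 1.6)),
               2.2)
  expect_equal(fold_vs_mpv_ratio(c(2, 2), c(2.5, 1.5), c(2.2, 1.8)), 1)
})

test_that("ratio analysis is scale-invariant jointly and linear in fumarate", {
  sim <- simulate_metabolome(metabolome_config(seed = 101))
  norm <- is_normalize(sim$matrix)
  res <- tca_ratio(norm)
  # multiplying both areas by a constant changes nothing
  both <- norm
  fi <- which(both$peaks$annotation == "fumarate")
  mi <- which(both$peaks$annotation == "malate")
  both$values[c(fi, mi), ] <- both$values[c(fi, mi), ] * 7.5
  res_both <- tca_ratio(both)
  expect_equal(res_both$samples$ratio, res$samples$ratio)
  expect_equal(res_both$fold_vs_mpv, res$fold_vs_mpv)
  expect_equal(res_both$letters, res$letters)
  # multiplying only fumarate by c multiplies ratios and line means by c,
  # while the fold vs MPV (a ratio of ratios) is unchanged
  fum <- norm
  fum$values[fi, ] <- fum$values[fi, ] * 3
  res_fum <- tca_ratio(fum)
  expect_equal(res_fum$samples$ratio, res$samples$ratio * 3)
  expect_equal(res_fum$line_means, res$line_means * 3)
  expect_equal(res_fum$fold_vs_mpv, res$fold_vs_mpv)
})

test_that("the injected fumarate effect is recovered as the fold vs MPV", {
  folds <- purrr::map_dfr(1:25, function(i) {
    sim <- simulate_metabolome(metabolome_config(seed = 3000 + i))
    res <- tca_ratio(is_normalize(sim$matrix))
    tibble::tibble(F1 = res$fold_vs_mpv[["F1"]],
                   F1rec = res$fold_vs_mpv[["F1rec"]])
  })
  expect_equal(mean(folds$F1), 2.2, tolerance = 0.05)
  expect_equal(mean(folds$F1rec), 1.9, tolerance = 0.05)
})

test_that("a no-effect configuration concentrates the fold at 1", {
  folds <- purrr::map_dbl(1:25, function(i) {
    sim <- simulate_metabolome(metabolome_config(
      line_effects = list(), seed = 4000 + i))
    tca_ratio(is_normalize(sim$matrix))$fold_vs_mpv[["F1"]]
  })
  expect_equal(mean(folds), 1, tolerance = 0.02)
})

test_that("ANOVA + Tukey letters separate what differs and only that", {
  # four identical groups share one letter
  same <- lapply(1:4, function(i) c(1, 2, 3))
  names(same) <- letters[1:4]
  res <- anova_tukey(same)
  expect_true(all(res$letters == "a"))

  # an outlier group gets a letter of its own
  set.seed(103)
  grps <- list(a = rnorm(6, 0), b = rnorm(6, 0), c = rnorm(6, 0),
               d = rnorm(6, 100))
  res2 <- anova_tukey(grps)
  expect_false(any(strsplit(res2$letters[["d"]], "")[[1]] %in%
                     unlist(strsplit(res2$letters[c("a", "b", "c")], ""))))
  expect_lt(res2$anova_p, 1e-10)

  # two groups: letters differ iff the single Tukey p is below alpha
  two_far <- anova_tukey(list(a = c(1, 1.1, 0.9), b = c(5, 5.1, 4.9)))
  expect_false(two_far$letters[["a"]] == two_far$letters[["b"]])
  two_near <- anova_tukey(list(a = c(1, 1.1, 0.9), b = c(1.05, 1.15, 0.95)))
  expect_true(two_near$letters[["a"]] == two_near$letters[["b"]])
})

test_that("letter displays agree exhaustively with pairwise adjusted p-values", {
  set.seed(107)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    centers <- runif(k, 0, 3)
    grps <- stats::setNames(
      lapply(centers, function(mu) rnorm(sample(3:6, 1), mu, 0.5)),
      paste0("g", seq_len(k)))
    expect_true(letters_match_pairwise(grps, alpha = 0.05))
  }
})

test_that("letter displays match multcomp's independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(109)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    grps <- stats::setNames(
      lapply(runif(k, 0, 2.5), function(mu) rnorm(5, mu, 0.4)),
      paste0("g", seq_len(k)))
    ours <- anova_tukey(grps, alpha = 0.05)$letters
    df <- data.frame(g = factor(rep(names(grps), lengths(grps))),
                     v = unlist(grps))
    glht <- multcomp::glht(stats::aov(v ~ g, df),
                           linfct = multcomp::mcp(g = "Tukey"))
    theirs <- multcomp::cld(glht, level = 0.05)$mcletters$Letters
    # same sharing structure (letter names may differ)
    share <- function(l, a, b) {
      any(strsplit(l[[a]], "")[[1]] %in% strsplit(l[[b]], "")[[1]])
    }
    for (pair in utils::combn(names(grps), 2, simplify = FALSE)) {
      expect_equal(share(ours, pair[1], pair[2]),
                   share(theirs, pair[1], pair[2]))
    }
  }
})

test_that("the combination-level ratio result is coherent", {
  sim <- simulate_metabolome(metabolome_config(seed = 113))
  res <- tca_ratio(is_normalize(sim$matrix))
  expect_s3_class(res, "ratio_result")
  expect_true(all(res$samples$ratio > 0))
  expect_equal(nrow(res$samples), 24)
  # folds recompute from the per-line means
  mpv <- (res$line_means[["parent1"]] + res$line_means[["parent2"]]) / 2
  expect_equal(res$fold_vs_mpv[["F1"]], res$line_means[["F1"]] / mpv)
  expect_error(tca_ratio(is_normalize(sim$matrix), fumarate = "nope"),
               "not found")
})
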