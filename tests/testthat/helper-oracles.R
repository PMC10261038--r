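# Independent oracles kept free of the code paths they check.

# Benjamini-Hochberg step-up by explicit sort + right-to-left minimum.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided pooled-variance t-test p-value via the incomplete-beta identity
# P(|T| > t) = pbeta(df / (df + t^2), df / 2, 1 / 2), avoiding pt().
pooled_t_p_beta <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  pbeta(df / (df + t^2), df / 2, 0.5)
}

# Letter-display consistency: shared letter <=> Tukey-adjusted p >= alpha.
letters_match_pairwise <- function(groups, alpha = 0.05) {
  res <- anova_tukey(groups, alpha = alpha)
  shares <- function(a, b) {
    any(strsplit(res$letters[[a]], "")[[1]] %in%
          strsplit(res$letters[[b]], "")[[1]])
  }
  ok <- TRUE
  for (k in seq_len(nrow(res$tukey))) {
    a <- res$tukey$group1[k]
    b <- res$tukey$group2[k]
    ok <- ok && (shares(a, b) == (res$tukey$p_adj[k] >= alpha))
  }
  ok
}

# Small metabolite matrix built directly (no generator) for unit tests.
tiny_matrix <- function(values, n_is = 1, log2 = FALSE,
                        annotations = NULL) {
  n_peaks <- nrow(values)
  n_s <- ncol(values)
  stopifnot(n_s %% 4 == 0)
  reps <- n_s / 4
  roles <- rep(c("parent1", "parent2", "F1", "F1rec"), each = reps)
  lines <- rep(c("P1", "P2", "P1 x P2", "P2 x P1"), each = reps)
  samples <- tibble::tibble(
    sample_id = paste(lines, rep(seq_len(reps), 4), sep = "."),
    line_id = lines, role = roles,
    replicate = rep(seq_len(reps), 4))
  ann <- annotations %||%
    c(rep("unknown", n_peaks - n_is), rep("IS", n_is))
  peaks <- tibble::tibble(
    peak_id = sprintf("pk%02d", seq_len(n_peaks)),
    annotation = ann,
    is_internal_standard = c(rep(FALSE, n_peaks - n_is),
                             rep(TRUE, n_is)))
  metabolite_matrix(values, peaks, samples, log2 = log2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
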