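# exact enumeration oracle for the paired Wilcoxon signed-rank test
# (no zero differences, no tied absolute differences)
wilcoxon_oracle <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  # null distribution by enumerating all 2^n sign assignments
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(rk[signs])
  }, numeric(1))
  p <- mean(abs(ws - n * (n + 1) / 4) >= abs(W - n * (n + 1) / 4))
  list(W = W, p = p)
}

# tie-corrected Friedman statistic from the textbook formula
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  A <- sum(R^2)
  Cj <- colSums(R)
  stat <- (k - 1) * (sum(Cj^2) - n^2 * k * (k + 1)^2 / 4) /
    (A - n * k * (k + 1)^2 / 4)
  list(chisq = stat, df = k - 1, p = pchisq(stat, k - 1, lower.tail = FALSE))
}

make_fits <- function(tbl) {
  tidyr::pivot_longer(tbl, -subject, names_to = "metric",
                      values_to = "rho_max")
}

test_that("metric comparison matches an exact enumeration oracle for 8 subjects", {
  set.seed(20)
  a <- round(runif(8, 0.05, 0.3), 3)
  d <- round(runif(8, -0.1, 0.1), 4)
  d[d == 0] <- 0.013
  b <- a - d
  tbl <- tibble::tibble(subject = 1:8, aec = a, pli = b)
  res <- compare_metric_fits(make_fits(tbl))
  oracle <- wilcoxon_oracle(a - b)
  expect_equal(res$W, oracle$W)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$median_a, median(a))
  expect_equal(res$median_b, median(b))
})

test_that("uniformly shifted metrics give the extreme signed-rank statistic", {
  tbl <- tibble::tibble(subject = 1:8, aec = seq(0.1, 0.31, by = 0.03))
  tbl$pli <- tbl$aec - seq(0.01, 0.08, by = 0.01)  # distinct positive shifts
  res <- compare_metric_fits(make_fits(tbl))
  expect_equal(res$W, 8 * 9 / 2)           # all differences positive
  expect_lt(res$p, 0.01)
  # identical columns are flagged, not tested
  tbl$pli <- tbl$aec
  expect_warning(res0 <- compare_metric_fits(make_fits(tbl)), "zero")
  expect_true(res0$degenerate)
  expect_true(is.na(res0$W))
})

test_that("Friedman test matches the hand rank computation on a 4x3 table", {
  m <- matrix(c(0.10, 0.14, 0.12,
                0.20, 0.26, 0.19,
                0.15, 0.16, 0.18,
                0.08, 0.12, 0.11), 4, 3, byrow = TRUE)
  fits <- tibble::tibble(subject = rep(1:4, each = 3),
                         metric = rep(c("m1", "m2", "m3"), 4),
                         K_opt = as.vector(t(m)))
  res <- compare_optimal_couplings(fits)
  oracle <- friedman_oracle(m)
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
})

test_that("Friedman is 0 for identical columns and maximal for ordered columns", {
  ident <- tibble::tibble(subject = rep(1:4, each = 3),
                          metric = rep(c("m1", "m2", "m3"), 4),
                          K_opt = rep(c(0.1, 0.1, 0.1), 4))
  expect_warning(res <- compare_optimal_couplings(ident), "tie")
  expect_equal(res$chisq, 0)
  # perfectly ordered columns: closed form 12n/(k(k+1)) * sum (j - (k+1)/2)^2
  n <- 5; k <- 3
  ordered <- tibble::tibble(subject = rep(1:n, each = k),
                            metric = rep(paste0("m", 1:k), n),
                            K_opt = rep(c(0.1, 0.2, 0.3), n))
  res2 <- compare_optimal_couplings(ordered)
  expect_equal(res2$chisq, 12 * n / (k * (k + 1)) *
                 sum((1:k - (k + 1) / 2)^2))
})

test_that("individual-vs-group pairs fits and tests per metric", {
  set.seed(23)
  subs <- 1:8
  ind <- tibble::tibble(subject = rep(subs, 2),
                        metric = rep(c("aec", "pli"), each = 8),
                        rho_max = round(runif(16, 0.1, 0.3), 3))
  grp <- dplyr::mutate(ind, rho_max = rho_max - round(runif(16, 0, 0.08), 3))
  res <- individual_vs_group(ind, grp)
  expect_equal(nrow(res$pairs), 16)
  expect_true(all(res$pairs$diff >= 0))
  expect_equal(res$test$W, rep(36, 2))     # own SC uniformly better: extreme W
  # degenerate: identical fits
  expect_warning(res0 <- individual_vs_group(ind, ind)$test, NA)
  res0 <- individual_vs_group(ind, ind)$test
  expect_true(all(res0$degenerate))
  # mismatched subject sets error
  expect_error(individual_vs_group(ind, grp[-1, ]), "match")
})

test_that("specificity ranking matches a brute-force sort oracle", {
  set.seed(24)
  n <- 10
  mk_fc <- function(seed) {
    set.seed(seed)
    v <- matrix(rnorm(64), 8, 8)
    fc_matrix((v + t(v)) / 2, metric = "aec")
  }
  emp <- lapply(1:n, function(i) mk_fc(300 + i))
  # simulated = noisy copy of matched empirical: matched should win often
  sim <- lapply(1:n, function(i) {
    set.seed(400 + i)
    noise <- matrix(rnorm(64, sd = 0.4), 8, 8)
    fc_matrix(unclass(emp[[i]]) * 0 + (ifelse(is.na(unclass(emp[[i]])), 0,
              unclass(emp[[i]])) + (noise + t(noise)) / 2), metric = "aec")
  })
  res <- specificity_analysis(sim, emp)
  expect_equal(diag(res$cross_rho), res$table$own_rho)
  for (i in 1:n) {
    row <- res$cross_rho[i, ]
    expect_equal(res$table$rank[i], sum(sort(row, decreasing = TRUE) >= row[i]))
    expect_equal(res$table$significant[i],
                 res$table$rank[i] <= max(1, floor(n * 0.025)))
  }
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_subjects, n)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("specificity extremes: perfect match vs indistinguishable targets", {
  mk_fc <- function(seed) {
    set.seed(seed)
    v <- matrix(rnorm(49), 7, 7)
    fc_matrix((v + t(v)) / 2, metric = "aec")
  }
  emp <- lapply(1:5, function(i) mk_fc(i))
  res <- specificity_analysis(emp, emp)      # sim_i == emp_i, distinct
  expect_true(all(res$table$significant))
  expect_equal(res$table$own_rho, rep(1, 5))
  same <- lapply(1:5, function(i) emp[[1]])  # all empirical identical
  res2 <- specificity_analysis(emp, same)
  expect_false(any(res2$table$significant))
})

test_that("specificity significance is invariant under common monotone transforms", {
  mk_fc <- function(seed) {
    set.seed(seed)
    v <- matrix(rnorm(49), 7, 7)
    fc_matrix((v + t(v)) / 2, metric = "aec")
  }
  emp <- lapply(1:6, function(i) mk_fc(50 + i))
  sim <- lapply(1:6, function(i) mk_fc(80 + i))
  warp <- function(f) fc_matrix(tanh(ifelse(is.na(unclass(f)), 0,
                                            unclass(f)) * 2), metric = "aec")
  r1 <- specificity_analysis(sim, emp)
  r2 <- specificity_analysis(lapply(sim, warp), lapply(emp, warp))
  expect_equal(r1$table$significant, r2$table$significant)
  expect_equal(r1$table$rank, r2$table$rank)
})

test_that("strongest-connections mask is the sorted top fraction of empirical edges", {
  set.seed(26)
  v <- matrix(rnorm(36), 6, 6)
  emp <- fc_matrix((v + t(v)) / 2, metric = "aec")
  w <- matrix(rnorm(36), 6, 6)
  sim <- fc_matrix((w + t(w)) / 2, metric = "aec")
  # fraction 1 reduces to the full-matrix correlation
  full <- strongest_connections_match(sim, emp, fraction = 1)
  expect_equal(full$rho, spearman_rho(ut_vec(sim), ut_vec(emp))$rho)
  # fraction 0.4 of 15 edges -> top 6, verified against a sorted brute force
  res <- strongest_connections_match(sim, emp, fraction = 0.4)
  e <- ut_vec(emp); s <- ut_vec(sim)
  keep <- order(e, decreasing = TRUE)[1:6]
  expect_equal(res$n_edges, 6)
  expect_equal(res$rho, spearman_rho(s[keep], e[keep])$rho)
  # monotone transform of the empirical matrix: same mask, same rho
  warped <- fc_matrix(exp(ifelse(is.na(unclass(emp)), 0, unclass(emp))),
                      metric = "aec")
  expect_equal(strongest_connections_match(sim, warped, fraction = 0.4)$rho,
               res$rho)
  expect_error(strongest_connections_match(sim, emp, fraction = 0.1),
               "3 edges")
})
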