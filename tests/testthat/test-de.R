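expr_from_matrix <- function(m, arrays) {
  out <- tibble::tibble(probeset_id = sprintf("ps%04d", seq_len(nrow(m))))
  out[arrays] <- as.data.frame(m)
  out
}

two_group <- function(n1 = 2, n2 = 2) {
  tibble::tibble(
    array_id = c(paste0("A", seq_len(n1)), paste0("B", seq_len(n2))),
    condition = rep(c("A", "B"), c(n1, n2))
  )
}

test_that("the moderated t reproduces the hand-worked shrinkage example", {
  # logFC = 1, pooled s2 = 3 with n1 = n2 = 2 (d_g = 2)
  a <- sqrt(1.5)
  m <- rbind(c(-a, a, 1 - a, 1 + a))
  de <- moderated_t_test(
    expr_from_matrix(m, c("A1", "A2", "B1", "B2")), two_group(),
    prior = list(d0 = 2, s02 = 1)
  )
  expect_equal(de$logfc, 1)
  expect_equal(de$s2, 3)
  # s~^2 = (2*1 + 2*3) / 4 = 2 ; t = 1 / sqrt(2 * (1/2 + 1/2)) ; df = 4
  expect_equal(de$t, 1 / sqrt(2))
  expect_equal(de$df_total, 4)
  expect_equal(de$p_value, 2 * pt(1 / sqrt(2), df = 4, lower.tail = FALSE))
})

test_that("d0 = 0 recovers the ordinary pooled t; d0 = Inf uses the prior variance", {
  withr::local_seed(21)
  m <- matrix(rnorm(50 * 7, 8, 1), 50, 7)
  groups <- two_group(4, 3)
  de0 <- moderated_t_test(
    expr_from_matrix(m, groups$array_id), groups, prior = list(d0 = 0, s02 = 5)
  )
  # ordinary pooled two-sample t, computed independently
  ref <- apply(m, 1, function(x) {
    unname(stats::t.test(x[5:7], x[1:4], var.equal = TRUE)$statistic)
  })
  expect_equal(de0$t, ref)
  expect_equal(de0$df_total, rep(5, 50))
  dinf <- moderated_t_test(
    expr_from_matrix(m, groups$array_id), groups, prior = list(d0 = Inf, s02 = 5)
  )
  se <- sqrt(5 * (1 / 4 + 1 / 3))
  expect_equal(dinf$t, (rowMeans(m[, 5:7]) - rowMeans(m[, 1:4])) / se)
  # normal tail when prior df are infinite
  expect_equal(dinf$p_value, 2 * stats::pnorm(abs(dinf$t), lower.tail = FALSE))
})

test_that("zero fold change gives t = 0, p = 1", {
  m <- cbind(c(1, 2), c(3, 0.5), c(1, 2), c(3, 0.5))
  de <- moderated_t_test(
    expr_from_matrix(m, c("A1", "A2", "B1", "B2")), two_group(),
    prior = list(d0 = 1, s02 = 1)
  )
  expect_equal(de$t, c(0, 0))
  expect_equal(de$p_value, c(1, 1))
})

test_that("variance prior fitting handles the degenerate and small-G contracts", {
  expect_error(
    fit_variance_prior(rep(0, 100), 5),
    class = "maxrs_degenerate_error"
  )
  expect_error(
    fit_variance_prior(c(1, 2, 3, 4, 5), 5),
    class = "maxrs_insufficient_data_error"
  )
  # identical variances: no excess spread, infinite prior df; the scale is
  # exp(mean(e)), which corrects log s2 for the sampling bias of log chi-square
  pr <- fit_variance_prior(rep(2.5, 1000), 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s02, exp(log(2.5) - digamma(2) + log(2)))
  # and the posterior variance is then constant at s02 for every gene
  m <- matrix(c(1, 3, 2, 4, 1.5, 3.5, 2.5, 4.5), 2, 4)
  de <- moderated_t_test(
    tibble::tibble(
      probeset_id = c("a", "b"),
      A1 = m[, 1], A2 = m[, 2], B1 = m[, 3], B2 = m[, 4]
    ),
    two_group(), prior = list(d0 = Inf, s02 = 0.7)
  )
  expect_equal(de$t * sqrt(0.7 * (1 / 2 + 1 / 2)), de$logfc)
})

test_that("the prior fit recovers hierarchical scaled-inv-chi-square parameters", {
  withr::local_seed(22)
  d0 <- 4
  s02 <- 2
  dg <- 5
  g <- 20000
  sigma2 <- s02 * d0 / stats::rchisq(g, d0)
  s2 <- sigma2 * stats::rchisq(g, dg) / dg
  pr <- fit_variance_prior(s2, dg)
  expect_lt(abs(pr$d0 - d0), 0.5)
  expect_lt(abs(pr$s02 - s02) / s02, 0.10)
})

test_that("moderated t matches limma::eBayes on random data", {
  withr::local_seed(23)
  # heteroscedastic gene variances so the prior df are finite for both fits
  sigma <- sqrt(1.2 * 5 / stats::rchisq(300, 5))
  m <- matrix(rnorm(300 * 7, 8, sigma), 300, 7)
  m[1:30, 5:7] <- m[1:30, 5:7] + 2
  groups <- two_group(4, 3)
  de <- moderated_t_test(expr_from_matrix(m, groups$array_id), groups)
  design <- cbind(1, rep(c(0, 1), c(4, 3)))
  efit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(de, "d0"), efit$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "s02"), efit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(efit$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p_value, unname(efit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(de$df_total, unname(efit$df.total), tolerance = 1e-4)
})

test_that("BH adjustment matches the hand case and the brute-force definition", {
  expect_equal(
    bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5)
  )
  expect_equal(bh_adjust(0.37), 0.37)
  withr::local_seed(24)
  for (rep in 1:100) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "maxrs_config_error")
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("calls respect the inclusive FDR threshold and logFC sign", {
  de <- tibble::tibble(
    probeset_id = c("a", "b", "c", "d"),
    logfc = c(2, -2, 2, 0.5),
    p_adj = c(0.10, 0.05, 0.2, 1)
  )
  called <- call_de(de, alpha = 0.10)
  expect_identical(called$de_call, c("up", "down", "none", "none"))
  none <- call_de(dplyr::mutate(de, p_adj = 1), alpha = 0.10)
  expect_true(all(none$de_call == "none"))
  expect_error(call_de(de, alpha = 0), class = "maxrs_config_error")
})

test_that("a group with fewer than two arrays is a design error", {
  m <- matrix(rnorm(30), 10, 3)
  groups <- tibble::tibble(
    array_id = c("A1", "A2", "B1"), condition = c("A", "A", "B")
  )
  expect_error(
    moderated_t_test(expr_from_matrix(m, groups$array_id), groups),
    class = "maxrs_format_error"
  )
})

test_that("type-I error and FDR are controlled on the model's own data", {
  withr::local_seed(25)
  groups <- two_group(4, 3)
  # null: every gene from the hierarchical variance model, no mean shift
  g <- 4000
  sigma <- sqrt(1.5 * 6 / stats::rchisq(g, 6))
  m <- matrix(rnorm(g * 7, 0, sigma), g, 7)
  de_null <- moderated_t_test(expr_from_matrix(m, groups$array_id), groups)
  frac <- mean(de_null$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / g))
  # planted DE: observed FDR at alpha = 0.10 within Monte Carlo error
  fdrs <- vapply(1:4, function(s) {
    withr::with_seed(250 + s, {
      sig <- sqrt(1.5 * 6 / stats::rchisq(g, 6))
      x <- matrix(rnorm(g * 7, 0, sig), g, 7)
      truth <- seq_len(g) <= g / 10
      x[truth, 5:7] <- x[truth, 5:7] + sample(c(-2, 2), g / 10, replace = TRUE)
      de <- moderated_t_test(expr_from_matrix(x, groups$array_id), groups)
      called <- de$de_call != "none"
      if (any(called)) sum(called & !truth) / sum(called) else 0
    })
  }, 0)
  expect_lte(mean(fdrs), 0.10 + 3 * stats::sd(fdrs) / sqrt(length(fdrs)))
})

test_that("moderation gains power over the ordinary t at matched type-I error", {
  withr::local_seed(26)
  groups <- two_group(3, 3)
  g <- 3000
  sigma <- sqrt(1.0 * 4 / stats::rchisq(g, 4))
  m <- matrix(rnorm(g * 6, 0, sigma), g, 6)
  truth <- seq_len(g) <= 300
  m[truth, 4:6] <- m[truth, 4:6] + 1.5
  expr <- expr_from_matrix(m, groups$array_id)
  de_mod <- moderated_t_test(expr, groups)
  de_ord <- moderated_t_test(expr, groups, prior = list(d0 = 0, s02 = 1))
  # equal nominal type-I on the null genes
  alpha_emp_mod <- mean(de_mod$p_value[!truth] < 0.05)
  alpha_emp_ord <- mean(de_ord$p_value[!truth] < 0.05)
  expect_lt(abs(alpha_emp_mod - alpha_emp_ord), 0.02)
  power_mod <- mean(de_mod$p_value[truth] < 0.05)
  power_ord <- mean(de_ord$p_value[truth] < 0.05)
  expect_gt(power_mod, power_ord)
})
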