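make_study <- function(values, condition = NULL, batch = "b1") {
  n <- ncol(values)
  condition <- condition %||% rep(c("UC", "CRC"), length.out = n)
  layernet::expression_study(values, condition, rep(batch, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("quantile normalization matches the hand-computed reference", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  out <- rank_normalize(make_study(m))$values
  # reference distribution = mean of order statistics: (1+4)/2, (2+5)/2,
  # (3+6)/2 = 2.5, 3.5, 4.5, placed by rank in each column
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
})

test_that("all columns share one value multiset after normalization", {
  set.seed(1)
  m <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  out <- rank_normalize(make_study(m))$values
  ref <- sort(unname(out[, 1]))
  for (j in 2:4) expect_equal(sort(unname(out[, j])), ref)
})

test_that("quantile normalization is idempotent", {
  set.seed(2)
  m <- matrix(rnorm(120), 30, 4,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:4)))
  once <- rank_normalize(make_study(m))
  twice <- rank_normalize(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("normalization rejects degenerate inputs", {
  m <- matrix(1:3, 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_error(rank_normalize(make_study(m, condition = "UC")), ">= 2")
  m2 <- matrix(c(1, NA, 3, 4), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(rank_normalize(make_study(m2)), "missing")
})

test_that("merge reports common and unique gene counts", {
  m1 <- matrix(rnorm(8), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  m2 <- matrix(rnorm(8), 4, 2,
               dimnames = list(c("B", "C", "D", "E"), c("t1", "t2")))
  res <- merge_studies(list(make_study(m1, batch = "b1"),
                            make_study(m2, batch = "b2")))
  expect_equal(res$report$n_common, 3)
  expect_equal(unname(res$report$n_unique), c(1, 1))
  expect_equal(res$report$n_union, 5)
  expect_equal(ncol(res$merged$values), 4)   # sample conservation
  expect_setequal(rownames(res$merged$values), c("B", "C", "D"))
  # identical gene lists: everything common
  m1b <- m1
  colnames(m1b) <- c("t1", "t2")
  res2 <- merge_studies(list(make_study(m1, batch = "b1"),
                             make_study(m1b, batch = "b2")))
  expect_equal(res2$report$n_common, 4)
  expect_equal(sum(res2$report$n_unique), 0)
  # disjoint universes are an error
  m3 <- matrix(rnorm(4), 2, 2, dimnames = list(c("X", "Y"), c("u1", "u2")))
  expect_error(merge_studies(list(make_study(m1), make_study(m3))),
               "intersection")
})

two_batch_study <- function(G = 300, n_per = 20, gamma_sd = 0.6,
                            delta_shape = 4, beta_effect = 1.5,
                            de_frac = 0.1, noise = 0.5, seed = 1) {
  set.seed(seed)
  gamma <- cbind(rnorm(G, 0, gamma_sd), rnorm(G, 0, gamma_sd))
  delta <- cbind((delta_shape - 1) / rgamma(G, delta_shape, 1),
                 (delta_shape - 1) / rgamma(G, delta_shape, 1))
  beta <- ifelse(runif(G) < de_frac, beta_effect, 0)
  cond <- rep(rep(c("UC", "CRC"), each = n_per / 2), 2)
  batch <- rep(c("b1", "b2"), each = n_per)
  m <- matrix(0, G, 2 * n_per)
  for (j in seq_len(2 * n_per)) {
    bi <- if (batch[j] == "b1") 1 else 2
    m[, j] <- 7 + beta * (cond[j] == "CRC") + gamma[, bi] +
      delta[, bi] * rnorm(G, 0, noise)
  }
  rownames(m) <- sprintf("G%03d", seq_len(G))
  colnames(m) <- sprintf("S%02d", seq_len(2 * n_per))
  list(study = layernet::expression_study(m, cond, batch),
       gamma = gamma, delta = delta, beta = beta)
}

test_that("single-batch adjustment is the identity", {
  set.seed(4)
  m <- matrix(rnorm(60, 7), 15, 4,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%d", 1:4)))
  st <- make_study(m)
  out <- eb_batch_adjust(st)
  expect_identical(out$adjusted$values, m)
})

test_that("EB adjustment centers batch differences and shrinkage helps", {
  mae_raw <- mae_shrunk <- numeric(3)
  for (r in 1:3) {
    sim <- two_batch_study(G = 600, n_per = 50, de_frac = 0, seed = 7 + r)
    out <- eb_batch_adjust(sim$study)
    # shape and ordering preserved
    expect_identical(dim(out$adjusted$values), dim(sim$study$values))
    expect_identical(dimnames(out$adjusted$values),
                     dimnames(sim$study$values))
    # post-adjustment per-gene batch mean differences center on 0
    v <- out$adjusted$values
    b <- sim$study$batch
    diff_after <- rowMeans(v[, b == "b1"]) - rowMeans(v[, b == "b2"])
    diff_before <- rowMeans(sim$study$values[, b == "b1"]) -
      rowMeans(sim$study$values[, b == "b2"])
    expect_lt(mean(abs(diff_after)), 0.1 * mean(abs(diff_before)))
    expect_lt(abs(mean(diff_after)), 0.01)
    # shrunken additive estimates vs raw ones against the centered truth
    sdp <- sqrt(out$model$var_pooled)
    truth_centered <- sim$gamma - rowMeans(sim$gamma)  # equal batch sizes
    mae_raw[r] <- mean(abs(t(out$model$gamma_hat) * sdp - truth_centered))
    mae_shrunk[r] <- mean(abs(t(out$model$gamma_star) * sdp -
                                truth_centered))
  }
  expect_lt(mean(mae_shrunk), mean(mae_raw))
})

test_that("parametric gamma* lies between gamma_hat and the prior mean", {
  sim <- two_batch_study(G = 200, n_per = 16, seed = 10)
  model <- eb_batch_adjust(sim$study)$model
  for (bi in 1:2) {
    gh <- model$gamma_hat[bi, ]
    gs <- model$gamma_star[bi, ]
    gbar <- model$hyperparams[[bi]]$gamma_bar
    between <- (gs >= pmin(gh, gbar) - 1e-9) & (gs <= pmax(gh, gbar) + 1e-9)
    expect_true(all(between))
    expect_true(all(model$delta_star[bi, ] > 0))
  }
})

test_that("planted condition effects survive adjustment", {
  sim <- two_batch_study(G = 400, n_per = 40, beta_effect = 1.5,
                         de_frac = 0.15, seed = 12)
  out <- eb_batch_adjust(sim$study)
  de <- sim$beta != 0
  cond <- sim$study$condition
  d_after <- rowMeans(out$adjusted$values[de, cond == "CRC"]) -
    rowMeans(out$adjusted$values[de, cond == "UC"])
  # attenuation below 10% of the planted effect
  expect_gt(mean(d_after) / 1.5, 0.9)
})

test_that("both EB modes agree with the independent ComBat oracle", {
  sim <- two_batch_study(G = 150, n_per = 12, seed = 14)
  mod <- stats::model.matrix(~factor(sim$study$condition,
                                     levels = c("UC", "CRC")))
  for (mode in c("parametric", "nonparametric")) {
    mine <- eb_batch_adjust(sim$study, mode = mode)$adjusted$values
    ref <- suppressMessages(
      sva::ComBat(sim$study$values, batch = sim$study$batch, mod = mod,
                  par.prior = (mode == "parametric")))
    expect_equal(mine, ref, tolerance = 1e-4,
                 info = paste("mode:", mode))
  }
})

test_that("zero-variance genes pass through with a warning", {
  sim <- two_batch_study(G = 50, n_per = 10, seed = 16)
  vals <- sim$study$values
  vals[3, ] <- 5
  st <- layernet::expression_study(vals, sim$study$condition,
                                   sim$study$batch)
  expect_warning(out <- eb_batch_adjust(st), "zero-variance")
  expect_identical(unname(out$adjusted$values[3, ]), rep(5, 20))
  expect_equal(out$model$zero_variance_genes, rownames(vals)[3])
})
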