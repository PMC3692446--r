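#' Empirical-Bayes batch adjustment of a merged cohort
#'
#' Location/scale batch model: the expression of gene g in sample j of
#' batch i is `alpha_g + X beta_g + gamma_ig + delta_ig * eps`, with
#' additive (`gamma`) and multiplicative (`delta`) per-gene batch effects.
#' The data are standardized with the gene-wise grand mean, protected
#' condition effect and pooled variance; per-batch effects are estimated
#' gene-wise and then shrunk toward batch-level priors before removal:
#'
#' * parametric: normal prior on `gamma`, inverse-gamma prior on `delta`,
#'   method-of-moments hyperparameters, and the iterative joint posterior
#'   solution for `(gamma*, delta*)` (tolerance `1e-6`, at most 500
#'   iterations; non-convergence is an error);
#' * nonparametric: weighted-likelihood posterior means over the empirical
#'   distribution of the other genes' `(gamma_hat, delta_hat)`.
#'
#' Adjusted values are `(standardized - gamma*)/sqrt(delta*)` rescaled to
#' the original location/scale. The condition is a protected covariate so
#' real biology is not regressed out. Genes with zero pooled variance are
#' flagged and passed through unadjusted (with a warning count) rather than
#' dropped, keeping the gene universe aligned with the network stage.
#'
#' @param merged an [expression_study()] with >= 2 batches, each with >= 2
#'   samples; condition labels are used to protect the group effect.
#' @param mode `"parametric"` (default) or `"nonparametric"`.
#' @param tol convergence tolerance of the parametric fixpoint.
#' @param max_iter iteration cap of the parametric fixpoint.
#' @return list with `adjusted` (ExpressionStudy, same shape and ordering)
#'   and `model` (a `BatchModel` list: `alpha`, `beta`, `gamma_hat`,
#'   `gamma_star`, `delta_hat`, `delta_star`, `hyperparams`, `var_pooled`,
#'   `zero_variance_genes`).
#' @export
eb_batch_adjust <- function(merged, mode = c("parametric", "nonparametric"),
                            tol = 1e-6, max_iter = 500L) {
  mode <- match.arg(mode)
  stopifnot(inherits(merged, "ExpressionStudy"))
  dat <- merged$values
  if (anyNA(dat))
    stopf("missing values in merged matrix; merge with scope = \"common\"")
  batch <- factor(merged$batch, levels = unique(merged$batch))
  batches <- levels(batch)
  n_batch <- length(batches)
  if (n_batch < 2) {
    # degenerate single-batch call: nothing to adjust
    return(list(adjusted = merged, model = NULL))
  }
  tab <- table(batch)
  if (any(tab < 2)) stopf("every batch needs >= 2 samples")
  N <- ncol(dat)
  G <- nrow(dat)

  zero_var <- apply(dat, 1, stats::var) == 0
  keep <- which(!zero_var)
  if (any(zero_var))
    warnf("%d zero-variance gene(s) passed through unadjusted",
          sum(zero_var))
  X <- dat[keep, , drop = FALSE]
  g <- nrow(X)

  batch_design <- stats::model.matrix(~ 0 + batch)
  cond <- factor(merged$condition, levels = CONDITION_LEVELS)
  mod <- stats::model.matrix(~cond)[, -1, drop = FALSE]
  # a single-condition cohort leaves nothing to protect
  mod <- mod[, apply(mod, 2, function(x) length(unique(x)) > 1),
             drop = FALSE]
  design <- cbind(batch_design, mod)

  B_hat <- solve(crossprod(design), t(design) %*% t(X))   # p x g
  w <- as.numeric(tab) / N
  grand_mean <- crossprod(w, B_hat[seq_len(n_batch), , drop = FALSE]) # 1 x g
  fitted <- t(design %*% B_hat)
  var_pooled <- rowSums((X - fitted)^2) / N
  stand_mean <- matrix(grand_mean, g, N)
  tmp <- design
  tmp[, seq_len(n_batch)] <- 0
  stand_mean <- stand_mean + t(tmp %*% B_hat)
  sd_pooled <- sqrt(var_pooled)
  s_data <- (X - stand_mean) / sd_pooled

  gamma_hat <- solve(crossprod(batch_design),
                     t(batch_design) %*% t(s_data))       # n_batch x g
  delta_hat <- t(vapply(batches, function(b) {
    apply(s_data[, batch == b, drop = FALSE], 1, stats::var)
  }, numeric(g)))
  rownames(gamma_hat) <- rownames(delta_hat) <- batches

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  aprior <- function(d) { m <- mean(d); s2 <- stats::var(d)
    (2 * s2 + m^2) / s2 }
  bprior <- function(d) { m <- mean(d); s2 <- stats::var(d)
    (m * s2 + m^3) / s2 }

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  hyper <- vector("list", n_batch)
  names(hyper) <- batches

  for (bi in seq_len(n_batch)) {
    sdat <- s_data[, batch == batches[bi], drop = FALSE]
    n_i <- ncol(sdat)
    g_hat <- gamma_hat[bi, ]
    d_hat <- delta_hat[bi, ]
    if (mode == "parametric") {
      a <- aprior(d_hat); b <- bprior(d_hat)
      hyper[[bi]] <- list(gamma_bar = gamma_bar[bi], t2 = t2[bi],
                          lambda = a, theta = b)
      g_old <- g_hat; d_old <- d_hat
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        g_new <- (t2[bi] * n_i * g_hat + d_old * gamma_bar[bi]) /
          (t2[bi] * n_i + d_old)
        sum2 <- rowSums((sdat - g_new)^2)
        d_new <- (0.5 * sum2 + b) / (n_i / 2 + a - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old))
        g_old <- g_new; d_old <- d_new
        if (change < tol) { converged <- TRUE; break }
      }
      if (!converged)
        stopf("parametric EB fixpoint did not converge in %d iterations",
              max_iter)
      gamma_star[bi, ] <- g_old
      delta_star[bi, ] <- d_old
    } else {
      hyper[[bi]] <- list(gamma_bar = gamma_bar[bi], t2 = t2[bi])
      post <- np_posterior(sdat, g_hat, d_hat)
      gamma_star[bi, ] <- post$gamma
      delta_star[bi, ] <- post$delta
    }
  }

  adj <- s_data
  for (bi in seq_len(n_batch)) {
    j <- batch == batches[bi]
    adj[, j] <- (s_data[, j, drop = FALSE] - gamma_star[bi, ]) /
      sqrt(delta_star[bi, ])
  }
  adj <- adj * sd_pooled + stand_mean

  out <- dat
  out[keep, ] <- adj
  model <- structure(list(
    alpha = stats::setNames(as.numeric(grand_mean), rownames(X)),
    beta = stats::setNames(
      if (ncol(mod) >= 1) as.numeric(B_hat[n_batch + 1, ]) else rep(0, g),
      rownames(X)),
    gamma_hat = gamma_hat, gamma_star = gamma_star,
    delta_hat = delta_hat, delta_star = delta_star,
    hyperparams = hyper, var_pooled = var_pooled,
    zero_variance_genes = rownames(dat)[zero_var],
    mode = mode
  ), class = "BatchModel")
  list(adjusted = expression_study(out, merged$condition, merged$batch),
       model = model)
}

# nonparametric posterior means: for each gene, weight the other genes'
# (gamma_hat, delta_hat) by the likelihood of this gene's standardized data;
# computed in log space for stability
np_posterior <- function(sdat, g_hat, d_hat) {
  g <- nrow(sdat)
  n <- ncol(sdat)
  sx <- rowSums(sdat)
  sx2 <- rowSums(sdat^2)
  gamma_out <- numeric(g)
  delta_out <- numeric(g)
  for (i in seq_len(g)) {
    gj <- g_hat[-i]
    dj <- d_hat[-i]
    sum2 <- sx2[i] - 2 * gj * sx[i] + n * gj^2
    loglh <- -(n / 2) * log(2 * pi * dj) - sum2 / (2 * dj)
    wgt <- exp(loglh - max(loglh))
    sw <- sum(wgt)
    gamma_out[i] <- sum(gj * wgt) / sw
    delta_out[i] <- sum(dj * wgt) / sw
  }
  list(gamma = gamma_out, delta = delta_out)
}
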