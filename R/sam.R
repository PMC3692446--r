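#' Parameters for the SAM differential screen
#'
#' @param s0 fudge constant added to the pooled standard error; `NULL`
#'   (default) selects it with [choose_s0()].
#' @param n_permutations number of balanced label permutations for the
#'   null; all distinct assignments are enumerated when fewer exist.
#' @param target_fdr target false discovery rate for delta selection.
#' @param fc_threshold two-sided fold-change cut (anti-logged ratio).
#' @param seed integer seed for the permutation draw.
#' @return a `sam_params` list.
#' @export
sam_params <- function(s0 = NULL, n_permutations = 100L, target_fdr = 0.05,
                       fc_threshold = 1.2, seed = 1L) {
  if (!is.null(s0) && s0 < 0) stopf("s0 must be >= 0")
  if (target_fdr <= 0 || target_fdr >= 1) stopf("target_fdr must be in (0,1)")
  if (fc_threshold <= 1) stopf("fc_threshold must be > 1")
  structure(list(s0 = s0, n_permutations = as.integer(n_permutations),
                 target_fdr = target_fdr, fc_threshold = fc_threshold,
                 seed = as.integer(seed)), class = "sam_params")
}

check_groups <- function(labels) {
  labels <- as.character(labels)
  n1 <- sum(labels == "UC"); n2 <- sum(labels == "CRC")
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 samples (UC=%d, CRC=%d)",
                              n1, n2)
  list(uc = which(labels == "UC"), crc = which(labels == "CRC"))
}

#' The SAM modified t-statistic
#'
#' `d = (mean(CRC) - mean(UC)) / (s + s0)` with the pooled two-sample
#' standard error
#' `s = sqrt((1/n1 + 1/n2) * (SS_UC + SS_CRC) / (n1 + n2 - 2))`.
#'
#' @param matrix gene x sample log2 matrix.
#' @param labels per-sample condition labels in `c("UC", "CRC")`.
#' @param s0 fudge constant.
#' @return list with per-gene `d` and `s`.
#' @export
sam_statistic <- function(matrix, labels, s0 = 0) {
  idx <- check_groups(labels)
  x1 <- matrix[, idx$uc, drop = FALSE]
  x2 <- matrix[, idx$crc, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  d <- (m2 - m1) / (s + s0)
  list(d = d, s = s)
}

#' Select the SAM fudge constant s0
#'
#' Grid search over percentiles of the pooled standard errors `s`; returns
#' the candidate minimizing the coefficient of variation of the median
#' absolute deviation of `d` across `s`-quantile windows (the standard SAM
#' recipe). On ties the 5th-percentile candidate wins.
#'
#' @param matrix gene x sample log2 matrix (>= 10 genes).
#' @param labels per-sample condition labels.
#' @return the selected s0 (in `[0, max(s)]`).
#' @export
choose_s0 <- function(matrix, labels) {
  if (nrow(matrix) < 10) stopf("choose_s0 needs >= 10 genes")
  base <- sam_statistic(matrix, labels, s0 = 0)
  s <- base$s
  num <- base$d * s            # mean difference, reused per candidate
  probs <- c(0.05, setdiff(seq(0, 1, by = 0.05), 0.05))
  # 0 itself is always a candidate; the 5th-percentile candidate is listed
  # first so it wins ties (which.min takes the first minimum)
  cands <- c(unname(stats::quantile(s, 0.05, type = 7)), 0,
             unname(stats::quantile(s, setdiff(probs, 0.05), type = 7)))
  m <- length(s)
  n_win <- max(3L, min(100L, m %/% 10L))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(cands, function(a) {
    d_a <- num / (s + a)
    mads <- tapply(abs(d_a), win, stats::mad)
    mu <- mean(mads)
    if (!is.finite(mu) || mu == 0) return(NA_real_)
    stats::sd(mads) / mu
  }, numeric(1))
  if (all(is.na(cv))) return(cands[1])
  cands[which.min(cv)]
}

# all (or B sampled) balanced re-labelings: which samples carry the UC label
balanced_splits <- function(n, n1, B, seed) {
  total <- choose(n, n1)
  if (total <= B) {
    if (total < B)
      warnf("only %d distinct balanced permutations exist; using all", total)
    return(utils::combn(n, n1, simplify = FALSE))
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- vector("list", B)
    k <- 0L
    while (k < B) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        k <- k + 1L
        out[[k]] <- cand
      }
    }
    out
  })
}

#' Permutation null distribution of the SAM statistic
#'
#' For B balanced re-labelings of the samples (sampled without replacement
#' from all distinct assignments, or enumerated exhaustively when fewer
#' than B exist), computes the sorted statistic per permutation and the
#' expected order statistics `dbar_(i)` (means across permutations).
#'
#' @param matrix gene x sample matrix.
#' @param labels per-sample condition labels.
#' @param B requested number of permutations.
#' @param seed seed for the permutation draw.
#' @param s0 fudge constant (use the observed-data choice).
#' @return list with `dbar` (expected order statistics, ascending) and
#'   `perm_d` (gene x permutation matrix of sorted statistics).
#' @export
permutation_null <- function(matrix, labels, B = 100L, seed = 1L, s0 = 0) {
  idx <- check_groups(labels)
  n <- length(labels)
  n1 <- length(idx$uc)
  splits <- balanced_splits(n, n1, B, seed)
  perm_d <- vapply(splits, function(uc_idx) {
    lab <- rep("CRC", n)
    lab[uc_idx] <- "UC"
    sort(sam_statistic(matrix, lab, s0)$d)
  }, numeric(nrow(matrix)))
  list(dbar = rowMeans(perm_d), perm_d = perm_d,
       iqr = unname(stats::quantile(perm_d, c(0.25, 0.75))))
}

# cut-points for one delta: scanning outward from the center of the ranked
# statistics, the first rank where d_(i) - dbar_(i) exceeds delta (above)
# or falls below -delta (below)
sam_cutpoints <- function(d_sorted, dbar, delta) {
  diff <- d_sorted - dbar
  center <- which.min(abs(dbar))
  up_idx <- which(diff > delta & seq_along(diff) >= center)
  lo_idx <- which(diff < -delta & seq_along(diff) <= center)
  list(cut_up = if (length(up_idx)) d_sorted[min(up_idx)] else Inf,
       cut_low = if (length(lo_idx)) d_sorted[max(lo_idx)] else -Inf)
}

#' Delta-based significance calling with permutation FDR
#'
#' Genes beyond the delta cut-points are called. The estimated FDR at a
#' cut is `pihat0 * median_b(#permuted d beyond cuts) / #called`, where
#' `pihat0 = min(1, #observed d inside the permutation interquartile range
#' / (0.5 * m))`. With zero called genes the FDR is 0 by convention and a
#' flag is set.
#'
#' @param d observed per-gene statistics.
#' @param null result of [permutation_null()].
#' @param delta half-width of the calling band on the quantile-quantile
#'   plot.
#' @param target_fdr target FDR (recorded; calling itself uses `delta`).
#' @return list with `called` (logical, in gene order of `d`), `fdr`
#'   (estimated FDR at this delta), `cut_up`, `cut_low`, `pi0`,
#'   `none_called` flag.
#' @export
call_significant <- function(d, null, delta, target_fdr = 0.05) {
  ord <- order(d)
  cuts <- sam_cutpoints(d[ord], null$dbar, delta)
  called <- d >= cuts$cut_up | d <= cuts$cut_low
  q <- null$iqr %||% unname(stats::quantile(null$perm_d, c(0.25, 0.75)))
  pi0 <- min(1, sum(d > q[1] & d < q[2]) / (0.5 * length(d)))
  n_called <- sum(called)
  if (n_called == 0) {
    return(list(called = called, fdr = 0, cut_up = cuts$cut_up,
                cut_low = cuts$cut_low, pi0 = pi0, none_called = TRUE))
  }
  false_per_perm <- colSums(null$perm_d >= cuts$cut_up |
                              null$perm_d <= cuts$cut_low)
  fdr <- min(1, pi0 * stats::median(false_per_perm) / n_called)
  list(called = called, fdr = fdr, cut_up = cuts$cut_up,
       cut_low = cuts$cut_low, pi0 = pi0, none_called = FALSE)
}

#' Fold-change filter on log2 data
#'
#' `FC = 2^(mean log2 CRC - mean log2 UC)`; a gene passes when `FC >
#' threshold` or `FC < 1/threshold` (two-sided: up- or down-regulation).
#'
#' @param matrix gene x sample log2 matrix.
#' @param labels per-sample condition labels.
#' @param threshold fold-change ratio (> 1).
#' @return list with `fold_change` and logical `pass`.
#' @export
fold_change_filter <- function(matrix, labels, threshold = 1.2) {
  idx <- check_groups(labels)
  fc <- 2^(rowMeans(matrix[, idx$crc, drop = FALSE]) -
             rowMeans(matrix[, idx$uc, drop = FALSE]))
  list(fold_change = fc, pass = fc > threshold | fc < 1 / threshold)
}

#' Two-class unpaired SAM with delta search and fold-change filter
#'
#' Runs the full screen: statistic, permutation null, smallest delta on a
#' 200-point grid achieving estimated FDR <= target, per-gene `q` (the
#' smallest achievable FDR among grid deltas that call the gene,
#' monotonized), and the fold-change filter. A gene's final `called` flag
#' requires the SAM call at the chosen delta, `q <= target_fdr`, and the
#' fold-change test.
#'
#' @param matrix gene x sample log2 matrix.
#' @param labels per-sample condition labels in `c("UC","CRC")`.
#' @param params a [sam_params()].
#' @return a `DETable` data.frame: `gene`, `d`, `s`, `fold_change`, `q`,
#'   `called`, `direction`; attributes `delta`, `s0`, `fdr`, `pi0`.
#' @export
sam_de <- function(matrix, labels, params = sam_params()) {
  stopifnot(inherits(params, "sam_params"))
  s0 <- params$s0 %||% choose_s0(matrix, labels)
  stat <- sam_statistic(matrix, labels, s0)
  null <- permutation_null(matrix, labels, B = params$n_permutations,
                           seed = params$seed, s0 = s0)
  ord <- order(stat$d)
  dev <- abs(stat$d[ord] - null$dbar)
  grid <- seq(max(dev), 0, length.out = 200)   # large delta -> small delta
  m <- length(stat$d)
  q <- rep(1, m)
  chosen <- NULL
  running_fdr <- Inf
  for (delta in grid) {
    res <- call_significant(stat$d, null, delta, params$target_fdr)
    # per-gene q: best (smallest) FDR of any delta that calls the gene,
    # monotonized so wider bands never look worse
    running_fdr <- if (res$none_called) 0 else res$fdr
    q[res$called] <- pmin(q[res$called], running_fdr)
    if (is.null(chosen) || res$fdr <= params$target_fdr)
      chosen <- c(list(delta = delta), res)
  }
  # chosen ends as the smallest grid delta with FDR <= target (grid runs
  # downward, so the last qualifying delta is the smallest); if none
  # qualifies the largest delta (fewest calls) stands
  best <- chosen
  fcf <- fold_change_filter(matrix, labels, params$fc_threshold)
  called <- best$called & q <= params$target_fdr & fcf$pass
  out <- data.frame(
    gene = rownames(matrix),
    d = unname(stat$d),
    s = unname(stat$s),
    fold_change = unname(fcf$fold_change),
    q = unname(q),
    called = unname(called),
    direction = ifelse(stat$d > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  attr(out, "delta") <- best$delta
  attr(out, "s0") <- s0
  attr(out, "fdr") <- best$fdr
  attr(out, "pi0") <- best$pi0
  class(out) <- c("DETable", "data.frame")
  out
}
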