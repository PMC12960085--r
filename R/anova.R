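# orthonormal contrast matrix: k x (k-1), columns orthonormal and orthogonal
# to the unit vector
.ortho_contrasts <- function(k) {
  Q <- stats::contr.helmert(k)
  Q %*% diag(1 / sqrt(colSums(Q^2)), ncol(Q), ncol(Q))
}

# Greenhouse-Geisser epsilon for an effect with orthonormal contrast matrix C
# applied to the sample covariance S of the repeated measures
.gg_epsilon <- function(S, C) {
  M <- t(C) %*% S %*% C
  d <- ncol(C)
  tr <- sum(diag(M))
  tr2 <- sum(M * t(M))
  if (tr2 <= 0) return(1)
  max(1 / d, min(1, tr^2 / (d * tr2)))
}

.effect_row <- function(effect, ss, df1, ss_err, df2, eps) {
  # classify numerically-zero sums of squares relative to the effect scale,
  # so exactly-additive designs give F = Inf rather than an arbitrary huge
  # ratio of rounding residue
  scale <- ss + ss_err
  f <- if (ss <= 1e-12 * scale || scale == 0) 0
       else if (ss_err <= 1e-12 * scale) Inf
       else (ss / df1) / (ss_err / df2)
  p <- if (is.infinite(f)) 0 else
    stats::pf(f, df1, df2, lower.tail = FALSE)
  p_gg <- if (is.infinite(f)) 0 else
    stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  data.frame(effect = effect, ss = ss, df1 = df1, df2 = df2, F = f,
             epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
             p = p, p_gg = p_gg, stringsAsFactors = FALSE)
}

.pairwise_paired <- function(Y, labels, family_size) {
  k <- ncol(Y)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- Y[, i1] - Y[, i2]
    if (stats::sd(d) == 0) {
      return(data.frame(a = labels[i1], b = labels[i2], t = NA_real_,
                        df = length(d) - 1, p = NA_real_,
                        p_bonferroni = NA_real_, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(Y[, i1], Y[, i2], paired = TRUE)
    data.frame(a = labels[i1], b = labels[i2], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * family_size),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One-way within-subjects ANOVA on a complete subjects-by-conditions
#' matrix, or a two-way fully within-subjects ANOVA when a second (e.g.
#' measure: uncorrected vs corrected VO2) factor is supplied. Each effect's
#' degrees of freedom are Greenhouse-Geisser corrected using the epsilon
#' estimated from the sample covariance matrix of the repeated measures
#' (epsilon is 1 by construction for two-level effects). Pairwise follow-up
#' paired t tests are Bonferroni-adjusted within each family.
#'
#' @param values Numeric matrix, subjects in rows. One-way: one column per
#'   condition. Two-way: one column per condition-by-measure cell, measure
#'   varying slowest (all conditions of measure 1, then all of measure 2).
#' @param second_factor Optional vector of length `ncol(values)` giving the
#'   measure level of each column (exactly 2 levels); `NULL` for one-way.
#' @param condition_names Optional condition labels.
#' @return An `rm_anova` object: `effects` (per-effect sums of squares,
#'   uncorrected and GG-corrected df, F, epsilon, p values) and `pairwise`
#'   (Bonferroni-adjusted paired comparisons).
#' @export
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(30), 10, 3) + rep(c(0, 0.5, 1), each = 10)
#' rm_anova(y)
rm_anova <- function(values, second_factor = NULL, condition_names = NULL) {
  Y <- as.matrix(values)
  if (anyNA(Y)) vc_stop("incomplete_design", "missing cells in the design")
  n <- nrow(Y)
  if (n < 3) vc_stop("insufficient_data", "need at least 3 subjects")

  if (is.null(second_factor)) {
    k <- ncol(Y)
    if (k < 2) vc_stop("domain_error", "need at least 2 conditions")
    labels <- condition_names %||% colnames(Y) %||% paste0("c", seq_len(k))
    gm <- mean(Y)
    ss_cond <- n * sum((colMeans(Y) - gm)^2)
    # error SS from the residual matrix directly (never negative)
    R <- Y - outer(rowMeans(Y), rep(1, k)) - outer(rep(1, n), colMeans(Y)) + gm
    ss_err <- sum(R^2)
    eps <- .gg_epsilon(stats::var(Y), .ortho_contrasts(k))
    effects <- .effect_row("condition", ss_cond, k - 1, ss_err,
                           (k - 1) * (n - 1), eps)
    pairwise <- .pairwise_paired(Y, labels, choose(k, 2))
    return(structure(list(effects = effects, pairwise = pairwise,
                          design = "one-way"),
                     class = "rm_anova"))
  }

  second_factor <- as.factor(second_factor)
  if (nlevels(second_factor) != 2 || length(second_factor) != ncol(Y)) {
    vc_stop("domain_error",
            "second_factor must assign each column one of exactly 2 levels")
  }
  b_lev <- levels(second_factor)
  a <- sum(second_factor == b_lev[1])
  if (a != sum(second_factor == b_lev[2])) {
    vc_stop("incomplete_design", "unequal conditions across measure levels")
  }
  # reorder columns: measure slowest, condition fastest
  ord <- order(second_factor)
  Y <- Y[, ord, drop = FALSE]
  labels <- condition_names %||% paste0("c", seq_len(a))
  b <- 2L
  gm <- mean(Y)
  idx_a <- rep(seq_len(a), times = b)
  idx_b <- rep(seq_len(b), each = a)
  m_a <- tapply(colMeans(Y), idx_a, mean)
  m_b <- tapply(colMeans(Y), idx_b, mean)
  m_ab <- colMeans(Y)
  m_i <- rowMeans(Y)
  m_ia <- sapply(seq_len(a), function(j) rowMeans(Y[, idx_a == j, drop = FALSE]))
  m_ib <- sapply(seq_len(b), function(j) rowMeans(Y[, idx_b == j, drop = FALSE]))

  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - m_a[idx_a] - m_b[idx_b] + gm)^2)
  ss_s <- a * b * sum((m_i - gm)^2)
  ss_as <- b * sum((m_ia - outer(m_i, rep(1, a)) -
                      outer(rep(1, n), m_a) + gm)^2)
  ss_bs <- a * sum((m_ib - outer(m_i, rep(1, b)) -
                      outer(rep(1, n), m_b) + gm)^2)
  ss_abs <- sum((Y - gm)^2) - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)

  S <- stats::var(Y)
  Qa <- .ortho_contrasts(a)
  Qb <- .ortho_contrasts(b)
  ua <- matrix(1 / sqrt(a), a, 1)
  ub <- matrix(1 / sqrt(b), b, 1)
  eps_a <- .gg_epsilon(S, kronecker(ub, Qa))
  eps_b <- 1  # two-level effect: sphericity holds by construction
  eps_ab <- .gg_epsilon(S, kronecker(Qb, Qa))

  effects <- rbind(
    .effect_row("condition", ss_a, a - 1, ss_as, (a - 1) * (n - 1), eps_a),
    .effect_row("measure", ss_b, b - 1, ss_bs, (b - 1) * (n - 1), eps_b),
    .effect_row("condition:measure", ss_ab, (a - 1) * (b - 1), ss_abs,
                (a - 1) * (b - 1) * (n - 1), eps_ab))

  # follow-ups: measures within each condition, and conditions within each
  # measure; Bonferroni within each family
  fam1 <- do.call(rbind, lapply(seq_len(a), function(j) {
    d <- Y[, idx_a == j & idx_b == 1] - Y[, idx_a == j & idx_b == 2]
    if (stats::sd(d) == 0) {
      return(data.frame(family = "measure_within_condition",
                        at = labels[j], a = b_lev[1], b = b_lev[2],
                        t = NA_real_, df = n - 1, p = NA_real_,
                        p_bonferroni = NA_real_, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(Y[, idx_a == j & idx_b == 1],
                        Y[, idx_a == j & idx_b == 2], paired = TRUE)
    data.frame(family = "measure_within_condition", at = labels[j],
               a = b_lev[1], b = b_lev[2], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * a),
               stringsAsFactors = FALSE)
  }))
  fam2 <- do.call(rbind, lapply(seq_len(b), function(j) {
    pw <- .pairwise_paired(Y[, idx_b == j, drop = FALSE], labels, choose(a, 2))
    cbind(family = "condition_within_measure", at = b_lev[j], pw,
          stringsAsFactors = FALSE)
  }))
  structure(list(effects = effects, pairwise = rbind(fam1, fam2),
                 design = "two-way"),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s, Greenhouse-Geisser corrected)\n",
              x$design))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-18s F(%.3f, %.3f) = %.3f, eps = %.3f, p = %.4g\n",
                e$effect[i], e$df1_gg[i], e$df2_gg[i], e$F[i], e$epsilon[i],
                e$p_gg[i]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
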