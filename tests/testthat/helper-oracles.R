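# Expect a computed statistic to reproduce a printed (rounded) value:
# within half a unit of the printed last digit, plus the stated transcription
# slack of 1e-3.
expect_printed <- function(computed, printed, digits, slack = 1e-3) {
  expect_lt(abs(computed - printed), 0.5 * 10^(-digits) + slack)
}

# brute-force one-way repeated-measures decomposition (textbook sums of
# squares), independent of the package's implementation
oracle_rm_oneway <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_cond <- ss_err <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(Y[, j]) - gm)^2
  for (i in 1:n) for (j in 1:k) {
    ss_err <- ss_err + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + gm)^2
  }
  scale <- ss_cond + ss_err
  if (ss_cond <= 1e-12 * scale || scale == 0) return(0)
  if (ss_err <= 1e-12 * scale) return(Inf)
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# brute-force paired t from first principles
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  mean(d) / (sd(d) / sqrt(n))
}

# one-way GG epsilon and corrected p via the base-R multivariate route
oracle_mlm_spherical <- function(Y) {
  colnames(Y) <- paste0("c", seq_len(ncol(Y)))
  ml <- stats::lm(Y ~ 1)
  id <- data.frame(cond = factor(seq_len(ncol(Y))))
  av <- stats::anova(ml, M = ~cond, X = ~1, idata = id, test = "Spherical")
  heading <- attr(av, "heading")
  eps_line <- grep("Greenhouse-Geisser epsilon", heading, value = TRUE)
  list(F = av$F[1],
       eps = as.numeric(sub(".*epsilon:\\s*", "", eps_line)),
       p_gg = av[["G-G Pr"]][1])
}

# a small model-true cohort for fast validation tests
make_sim_cohort <- function(n = 20, noise_sd = 0.1, seed = 101) {
  generate_cohort(n, noise_sd = noise_sd, seed = seed)
}
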