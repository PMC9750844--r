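#' IBD-sharing (kappa) models for pairwise kinship
#'
#' The probability that a pair shares 0/1/2 alleles identical by descent at
#' a locus: unrelated U = (1, 0, 0), parent-offspring PO = (0, 1, 0), full
#' siblings FS = (0.25, 0.5, 0.25), half siblings HS = (0.5, 0.5, 0).
#'
#' @param name One of `"U"`, `"PO"`, `"FS"`, `"HS"`.
#' @return A list with `name` and `kappa` (numeric length 3, summing to 1).
#' @export
kappa_model <- function(name = c("U", "PO", "FS", "HS")) {
  name <- match.arg(name)
  kappa <- switch(name,
                  U = c(1, 0, 0),
                  PO = c(0, 1, 0),
                  FS = c(0.25, 0.5, 0.25),
                  HS = c(0.5, 0.5, 0))
  list(name = name, kappa = kappa)
}

#' Joint probability of an observed genotype pair at one locus
#'
#' Under a kappa model the true-pair probability decomposes as
#' `k0 P(G1) P(G2) + k1 P(G1) T(G2 | G1) + k2 P(G1) 1[G1 = G2]`, with
#' `P(.)` Hardy-Weinberg probabilities and `T(G2 | G1)` the probability
#' that G2 consists of one allele drawn uniformly from G1's two alleles
#' plus one independent draw from the population. With genotyping error
#' rate `mu` (independent whole-genotype replacement by a Hardy-Weinberg
#' draw in each member), the observed-pair probability is the mixture
#' `(1 - mu)^2 P_true + (1 - (1 - mu)^2) P(G1) P(G2)`.
#'
#' @param g1,g2 Unordered genotypes: length-2 vectors of allele names (or
#'   indices into `freqs`).
#' @param freqs Allele-frequency vector at the locus (a simplex; named if
#'   genotypes are given as names).
#' @param kappa A [kappa_model()] (or its name).
#' @param error_rate Whole-genotype error rate `mu`.
#' @return The probability (a scalar).
#' @export
joint_genotype_prob <- function(g1, g2, freqs, kappa, error_rate = 0) {
  if (is.character(kappa)) kappa <- kappa_model(kappa)
  if (is.character(g1)) {
    g1 <- match(g1, names(freqs)); g2 <- match(g2, names(freqs))
  }
  if (anyNA(g1) || anyNA(g2) ||
      any(c(g1, g2) < 1) || any(c(g1, g2) > length(freqs))) {
    stop("genotype allele outside the frequency support")
  }
  v <- .pair_prob_vec(g1[1], g1[2], g2[1], g2[2], freqs, kappa$kappa,
                      error_rate)
  as.numeric(v)
}

# vectorized observed-pair probability; a1,a2,b1,b2 are equal-length integer
# vectors of allele indices, p the frequency vector
.pair_prob_vec <- function(a1, a2, b1, b2, p, kappa, mu) {
  hwe <- function(x, y) ifelse(x == y, p[x]^2, 2 * p[x] * p[y])
  P1 <- hwe(a1, a2); P2 <- hwe(b1, b2)
  f <- function(x) ifelse(b1 == b2, (x == b1) * p[b1],
                          (x == b1) * p[b2] + (x == b2) * p[b1])
  Tt <- 0.5 * (f(a1) + f(a2))
  eq <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
  ptrue <- kappa[1] * P1 * P2 + kappa[2] * P1 * Tt + kappa[3] * P1 * eq
  keep <- (1 - mu)^2
  keep * ptrue + (1 - keep) * P1 * P2
}

#' Monte-Carlo ensemble of kinship log-likelihood ratios
#'
#' Simulates genotype pairs under `true_kappa` (via
#' [simulate_kin_pairs()]) and computes, for each pair, the summed per-locus
#' log-likelihood ratio `Lambda = sum_l ln P(G1, G2 | numerator) /
#' P(G1, G2 | U)`, using the same error rate in simulation and in both
#' probabilities. Loci where either member is missing are skipped.
#'
#' @param freqs List per locus of allele-frequency vectors.
#' @param true_kappa Relationship the pairs are simulated under (name).
#' @param numerator_kappa Relationship in the numerator of the ratio.
#' @param n_sim Number of simulated pairs.
#' @param error_rate Whole-genotype error rate `mu`.
#' @param seed Integer seed.
#' @return A list of class `gt_lr_ensemble`: `lambda` (numeric `n_sim`),
#'   `true_kappa`, `numerator_kappa`, `error_rate`, `n_loci`.
#' @export
lr_ensemble <- function(freqs, true_kappa, numerator_kappa, n_sim = 1000,
                        error_rate = 0, seed = NULL) {
  pairs <- simulate_kin_pairs(true_kappa, n_sim, freqs,
                              error_rate = error_rate, seed = seed)
  lambda <- pair_loglik_ratio(pairs$g1, pairs$g2, freqs,
                              numerator_kappa, error_rate)
  structure(list(lambda = lambda, true_kappa = true_kappa,
                 numerator_kappa = numerator_kappa, error_rate = error_rate,
                 n_loci = length(freqs)),
            class = "gt_lr_ensemble")
}

#' Log-likelihood ratio of a kinship hypothesis against unrelated
#'
#' @param g1,g2 Genotype sets: lists with integer matrices `a1`, `a2`
#'   (pairs x loci) of allele indices into `freqs`.
#' @param freqs List per locus of allele-frequency vectors.
#' @param numerator_kappa Hypothesis name for the numerator.
#' @param error_rate Whole-genotype error rate used in both densities.
#' @return Numeric vector of `Lambda` values, one per pair; loci missing in
#'   either member contribute 0.
#' @export
pair_loglik_ratio <- function(g1, g2, freqs, numerator_kappa,
                              error_rate = 0) {
  kap <- kappa_model(numerator_kappa)$kappa
  n <- nrow(g1$a1)
  lambda <- numeric(n)
  keep <- (1 - error_rate)^2
  for (l in seq_along(freqs)) {
    p <- freqs[[l]]
    a1 <- g1$a1[, l]; a2 <- g1$a2[, l]
    b1 <- g2$a1[, l]; b2 <- g2$a2[, l]
    ok <- !(is.na(a1) | is.na(b1))
    if (!any(ok)) next
    num <- .pair_prob_vec(a1[ok], a2[ok], b1[ok], b2[ok], p, kap, error_rate)
    hwe <- function(x, y) ifelse(x == y, p[x]^2, 2 * p[x] * p[y])
    den <- hwe(a1[ok], a2[ok]) * hwe(b1[ok], b2[ok])
    lambda[ok] <- lambda[ok] + log(num) - log(den)
  }
  lambda
}

#' False-positive rate at fixed false-negative rates
#'
#' For a kinship hypothesis `K`, the decision threshold at a false-negative
#' rate `f` is the empirical `f`-quantile `lambda*` of `Lambda` simulated
#' under `K`. The false-positive rate (probability an unrelated pair scores
#' `Lambda >= lambda*`) is estimated either by importance sampling --
#' `FPR = mean over K-draws of exp(-Lambda) 1[Lambda >= lambda*]`, valid
#' because `Lambda` is exactly the log density ratio between `K` and `U`,
#' which makes rates of order 1e-18 estimable with modest draws -- or by
#' direct Monte Carlo over `U`-simulated pairs. Monte-Carlo standard errors
#' are reported; a direct estimate with zero exceedances reports the upper
#' bound `3 / n_sim` with a flag.
#'
#' @param freqs List per locus of allele-frequency vectors.
#' @param hypothesis `"PO"`, `"FS"`, or `"HS"` (not `"U"`).
#' @param fnr_grid False-negative rates at which to set thresholds.
#' @param n_sim Simulated pairs per ensemble.
#' @param error_rate Whole-genotype error rate `mu`.
#' @param method `"importance"` (default) or `"direct"`.
#' @param seed Integer seed.
#' @return A tibble of class `gt_fpr_table`: per FNR, `lambda_star`, `fpr`,
#'   `se`, `n_sim`, `method`, `zero_exceedance` flag.
#' @export
fpr_at_fnr <- function(freqs, hypothesis = c("FS", "PO", "HS"),
                       fnr_grid = seq(0.01, 0.10, by = 0.01),
                       n_sim = 10000, error_rate = 0,
                       method = c("importance", "direct"), seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  ens_k <- lr_ensemble(freqs, hypothesis, hypothesis, n_sim,
                       error_rate = error_rate)
  lam_k <- ens_k$lambda
  lam_u <- NULL
  if (method == "direct") {
    lam_u <- lr_ensemble(freqs, "U", hypothesis, n_sim,
                         error_rate = error_rate)$lambda
  }
  rows <- lapply(fnr_grid, function(f) {
    lstar <- stats::quantile(lam_k, probs = f, type = 1, names = FALSE)
    if (method == "importance") {
      w <- exp(-lam_k) * (lam_k >= lstar)
      fpr <- mean(w)
      se <- stats::sd(w) / sqrt(n_sim)
      flag <- FALSE
    } else {
      hits <- sum(lam_u >= lstar)
      fpr <- hits / n_sim
      se <- sqrt(fpr * (1 - fpr) / n_sim)
      flag <- hits == 0
      if (flag) fpr <- 3 / n_sim
    }
    tibble::tibble(hypothesis = hypothesis, fnr = f, lambda_star = lstar,
                   fpr = fpr, se = se, n_sim = n_sim, method = method,
                   zero_exceedance = flag)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gt_fpr_table", class(out))
  out
}

#' Observed allele frequencies from a baseline
#'
#' Sample allele proportions per marker, pooled or within one group --
#' the frequency input expected by the kinship simulators.
#'
#' @param baseline A [gt_baseline()].
#' @param group Optional single group name; `NULL` pools all individuals.
#' @param group_by Grouping column used when `group` is given.
#' @param drop_unobserved Drop alleles never observed (default `TRUE`; the
#'   simulators require only that frequencies sum to 1).
#' @return A named list per marker of named frequency vectors.
#' @export
baseline_frequencies <- function(baseline, group = NULL,
                                 group_by = c("lake", "collection",
                                              "reporting_unit"),
                                 drop_unobserved = TRUE) {
  group_by <- match.arg(group_by)
  ac <- allele_counts(baseline,
                      if (is.null(group)) "pooled" else group_by)
  gi <- if (is.null(group)) 1 else match(group, ac$groups)
  if (is.na(gi)) stop("unknown group: ", group)
  out <- lapply(ac$counts, function(x) {
    v <- x[gi, ]
    if (sum(v) == 0) return(NULL)
    p <- v / sum(v)
    if (drop_unobserved) p <- p[p > 0]
    p
  })
  names(out) <- baseline$markers$marker_id
  out[!vapply(out, is.null, logical(1))]
}
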