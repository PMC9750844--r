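#' Per-collection, per-marker diversity summary
#'
#' Computes, for every (group, marker) cell: the number of genotyped
#' individuals `n`, observed allele count, observed heterozygosity `Ho`,
#' Nei's unbiased gene diversity `Hs = (2n/(2n-1)) (1 - sum p^2)`, effective
#' number of alleles `Ae = 1 / sum p^2`, Nei's inbreeding coefficient
#' `Gis = 1 - Ho/Hs`, and (optionally) a permutation p-value for departure
#' from Hardy-Weinberg equilibrium. Monomorphic cells report
#' `Ho = Hs = 0`, `Ae = 1`, `Gis = NA`; empty cells report `NA` throughout.
#'
#' @param baseline A [gt_baseline()].
#' @param group_by Grouping column (`"collection"` default) or `"pooled"`.
#' @param n_perm Permutations for the HWE test per cell (0 = skip, the
#'   default; the test shuffles gene copies among individuals).
#' @param hwe_direction Passed to [hwe_permutation_test()].
#' @return A tibble with one row per (group, marker).
#' @export
diversity <- function(baseline,
                      group_by = c("collection", "reporting_unit", "lake",
                                   "pooled"),
                      n_perm = 0, hwe_direction = "deficit") {
  group_by <- match.arg(group_by)
  ac <- allele_counts(baseline, group_by)
  r <- length(ac$groups); m <- n_markers(baseline)
  res <- vector("list", m)
  for (j in seq_len(m)) {
    x <- ac$counts[[j]]
    n <- ac$n_ind[, j]
    nhet <- rowSums(ac$het_counts[[j]]) / 2
    p <- x / pmax(2 * n, 1)
    sump2 <- rowSums(p^2)
    k_obs <- rowSums(x > 0)
    ho <- ifelse(n > 0, nhet / n, NA_real_)
    hs <- ifelse(n > 0, (2 * n / pmax(2 * n - 1, 1)) * (1 - sump2), NA_real_)
    ae <- ifelse(n > 0, 1 / sump2, NA_real_)
    gis <- ifelse(n > 0 & hs > 0, 1 - ho / hs, NA_real_)
    mono <- n > 0 & k_obs <= 1
    ho[mono] <- 0; hs[mono] <- 0; ae[mono] <- 1; gis[mono] <- NA_real_
    res[[j]] <- tibble::tibble(
      group = ac$groups, marker_id = baseline$markers$marker_id[j],
      kind = baseline$markers$kind[j],
      n = as.integer(n), n_alleles = as.integer(k_obs),
      Ho = ho, Hs = hs, Ae = ae, Gis = gis
    )
  }
  out <- dplyr::bind_rows(res)
  if (n_perm > 0) {
    g <- if (group_by == "pooled") rep("pooled", n_individuals(baseline))
         else baseline$samples[[group_by]]
    out$hwe_p <- NA_real_
    for (j in seq_len(m)) {
      for (gr in ac$groups) {
        sel <- g == gr
        row <- out$group == gr & out$marker_id == baseline$markers$marker_id[j]
        out$hwe_p[row] <- hwe_permutation_test(
          baseline$a1[sel, j], baseline$a2[sel, j],
          n_perm = n_perm, direction = hwe_direction)
      }
    }
  }
  out
}

#' Permutation test for Hardy-Weinberg equilibrium
#'
#' The test statistic is Nei's `Gis`; the null distribution is built by
#' shuffling gene copies among individuals within the group. Because
#' shuffling leaves the allele frequencies (hence `Hs`) unchanged, the
#' deficit-direction tail `perm Gis >= observed` is equivalent to
#' `perm Ho <= observed Ho`. The observed configuration is included in the
#' null set, so `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param a1,a2 Allele vectors (integer indices or strings) for one marker
#'   in one group; `NA` pairs are dropped.
#' @param n_perm Number of permutations.
#' @param direction `"deficit"` (heterozygote deficit, `Gis > 0`),
#'   `"excess"`, or `"two_sided"` (double the smaller tail, capped at 1).
#' @param seed Optional seed for the permutations.
#' @return A p-value. Monomorphic or unscorable input returns 1.
#' @export
hwe_permutation_test <- function(a1, a2, n_perm = 999,
                                 direction = c("deficit", "excess",
                                               "two_sided"),
                                 seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) return(1)
  copies <- c(a1, a2)
  if (length(unique(copies)) < 2) return(1)
  ho_obs <- mean(a1 != a2)
  ho_perm <- vapply(seq_len(n_perm), function(i) {
    s <- sample(copies)
    mean(s[seq_len(n)] != s[n + seq_len(n)])
  }, numeric(1))
  p_def <- (1 + sum(ho_perm <= ho_obs)) / (n_perm + 1)
  p_exc <- (1 + sum(ho_perm >= ho_obs)) / (n_perm + 1)
  switch(direction,
         deficit = p_def,
         excess = p_exc,
         two_sided = min(1, 2 * min(p_def, p_exc)))
}

#' Weir-Cockerham F-statistics
#'
#' Multiallelic theta from the 1984 variance components: for each allele at
#' each locus, `a` (among groups), `b` (among individuals within groups),
#' and `c` (within individuals) are computed and summed over alleles;
#' per-locus `theta = sum(a) / sum(a + b + c)` and the multi-locus estimate
#' is the ratio of components summed over loci (negative per-locus values
#' are retained, not truncated). Markers monomorphic across all groups
#' contribute zero components and drop out of the ratio. An optional
#' bootstrap over loci gives a percentile confidence interval, and
#' `pairwise = TRUE` adds the matrix of two-group estimates.
#'
#' @param baseline A [gt_baseline()].
#' @param group_by Grouping column of the sample metadata.
#' @param pairwise If `TRUE`, also compute the pairwise group matrix.
#' @param n_boot Bootstrap replicates over loci for the 95% CI (0 = none).
#' @param seed Optional seed for the bootstrap.
#' @return A list of class `gt_fst`: `theta` (multi-locus), `per_locus`
#'   tibble (`marker_id`, `a`, `abc`, `theta`), `ci` (length-2 vector or
#'   `NULL`), `pairwise` (symmetric matrix or `NULL`), `groups`.
#' @export
wc_fst <- function(baseline,
                   group_by = c("collection", "reporting_unit", "lake"),
                   pairwise = FALSE, n_boot = 0, seed = NULL) {
  group_by <- match.arg(group_by)
  ac <- allele_counts(baseline, group_by)
  if (length(ac$groups) < 2) stop("need >= 2 groups for differentiation")
  comp <- .wc_components(ac)
  theta <- sum(comp$a) / sum(comp$abc)
  per_locus <- tibble::tibble(
    marker_id = baseline$markers$marker_id,
    a = comp$a, abc = comp$abc,
    theta = ifelse(comp$abc != 0, comp$a / comp$abc, NA_real_)
  )
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- length(comp$a)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(m, m, replace = TRUE)
      sum(comp$a[i]) / sum(comp$abc[i])
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
  }
  pw <- NULL
  if (pairwise) {
    gs <- ac$groups
    pw <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
    for (i in seq_along(gs)[-length(gs)]) {
      for (k in seq((i + 1), length(gs))) {
        sub <- list(groups = gs[c(i, k)],
                    counts = lapply(ac$counts, function(x) x[c(i, k), , drop = FALSE]),
                    het_counts = lapply(ac$het_counts,
                                        function(x) x[c(i, k), , drop = FALSE]),
                    n_ind = ac$n_ind[c(i, k), , drop = FALSE])
        cc <- .wc_components(sub)
        pw[i, k] <- pw[k, i] <- sum(cc$a) / sum(cc$abc)
      }
    }
  }
  structure(list(theta = theta, per_locus = per_locus, ci = ci,
                 pairwise = pw, groups = ac$groups),
            class = "gt_fst")
}

# per-locus summed variance components from an allele_counts() list
.wc_components <- function(ac) {
  m <- length(ac$counts)
  a_out <- numeric(m); abc_out <- numeric(m)
  for (j in seq_len(m)) {
    x <- ac$counts[[j]]
    hx <- ac$het_counts[[j]]
    n_i <- ac$n_ind[, j]
    use <- n_i > 0
    r <- sum(use)
    if (r < 2) next
    n_i <- n_i[use]
    x <- x[use, , drop = FALSE]; hx <- hx[use, , drop = FALSE]
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    p <- x / (2 * n_i)
    h <- hx / n_i
    pbar <- colSums(n_i * p) / (r * nbar)
    s2 <- colSums(n_i * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
    hbar <- colSums(n_i * h) / (r * nbar)
    a_c <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_c <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_c <- hbar / 2
    poly <- pbar > 0 & pbar < 1
    a_out[j] <- sum(a_c[poly]); abc_out[j] <- sum((a_c + b_c + c_c)[poly])
  }
  list(a = a_out, abc = abc_out)
}

#' @export
print.gt_fst <- function(x, ...) {
  cat("<gt_fst> multi-locus theta =", format(x$theta, digits = 4), "\n")
  if (!is.null(x$ci)) {
    cat("  95% bootstrap CI over loci: [",
        format(x$ci[1], digits = 4), ", ", format(x$ci[2], digits = 4),
        "]\n", sep = "")
  }
  cat("  groups:", length(x$groups), "; loci:", nrow(x$per_locus), "\n")
  invisible(x)
}

#' Composite linkage disequilibrium (r-squared) among panel SNPs
#'
#' Expands every marker into its constituent SNPs (each character position
#' of a microhaplotype allele string is one SNP), codes unphased dosages
#' 0/1/2 against the first allele's character, and computes the squared
#' Pearson correlation over co-genotyped individuals. Pairs with fewer than
#' `min_n` co-genotyped individuals, or a zero-variance dosage vector, are
#' `NA`. The summary reports the mean r-squared over inter-marker pairs and
#' the fraction of SNPs whose maximum inter-marker r-squared exceeds 0.3.
#'
#' @param baseline A [gt_baseline()].
#' @param min_n Minimum co-genotyped individuals per pair.
#' @return A list of class `gt_ld`: `r2` (SNP x SNP matrix, same-marker
#'   pairs `NA`), `snp_marker` (marker id per SNP column), `mean_r2`,
#'   `frac_linked` (share of SNPs with max r2 > 0.3).
#' @export
ld_r2 <- function(baseline, min_n = 10) {
  mk <- baseline$markers
  dos_cols <- list(); owner <- character(0); nm <- character(0)
  for (j in seq_len(nrow(mk))) {
    al <- mk$alleles[[j]]
    w <- nchar(al[1])
    for (k in seq_len(w)) {
      ch <- substr(al, k, k)
      if (length(unique(ch)) < 2) next  # invariant position
      ref <- ch[1]
      d1 <- (ch != ref)[baseline$a1[, j]]
      d2 <- (ch != ref)[baseline$a2[, j]]
      dos_cols[[length(dos_cols) + 1]] <- as.numeric(d1) + as.numeric(d2)
      owner <- c(owner, mk$marker_id[j])
      nm <- c(nm, paste0(mk$marker_id[j], if (w > 1) paste0("_p", k) else ""))
    }
  }
  if (length(dos_cols) < 2) stop("fewer than 2 scorable SNPs")
  D <- do.call(cbind, dos_cols)
  colnames(D) <- nm
  r2 <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))^2
  nco <- crossprod(!is.na(D))
  r2[nco < min_n] <- NA_real_
  diag(r2) <- NA_real_
  same <- outer(owner, owner, "==")
  inter <- r2
  inter[same] <- NA_real_
  max_r2 <- apply(inter, 1, function(z) if (all(is.na(z))) NA_real_
                  else max(z, na.rm = TRUE))
  structure(list(r2 = r2, snp_marker = owner,
                 mean_r2 = mean(inter[upper.tri(inter)], na.rm = TRUE),
                 frac_linked = mean(max_r2 > 0.3, na.rm = TRUE)),
            class = "gt_ld")
}
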