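# Independent oracles and fixture builders shared across the test files.
# The oracles are deliberately scalar, loop-based codings kept separate from
# the package's vectorized implementations.

# Weir-Cockerham (1984) theta components for one locus, coded directly from
# the printed per-allele formulas with explicit loops over groups/alleles.
oracle_wc_onelocus <- function(a1, a2, grp) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]; grp <- as.character(grp[ok])
  gs <- sort(unique(grp))
  r <- length(gs)
  n_i <- vapply(gs, function(g) sum(grp == g), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  A <- 0; B <- 0; C <- 0
  for (al in sort(unique(c(a1, a2)))) {
    p_i <- numeric(r); h_i <- numeric(r)
    for (g in seq_len(r)) {
      sel <- grp == gs[g]
      p_i[g] <- (sum(a1[sel] == al) + sum(a2[sel] == al)) / (2 * n_i[g])
      h_i[g] <- sum(a1[sel] != a2[sel] &
                      (a1[sel] == al | a2[sel] == al)) / n_i[g]
    }
    pbar <- sum(n_i * p_i) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  list(a = A, abc = A + B + C)
}

# Pedigree-enumeration oracle for the joint probability of an unordered
# genotype pair under PO/FS/HS/U: enumerates every ordered parental allele
# configuration and every Mendelian transmission outcome. Independent of the
# kappa decomposition used by the package.
same_geno <- function(x, y) all(sort(x) == sort(y))

oracle_pair_prob <- function(g1, g2, p, rel, mu = 0) {
  A <- length(p)
  hwe <- function(g) if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  ptrue <- 0
  if (rel == "U") {
    ptrue <- hwe(g1) * hwe(g2)
  } else if (rel == "PO") {
    for (m1 in 1:A) for (m2 in 1:A) {
      if (!same_geno(g1, c(m1, m2))) next
      for (f1 in 1:A) for (f2 in 1:A) {
        pm <- p[m1] * p[m2] * p[f1] * p[f2]
        for (i in 1:2) for (j in 1:2) {
          if (same_geno(g2, c(c(m1, m2)[i], c(f1, f2)[j]))) {
            ptrue <- ptrue + pm / 4
          }
        }
      }
    }
  } else if (rel == "FS") {
    for (m1 in 1:A) for (m2 in 1:A) for (f1 in 1:A) for (f2 in 1:A) {
      pm <- p[m1] * p[m2] * p[f1] * p[f2]
      for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
        c1 <- c(c(m1, m2)[i], c(f1, f2)[j])
        c2 <- c(c(m1, m2)[k], c(f1, f2)[l])
        if (same_geno(g1, c1) && same_geno(g2, c2)) {
          ptrue <- ptrue + pm / 16
        }
      }
    }
  } else if (rel == "HS") {
    # shared mother (m1, m2); independent fathers (f1, f2) and (e1, e2)
    for (m1 in 1:A) for (m2 in 1:A) for (f1 in 1:A) for (f2 in 1:A) {
      for (e1 in 1:A) for (e2 in 1:A) {
        pm <- p[m1] * p[m2] * p[f1] * p[f2] * p[e1] * p[e2]
        for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
          c1 <- c(c(m1, m2)[i], c(f1, f2)[j])
          c2 <- c(c(m1, m2)[k], c(e1, e2)[l])
          if (same_geno(g1, c1) && same_geno(g2, c2)) {
            ptrue <- ptrue + pm / 16
          }
        }
      }
    }
  }
  keep <- (1 - mu)^2
  unname(keep * ptrue + (1 - keep) * hwe(g1) * hwe(g2))
}

# all unordered genotypes over A alleles, as index pairs
all_genotypes <- function(A) {
  out <- list()
  for (i in 1:A) for (j in i:A) out[[length(out) + 1]] <- c(i, j)
  out
}

# tiny hand-built baseline: explicit character calls
toy_baseline <- function(calls1, calls2, collection,
                         marker_id = paste0("m", seq_len(ncol(calls1))),
                         reporting_unit = collection, lake = reporting_unit) {
  mk <- gt_markers(marker_id,
                   alleles = lapply(seq_len(ncol(calls1)), function(j) {
                     a <- unique(stats::na.omit(c(calls1[, j], calls2[, j])))
                     if (length(a) < 2) a <- unique(c(a, "A", "C"))[1:2]
                     sort(a)
                   }),
                   permissive = TRUE)
  sm <- gt_samples(sprintf("i%03d", seq_len(nrow(calls1))), collection,
                   reporting_unit, lake)
  gt_baseline(mk, sm, calls1, calls2)
}

# introduce whole-genotype errors into a baseline: each called genotype is
# replaced, with probability rate, by an HWE draw from the pooled sample
# frequencies (the package's genotyping error model)
perturb_baseline <- function(baseline, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ac <- allele_counts(baseline, "pooled")
  for (j in seq_len(n_markers(baseline))) {
    p <- ac$counts[[j]][1, ]
    p <- p / sum(p)
    ok <- which(!is.na(baseline$a1[, j]))
    err <- ok[stats::runif(length(ok)) < rate]
    if (length(err)) {
      baseline$a1[err, j] <- sample(seq_along(p), length(err),
                                    replace = TRUE, prob = p)
      baseline$a2[err, j] <- sample(seq_along(p), length(err),
                                    replace = TRUE, prob = p)
    }
  }
  baseline
}
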