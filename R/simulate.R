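#' Simulate a hierarchically structured genotype baseline
#'
#' Generates a truth-known multi-population baseline under a two-level
#' Balding-Nichols model. Ancestral allele frequencies are drawn per marker
#' (biallelic SNPs with minor allele frequency uniform on `maf_range`;
#' microhaplotypes with a symmetric Dirichlet(1) over `A` alleles, `A`
#' uniform on `mhap_allele_range`). Lake frequencies are Dirichlet with
#' concentration `ancestral * (1 - f_lake) / f_lake`, collection frequencies
#' Dirichlet with concentration `lake * (1 - f_coll) / f_coll`, so the
#' expected Weir-Cockerham differentiation at each level equals the
#' configured `F`. Genotypes are drawn under Hardy-Weinberg equilibrium
#' within collections and masked missing independently at `missing_rate`.
#'
#' Defaults emulate a Great Lakes walleye-style survey: 5 lakes x 6
#' collections, moderate hierarchical structure, ~500 loci of which ~40% are
#' microhaplotypes, and ~10% missing calls.
#'
#' @param n_lakes,collections_per_lake Hierarchy shape.
#' @param f_lake,f_coll Differentiation of lakes from the ancestral pool and
#'   of collections from their lake, each in `[0, 1)`. `0` is handled as the
#'   exact limit (child frequencies equal parent frequencies).
#' @param n_per_collection Individuals per collection; scalar or a vector
#'   recycled over collections.
#' @param n_snp,n_mhap Marker counts by kind.
#' @param mhap_allele_range Integer range of microhaplotype allele counts.
#' @param maf_range SNP ancestral minor-allele-frequency range.
#' @param missing_rate Independent per-call missingness probability.
#' @param seed Integer seed; fixed seed fully determines the output.
#' @return A list: `baseline` (a [gt_baseline()]) and `truth`, itself a list
#'   of `ancestral`, `lake`, and `collection` allele-frequency tables (per
#'   marker: named vector / group x allele matrices).
#' @export
simulate_baseline <- function(n_lakes = 5, collections_per_lake = 6,
                              f_lake = 0.08, f_coll = 0.02,
                              n_per_collection = 40,
                              n_snp = 300, n_mhap = 200,
                              mhap_allele_range = c(2, 10),
                              maf_range = c(0.05, 0.5),
                              missing_rate = 0.1, seed = NULL) {
  stopifnot(f_lake >= 0, f_lake < 1, f_coll >= 0, f_coll < 1,
            missing_rate >= 0, missing_rate < 1,
            n_lakes >= 1, collections_per_lake >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- n_snp + n_mhap
  kind <- c(rep("snp", n_snp), rep("mhap", n_mhap))

  # ancestral frequencies and marker definitions
  anc <- vector("list", m)
  marker_id <- character(m)
  alleles <- vector("list", m)
  n_snps <- integer(m)
  for (j in seq_len(m)) {
    if (kind[j] == "snp") {
      marker_id[j] <- sprintf("snp_%04d", j)
      alleles[[j]] <- c("A", "C")
      n_snps[j] <- 1L
      maf <- stats::runif(1, maf_range[1], maf_range[2])
      anc[[j]] <- stats::setNames(c(1 - maf, maf), alleles[[j]])
    } else {
      marker_id[j] <- sprintf("mhap_%04d", j)
      A <- sample(seq(mhap_allele_range[1], mhap_allele_range[2]), 1)
      n_snps[j] <- max(2L, ceiling(log2(A)))
      alleles[[j]] <- .haplotype_strings(A, n_snps[j])
      anc[[j]] <- stats::setNames(.rdirichlet(1, rep(1, A))[1, ], alleles[[j]])
    }
  }
  markers <- gt_markers(marker_id, kind = kind, n_snps = n_snps,
                        snp_positions = lapply(n_snps, function(k) {
                          as.integer(round(seq(20, 135, length.out = k)))
                        }),
                        alleles = alleles)

  lakes <- sprintf("lake%02d", seq_len(n_lakes))
  colls <- as.vector(t(outer(lakes, seq_len(collections_per_lake),
                             function(l, c) paste0(l, "_c", c))))
  coll_lake <- rep(lakes, each = collections_per_lake)
  n_c <- rep_len(as.integer(n_per_collection), length(colls))

  lake_fr <- vector("list", m); coll_fr <- vector("list", m)
  for (j in seq_len(m)) {
    p <- anc[[j]]
    lf <- .bn_child(p, f_lake, n_lakes)
    dimnames(lf) <- list(lakes, names(p))
    cf <- matrix(0, length(colls), length(p),
                 dimnames = list(colls, names(p)))
    for (l in seq_len(n_lakes)) {
      rows <- which(coll_lake == lakes[l])
      cf[rows, ] <- .bn_child(lf[l, ], f_coll, length(rows))
    }
    lake_fr[[j]] <- lf; coll_fr[[j]] <- cf
  }

  ind_coll <- rep(seq_along(colls), n_c)
  n <- length(ind_coll)
  samples <- gt_samples(sprintf("ind_%05d", seq_len(n)),
                        collection = colls[ind_coll],
                        reporting_unit = coll_lake[ind_coll],
                        lake = coll_lake[ind_coll])
  a1 <- matrix(NA_integer_, n, m); a2 <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    a1[, j] <- .rcat_rows(coll_fr[[j]], ind_coll)
    a2[, j] <- .rcat_rows(coll_fr[[j]], ind_coll)
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < missing_rate, n, m)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  baseline <- gt_baseline(markers, samples, a1, a2)
  truth <- list(ancestral = stats::setNames(anc, marker_id),
                lake = stats::setNames(lake_fr, marker_id),
                collection = stats::setNames(coll_fr, marker_id))
  list(baseline = baseline, truth = truth)
}

# Balding-Nichols child frequencies: k Dirichlet draws with concentration
# p * (1 - F) / F; F = 0 returns the parent exactly (the limit)
.bn_child <- function(p, f, k) {
  if (f == 0) {
    matrix(rep(p, each = k), k, length(p))
  } else {
    .rdirichlet(k, p * (1 - f) / f)
  }
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  sweep(x, 1, rowSums(x), "/")
}

# distinct haplotype strings of width w over {A,C,G,T}
.haplotype_strings <- function(A, w) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), w))
  labs <- apply(as.matrix(grid), 1, paste0, collapse = "")
  labs[seq_len(A)]
}

# one categorical draw per element of `rows`, probabilities from P[rows[i], ]
.rcat_rows <- function(P, rows) {
  cp <- t(apply(P, 1, cumsum))
  cp[, ncol(cp)] <- 1  # guard against rounding
  u <- stats::runif(length(rows))
  rowSums(u > cp[rows, , drop = FALSE]) + 1L
}

# single categorical sample matrix: n draws from prob vector p
.rcat <- function(n, p) {
  cp <- cumsum(p); cp[length(cp)] <- 1
  findInterval(stats::runif(n), cp) + 1L
}

#' Simulate genotype pairs under a kinship hypothesis
#'
#' Pairs are built by Mendelian descent from simulated parents drawn under
#' Hardy-Weinberg equilibrium at the supplied allele frequencies:
#' parent-offspring (PO) pairs an offspring with one of its two parents,
#' full siblings (FS) share both parents, half siblings (HS) share exactly
#' one, and unrelated (U) pairs are drawn independently. Loci are
#' independent. Each observed genotype is independently replaced, with
#' probability `error_rate`, by a fresh Hardy-Weinberg draw (a
#' whole-genotype error model: the simplest that breaks the "PO pairs always
#' share an allele" exclusion).
#'
#' @param relationship One of `"PO"`, `"FS"`, `"HS"`, `"U"`.
#' @param n_pairs Number of pairs.
#' @param freqs List (one element per locus) of allele-frequency vectors,
#'   each summing to 1.
#' @param error_rate Whole-genotype replacement probability `mu` in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list with `relationship`, and `g1`, `g2`: each a list of
#'   integer allele-index matrices `a1`, `a2` (`n_pairs` x loci).
#' @export
simulate_kin_pairs <- function(relationship = c("PO", "FS", "HS", "U"),
                               n_pairs, freqs, error_rate = 0, seed = NULL) {
  relationship <- match.arg(relationship)
  stopifnot(n_pairs >= 1, error_rate >= 0, error_rate < 1)
  bad <- which(abs(vapply(freqs, sum, numeric(1)) - 1) > 1e-6)
  if (length(bad)) stop("frequencies must sum to 1 per locus (locus ",
                        bad[1], ")")
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  g1a <- g1b <- g2a <- g2b <- matrix(NA_integer_, n_pairs, L)
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    pa <- cbind(.rcat(n_pairs, p), .rcat(n_pairs, p))  # parent 1
    pb <- cbind(.rcat(n_pairs, p), .rcat(n_pairs, p))  # parent 2
    pick <- function(par) par[cbind(seq_len(n_pairs),
                                    sample(1:2, n_pairs, replace = TRUE))]
    if (relationship == "U") {
      g1a[, l] <- .rcat(n_pairs, p); g1b[, l] <- .rcat(n_pairs, p)
      g2a[, l] <- .rcat(n_pairs, p); g2b[, l] <- .rcat(n_pairs, p)
    } else if (relationship == "PO") {
      g1a[, l] <- pa[, 1]; g1b[, l] <- pa[, 2]   # the parent itself
      g2a[, l] <- pick(pa); g2b[, l] <- pick(pb) # its offspring
    } else if (relationship == "FS") {
      g1a[, l] <- pick(pa); g1b[, l] <- pick(pb)
      g2a[, l] <- pick(pa); g2b[, l] <- pick(pb)
    } else { # HS: shared parent pa, independent second parents
      pc <- cbind(.rcat(n_pairs, p), .rcat(n_pairs, p))
      g1a[, l] <- pick(pa); g1b[, l] <- pick(pb)
      g2a[, l] <- pick(pa); g2b[, l] <- pick(pc)
    }
    if (error_rate > 0) {
      for (gg in list(c("g1a", "g1b"), c("g2a", "g2b"))) {
        err <- stats::runif(n_pairs) < error_rate
        if (any(err)) {
          e1 <- .rcat(sum(err), p); e2 <- .rcat(sum(err), p)
          m1 <- get(gg[1]); m2 <- get(gg[2])
          m1[err, l] <- e1; m2[err, l] <- e2
          assign(gg[1], m1); assign(gg[2], m2)
        }
      }
    }
  }
  list(relationship = relationship,
       g1 = list(a1 = g1a, a2 = g1b),
       g2 = list(a1 = g2a, a2 = g2b))
}

#' Simulate a per-run read-count table
#'
#' Emulates the read-depth structure of a multiplexed amplicon run: each
#' marker has a log-normal amplification factor (uneven primer efficiency),
#' each individual a log-normal total depth, primer reads are Poisson with
#' mean `depth * factor / sum(factors)`, probe (on-target) reads binomial
#' with the marker's on-target proportion, and off-target reads Poisson at
#' `off_target_rate` of individual depth.
#'
#' @param individuals Character vector of individual ids (or an integer
#'   count).
#' @param marker_ids Character vector of marker ids (or an integer count).
#' @param mean_depth Mean per-individual total on-panel read depth `D`.
#' @param sigma_marker SD of log amplification factors (0 = perfectly even).
#' @param sigma_indiv SD of log individual depths.
#' @param q On-target (probe/primer) proportion per marker; scalar or
#'   vector.
#' @param off_target_rate Expected off-target reads as a fraction of
#'   individual depth.
#' @param marker_factors Optional fixed amplification factors (recycled to
#'   the marker count), overriding the log-normal draw -- useful for
#'   constructing known over-amplifiers.
#' @param run_id Run label.
#' @param seed Integer seed.
#' @return A [gt_read_counts()] table.
#' @export
simulate_read_counts <- function(individuals, marker_ids,
                                 mean_depth = 5e4,
                                 sigma_marker = 0.7, sigma_indiv = 0.5,
                                 q = 0.8, off_target_rate = 0.1,
                                 marker_factors = NULL,
                                 run_id = "sim", seed = NULL) {
  stopifnot(sigma_marker >= 0, sigma_indiv >= 0,
            all(q >= 0 & q <= 1), off_target_rate >= 0, off_target_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(individuals) && length(individuals) == 1) {
    individuals <- sprintf("ind_%05d", seq_len(individuals))
  }
  if (is.numeric(marker_ids) && length(marker_ids) == 1) {
    marker_ids <- sprintf("mk_%04d", seq_len(marker_ids))
  }
  n <- length(individuals); m <- length(marker_ids)
  q <- rep_len(q, m)
  fac <- if (is.null(marker_factors)) stats::rlnorm(m, 0, sigma_marker)
         else rep_len(marker_factors, m)
  depth <- stats::rlnorm(n, log(mean_depth), sigma_indiv)
  mu <- outer(depth, fac / sum(fac))
  primer <- matrix(stats::rpois(n * m, mu), n, m)
  probe <- matrix(stats::rbinom(n * m, primer, rep(q, each = n)), n, m)
  counts <- tibble::tibble(
    individual_id = rep(individuals, times = m),
    marker_id = rep(marker_ids, each = n),
    primer_reads = as.integer(primer),
    probe_reads = as.integer(probe)
  )
  off <- tibble::tibble(
    individual_id = individuals,
    off_target_reads = stats::rpois(n, depth * off_target_rate)
  )
  gt_read_counts(run_id, counts, off)
}
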