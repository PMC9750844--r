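#' Fit baseline allele-frequency posteriors
#'
#' For every (group, marker, allele): the observed gene-copy count `x`, the
#' group total `n`, and the Dirichlet posterior-mean frequency
#' `p = (x + 1/A) / (n + 1)` under the unit-information prior with `A` the
#' marker's allele count. Every defined allele therefore has positive
#' frequency in every group, including groups where it was never observed
#' (`x = 0, n = 0` gives the uniform prior `p = 1/A`).
#'
#' @param baseline A [gt_baseline()].
#' @param group_by Baseline grouping used as mixture components
#'   (`"collection"` default).
#' @return A list of class `gt_freq_model`: `groups`, `units` (reporting
#'   unit per group), `sizes` (genotyped individuals per group),
#'   `marker_id`, `alleles`, `counts` (list per marker of group x allele
#'   gene-copy counts), `p` and `logp` (posterior means and their logs).
#' @export
fit_frequencies <- function(baseline,
                            group_by = c("collection", "reporting_unit",
                                         "lake")) {
  group_by <- match.arg(group_by)
  ac <- allele_counts(baseline, group_by)
  m <- n_markers(baseline)
  p <- vector("list", m); logp <- vector("list", m)
  for (j in seq_len(m)) {
    x <- ac$counts[[j]]
    A <- ncol(x)
    n <- rowSums(x)
    pj <- (x + 1 / A) / (n + 1)
    p[[j]] <- pj; logp[[j]] <- log(pj)
  }
  map <- unique(baseline$samples[, c(group_by, "reporting_unit")])
  units <- stats::setNames(map$reporting_unit, map[[group_by]])[ac$groups]
  if (group_by != "collection") units <- stats::setNames(ac$groups, ac$groups)
  sizes <- stats::setNames(
    as.integer(table(factor(baseline$samples[[group_by]],
                            levels = ac$groups))), ac$groups)
  structure(list(groups = ac$groups, units = units, sizes = sizes,
                 marker_id = baseline$markers$marker_id,
                 alleles = baseline$markers$alleles,
                 counts = ac$counts, p = p, logp = logp),
            class = "gt_freq_model")
}

#' Per-individual log-likelihood under each baseline group
#'
#' Hardy-Weinberg genotype likelihoods at posterior-mean frequencies:
#' a heterozygote (a, b) contributes `log(2 p_a p_b)`, a homozygote (a, a)
#' `log(p_a^2)`, and a missing locus contributes 0; the per-individual value
#' is the sum over loci. The prior mass guarantees positivity, so values
#' are always finite.
#'
#' @param mixture A [gt_baseline()] of individuals to score (markers matched
#'   to the model by id, alleles by string).
#' @param model A [fit_frequencies()] model.
#' @return A numeric matrix, individuals x groups, of log-likelihoods.
#' @export
genotype_loglik <- function(mixture, model) {
  idx <- .match_to_model(mixture, model)
  .loglik_matrix(idx$a1, idx$a2, model, idx$model_cols)
}

# map mixture calls onto the model's marker order / allele indexing;
# markers absent from the model are dropped, alleles absent from the model's
# allele list are an error (the model defines the support)
.match_to_model <- function(mixture, model) {
  shared <- intersect(mixture$markers$marker_id, model$marker_id)
  if (!length(shared)) stop("no shared markers between mixture and model")
  jm <- match(shared, mixture$markers$marker_id)
  jf <- match(shared, model$marker_id)
  n <- n_individuals(mixture)
  a1 <- matrix(NA_integer_, n, length(shared))
  a2 <- matrix(NA_integer_, n, length(shared))
  for (k in seq_along(shared)) {
    from <- mixture$markers$alleles[[jm[k]]]
    to <- model$alleles[[jf[k]]]
    remap <- match(from, to)
    if (anyNA(remap) &&
        any(stats::na.omit(unique(c(mixture$a1[, jm[k]],
                                    mixture$a2[, jm[k]]))) %in%
            which(is.na(remap)))) {
      stop("marker ", shared[k], ": mixture carries allele(s) outside the ",
           "model's support")
    }
    a1[, k] <- remap[mixture$a1[, jm[k]]]
    a2[, k] <- remap[mixture$a2[, jm[k]]]
  }
  list(a1 = a1, a2 = a2, model_cols = jf)
}

# core log-likelihood accumulation; a1/a2 are integer matrices indexed in
# the model's allele order, columns aligned with model_cols
.loglik_matrix <- function(a1, a2, model, model_cols = seq_along(model$p)) {
  n <- nrow(a1); C <- length(model$groups)
  ll <- matrix(0, n, C, dimnames = list(NULL, model$groups))
  log2_ <- log(2)
  for (k in seq_along(model_cols)) {
    lp <- t(model$logp[[model_cols[k]]])  # A x C
    e1 <- a1[, k]; e2 <- a2[, k]
    ok <- !is.na(e1)
    if (!any(ok)) next
    contrib <- lp[e1[ok], , drop = FALSE] + lp[e2[ok], , drop = FALSE] +
      log2_ * (e1[ok] != e2[ok])
    ll[ok, ] <- ll[ok, ] + contrib
  }
  ll
}

#' EM mixture estimation with posterior membership (pofZ)
#'
#' Fits mixture proportions over baseline groups by
#' expectation-maximization: the E-step computes each individual's posterior
#' membership `pofZ_ib` proportional to `pi_b exp(l_ib)` (stabilized by
#' log-sum-exp), the M-step sets `pi_b` to the mean membership. Iteration
#' stops when `max |delta pi| < tol`. Memberships are aggregated to
#' reporting units, and an individual is assigned to the unit with the
#' largest aggregated membership when that membership exceeds
#' `pofz_threshold` (otherwise it is unassigned).
#'
#' @param mixture A [gt_baseline()] of mixture individuals, or a
#'   precomputed log-likelihood matrix from [genotype_loglik()].
#' @param model A [fit_frequencies()] model.
#' @param tol Convergence tolerance on mixture proportions.
#' @param max_iter Iteration cap (a warning flag is set if reached).
#' @param pofz_threshold Minimum aggregated unit membership for assignment.
#' @return A list of class `gt_mixture`: `pi` (named simplex over groups),
#'   `pofZ` (individuals x groups, rows sum to 1), `unit_pofZ`
#'   (individuals x units), `assignment` (unit or `NA` = unassigned),
#'   `loglik` trace, `converged`, `n_iter`.
#' @export
em_mixture <- function(mixture, model, tol = 1e-8, max_iter = 1000,
                       pofz_threshold = 0.7) {
  ll <- if (is.matrix(mixture)) mixture else genotype_loglik(mixture, model)
  C <- ncol(ll); n <- nrow(ll)
  pi_b <- rep(1 / C, C)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(ll, 2, log(pi_b), "+")
    mx <- apply(lw, 1, max)
    w <- exp(lw - mx)
    rs <- rowSums(w)
    pofz <- w / rs
    trace <- c(trace, sum(mx + log(rs)))
    pi_new <- colMeans(pofz)
    if (max(abs(pi_new - pi_b)) < tol) {
      pi_b <- pi_new; converged <- TRUE; break
    }
    pi_b <- pi_new
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  lw <- sweep(ll, 2, log(pi_b), "+")
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  pofz <- w / rowSums(w)
  colnames(pofz) <- model$groups
  units <- unique(unname(model$units))
  unit_pofz <- sapply(units, function(u) {
    rowSums(pofz[, model$units == u, drop = FALSE])
  })
  if (n == 1) unit_pofz <- matrix(unit_pofz, 1, dimnames = list(NULL, units))
  best <- max.col(unit_pofz, ties.method = "first")
  best_p <- unit_pofz[cbind(seq_len(n), best)]
  assignment <- ifelse(best_p > pofz_threshold, units[best], NA_character_)
  structure(list(pi = stats::setNames(pi_b, model$groups), pofZ = pofz,
                 unit_pofZ = unit_pofz, assignment = assignment,
                 loglik = trace, converged = converged, n_iter = length(trace)),
            class = "gt_mixture")
}

#' 100% leave-one-out mixture simulation
#'
#' Estimates expected assignment accuracy for one reporting unit: in each
#' replicate, `mixture_size` individuals are simulated entirely from the
#' focal unit (source collection drawn proportional to baseline sample
#' size), each genotype built per locus by drawing two gene copies without
#' replacement from the source collection's observed copies. When that
#' individual's likelihood is computed against its own source collection,
#' the drawn copies are subtracted from the baseline counts (gene-copy
#' leave-one-out), so an individual's own alleles never inflate its source
#' likelihood. EM mixture estimation over all collections follows, and
#' accuracy is the fraction of threshold-assigned individuals whose
#' assigned unit is the focal unit.
#'
#' @param baseline A [gt_baseline()].
#' @param focal_unit A reporting unit present in the baseline (default:
#'   all units in turn).
#' @param mixture_size Simulated individuals per replicate.
#' @param n_reps Replicates per unit.
#' @param pofz_threshold Assignment threshold on aggregated unit membership.
#' @param seed Integer seed; fully determines the simulation.
#' @return A list of class `gt_gsi_report`: `summary` (tibble per
#'   (unit, replicate): `accuracy`, `prop_unassigned`, `n_assigned`),
#'   `destinations` (tibble of misassignment counts by destination unit),
#'   `unit_pofZ` (list per (unit, replicate) of retained membership
#'   matrices, for [threshold_sweep()]), `pofz_threshold`.
#' @export
simulate_100pct_loo <- function(baseline, focal_unit = NULL,
                                mixture_size = 200, n_reps = 99,
                                pofz_threshold = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- fit_frequencies(baseline, "collection")
  units <- unique(unname(model$units))
  if (is.null(focal_unit)) focal_unit <- units
  if (!all(focal_unit %in% units)) {
    stop("focal unit(s) not in baseline: ",
         paste(setdiff(focal_unit, units), collapse = ", "))
  }
  m <- length(model$p)
  A <- lengths(model$alleles)
  ncop <- lapply(model$counts, rowSums)
  rows <- list(); dest <- list(); keep_pofz <- list()
  for (fu in focal_unit) {
    src_groups <- which(model$units == fu)
    src_w <- model$sizes[src_groups]
    for (rep_i in seq_len(n_reps)) {
      s <- src_groups[.rcat(mixture_size, src_w / sum(src_w))]
      ll <- matrix(0, mixture_size, length(model$groups))
      for (j in seq_len(m)) {
        X <- model$counts[[j]]
        nj <- ncop[[j]]
        ok <- nj[s] >= 2
        if (!any(ok)) next
        so <- s[ok]
        P1 <- X[so, , drop = FALSE] / nj[so]
        e1 <- .rcat_mat(P1)
        X2 <- X[so, , drop = FALSE]
        X2[cbind(seq_along(so), e1)] <- X2[cbind(seq_along(so), e1)] - 1L
        e2 <- .rcat_mat(X2 / (nj[so] - 1))
        # likelihood vs all groups at full-baseline posterior means
        lp <- t(model$logp[[j]])
        contrib <- lp[e1, , drop = FALSE] + lp[e2, , drop = FALSE] +
          log(2) * (e1 != e2)
        # gene-copy leave-one-out for the own source collection
        x1 <- X[cbind(so, e1)]; x2 <- X[cbind(so, e2)]
        het <- e1 != e2
        own <- ifelse(het,
                      log(2) + log((x1 - 1 + 1 / A[j]) / (nj[so] - 1)) +
                        log((x2 - 1 + 1 / A[j]) / (nj[so] - 1)),
                      2 * (log(pmax(x1 - 2, 0) + 1 / A[j]) -
                             log(nj[so] - 1)))
        contrib[cbind(seq_along(so), so)] <- own
        ll[ok, ] <- ll[ok, ] + contrib
      }
      fit <- em_mixture(ll, model, pofz_threshold = pofz_threshold)
      assigned <- !is.na(fit$assignment)
      acc <- if (any(assigned)) mean(fit$assignment[assigned] == fu)
             else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        unit = fu, replicate = rep_i, accuracy = acc,
        prop_unassigned = mean(!assigned), n_assigned = sum(assigned))
      wrong <- fit$assignment[assigned & fit$assignment != fu]
      if (length(wrong)) {
        dest[[length(dest) + 1]] <- tibble::tibble(
          unit = fu, replicate = rep_i, destination = wrong)
      }
      keep_pofz[[paste(fu, rep_i, sep = "|")]] <- fit$unit_pofZ
    }
  }
  destinations <- if (length(dest)) {
    dplyr::count(dplyr::bind_rows(dest), .data$unit, .data$destination,
                 name = "n")
  } else {
    tibble::tibble(unit = character(0), destination = character(0),
                   n = integer(0))
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 destinations = destinations,
                 unit_pofZ = keep_pofz, pofz_threshold = pofz_threshold),
            class = "gt_gsi_report")
}

# vectorized categorical draw, one per row of a (possibly unnormalized)
# nonnegative weight matrix
.rcat_mat <- function(W) {
  cp <- W %*% upper.tri(diag(ncol(W)), diag = TRUE)
  tot <- cp[, ncol(cp)]
  u <- stats::runif(nrow(W)) * tot
  as.integer(rowSums(u > cp) + 1L)
}

#' @export
print.gt_gsi_report <- function(x, ...) {
  s <- dplyr::summarise(dplyr::group_by(x$summary, .data$unit),
                        mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
                        mean_unassigned = mean(.data$prop_unassigned))
  cat("<gt_gsi_report> pofZ threshold ", x$pofz_threshold, "\n", sep = "")
  print(s)
  invisible(x)
}

#' Re-evaluate assignment accuracy across pofZ thresholds
#'
#' Recomputes assignment accuracy and the unassigned rate from the retained
#' membership matrices of a [simulate_100pct_loo()] run, without
#' re-simulating. Accuracy is non-decreasing and the unassigned rate
#' non-decreasing in the threshold for any fixed membership matrix.
#'
#' @param report A `gt_gsi_report`.
#' @param thresholds Numeric vector of pofZ thresholds.
#' @return A tibble per (unit, threshold): mean `accuracy` and mean
#'   `prop_unassigned` over replicates.
#' @export
threshold_sweep <- function(report, thresholds = seq(0.70, 0.95, by = 0.05)) {
  stopifnot(inherits(report, "gt_gsi_report"))
  rows <- list()
  for (key in names(report$unit_pofZ)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    fu <- parts[1]
    up <- report$unit_pofZ[[key]]
    best <- max.col(up, ties.method = "first")
    best_p <- up[cbind(seq_len(nrow(up)), best)]
    best_u <- colnames(up)[best]
    for (th in thresholds) {
      assigned <- best_p > th
      rows[[length(rows) + 1]] <- tibble::tibble(
        unit = fu, replicate = as.integer(parts[2]), threshold = th,
        accuracy = if (any(assigned)) mean(best_u[assigned] == fu)
                   else NA_real_,
        prop_unassigned = mean(!assigned))
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::summarise(dplyr::group_by(out, .data$unit, .data$threshold),
                   accuracy = mean(.data$accuracy, na.rm = TRUE),
                   prop_unassigned = mean(.data$prop_unassigned),
                   .groups = "drop")
}
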