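#' Shannon equitability of per-marker read counts
#'
#' `H = -sum(p_i log p_i) / log(S)` over the `S` retained markers, with
#' `p_i` each marker's share of the summed primer reads. `H = 1` iff all
#' shares are equal; markers with zero reads stay in `S` (their limiting
#' contribution to the numerator is 0, so they depress evenness through the
#' denominator). Both richness (number of primer pairs retained) and
#' evenness of amplification therefore enter the index, which is why it
#' serves as the primer-pool optimization criterion.
#'
#' @param read_totals Numeric vector of per-marker read totals (>= 2
#'   markers; all-zero input is an error).
#' @return `H` in \[0, 1\].
#' @export
shannon_equitability <- function(read_totals) {
  if (length(read_totals) < 2) stop("need >= 2 markers")
  if (any(read_totals < 0)) stop("read counts must be >= 0")
  tot <- sum(read_totals)
  if (tot == 0) stop("all-zero read counts: H undefined")
  p <- read_totals / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(read_totals))
}

#' Iterative primer-pool optimization by read evenness
#'
#' Emulates the multiplex-balancing loop used across consecutive
#' sequencing runs: at each iteration, markers whose read share exceeds
#' `overamp_factor` times the mean share (overamplifiers) or whose
#' probe/primer on-target proportion falls below `min_on_target` (primer
#' dimers / off-target amplicons) are removed, and the Shannon equitability
#' of the remaining pool is recomputed. The loop stops when `H >= target_H`,
#' when no marker violates a rule, or when the pool would shrink below
#' `min_size` (reported with a warning).
#'
#' @param read_counts A [gt_read_counts()] table.
#' @param overamp_factor Removal threshold as a multiple of the mean read
#'   share (default 10).
#' @param min_on_target Minimum probe/primer proportion (default 0.2).
#' @param target_H Stop once equitability reaches this value (default 0.8).
#' @param min_size Minimum pool size.
#' @return A list of class `gt_equitability_report`: `iterations` (tibble
#'   per iteration: `iteration`, `n_markers`, `H`, `n_removed`), `removed`
#'   (tibble `marker_id`, `iteration`, `reason`), `retained` (marker ids),
#'   `H` (final), `reached_target`.
#' @export
optimize_pool <- function(read_counts, overamp_factor = 10,
                          min_on_target = 0.2, target_H = 0.8,
                          min_size = 2) {
  per_marker <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(read_counts), .data$marker_id),
    primer = sum(.data$primer_reads), probe = sum(.data$probe_reads),
    .groups = "drop")
  pool <- per_marker
  iters <- list(); removed <- list()
  it <- 0L
  H <- shannon_equitability(pool$primer)
  iters[[1]] <- tibble::tibble(iteration = 0L, n_markers = nrow(pool),
                               H = H, n_removed = 0L)
  repeat {
    if (H >= target_H) break
    share <- pool$primer / sum(pool$primer)
    q <- ifelse(pool$primer > 0, pool$probe / pool$primer, 0)
    over <- share > overamp_factor * mean(share)
    dim_ <- q < min_on_target
    viol <- over | dim_
    if (!any(viol)) break
    if (nrow(pool) - sum(viol) < min_size) {
      warning("pool would shrink below min_size before reaching target H")
      break
    }
    it <- it + 1L
    removed[[it]] <- tibble::tibble(
      marker_id = pool$marker_id[viol], iteration = it,
      reason = ifelse(over[viol] & dim_[viol], "overamplified+off_target",
                      ifelse(over[viol], "overamplified", "off_target")))
    pool <- pool[!viol, ]
    H <- shannon_equitability(pool$primer)
    iters[[it + 1]] <- tibble::tibble(iteration = it, n_markers = nrow(pool),
                                      H = H, n_removed = sum(viol))
  }
  structure(list(iterations = dplyr::bind_rows(iters),
                 removed = if (length(removed)) dplyr::bind_rows(removed)
                           else tibble::tibble(marker_id = character(0),
                                               iteration = integer(0),
                                               reason = character(0)),
                 retained = pool$marker_id, H = H,
                 reached_target = H >= target_H),
            class = "gt_equitability_report")
}

#' @export
print.gt_equitability_report <- function(x, ...) {
  cat("<gt_equitability_report> H = ", format(x$H, digits = 3), " after ",
      max(x$iterations$iteration), " iteration(s); ",
      length(x$retained), " markers retained\n", sep = "")
  invisible(x)
}

#' Primer:probe consistency across sequencing runs
#'
#' The primer:probe proportion is the on-target fraction probe/primer
#' (`NA` where a key has no primer reads). For each pair of runs the
#' proportions, aggregated per marker and per individual over shared keys,
#' are compared by Pearson correlation; per-run standard deviations along
#' both axes and the per-individual coverage (summed probe reads divided by
#' the panel size, an X-fold depth) are also reported. Zero variance on
#' either side of a correlation yields `NA` with a reason.
#'
#' @param tables A list of >= 2 [gt_read_counts()] tables sharing >= 10
#'   markers and >= 2 individuals.
#' @return A list of class `gt_consistency_report`: `marker_cor` and
#'   `individual_cor` (tibbles per run pair: `r`, `p`, `n`, `note`),
#'   `proportions` (per run x marker and run x individual tibbles), `sds`
#'   (per run, marker-wise and individual-wise SD of the proportion),
#'   `coverage` (per run x individual).
#' @export
primer_probe_consistency <- function(tables) {
  if (length(tables) < 2) stop("need >= 2 read-count tables")
  run_ids <- vapply(tables, attr, character(1), "run_id")
  agg <- function(tb, key) {
    d <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(tb), .data[[key]]),
      primer = sum(.data$primer_reads), probe = sum(.data$probe_reads),
      .groups = "drop")
    d$prop <- ifelse(d$primer > 0, d$probe / d$primer, NA_real_)
    d
  }
  mk <- lapply(tables, agg, key = "marker_id")
  ind <- lapply(tables, agg, key = "individual_id")
  shared_mk <- Reduce(intersect, lapply(mk, `[[`, "marker_id"))
  shared_ind <- Reduce(intersect, lapply(ind, `[[`, "individual_id"))
  if (length(shared_mk) < 10) stop("runs share fewer than 10 markers")
  if (length(shared_ind) < 2) stop("runs share fewer than 2 individuals")
  pair_cor <- function(tabs, shared, key) {
    out <- list()
    for (i in seq_along(tabs)[-length(tabs)]) {
      for (k in seq((i + 1), length(tabs))) {
        x <- tabs[[i]]$prop[match(shared, tabs[[i]][[key]])]
        y <- tabs[[k]]$prop[match(shared, tabs[[k]][[key]])]
        ok <- !is.na(x) & !is.na(y)
        note <- NA_character_
        if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          r <- NA_real_; p <- NA_real_
          note <- "zero variance or too few shared keys"
        } else {
          ct <- stats::cor.test(x[ok], y[ok])
          r <- unname(ct$estimate); p <- ct$p.value
        }
        out[[length(out) + 1]] <- tibble::tibble(
          run1 = run_ids[i], run2 = run_ids[k], r = r, p = p,
          n = sum(ok), note = note)
      }
    }
    dplyr::bind_rows(out)
  }
  cov <- dplyr::bind_rows(lapply(seq_along(tables), function(i) {
    d <- ind[[i]]
    n_mk <- length(unique(tables[[i]]$marker_id))
    tibble::tibble(run = run_ids[i], individual_id = d$individual_id,
                   coverage = d$probe / n_mk)
  }))
  sds <- tibble::tibble(
    run = run_ids,
    sd_marker = vapply(mk, function(d) stats::sd(d$prop, na.rm = TRUE),
                       numeric(1)),
    sd_individual = vapply(ind, function(d) stats::sd(d$prop, na.rm = TRUE),
                           numeric(1)))
  structure(list(
    marker_cor = pair_cor(mk, shared_mk, "marker_id"),
    individual_cor = pair_cor(ind, shared_ind, "individual_id"),
    proportions = list(
      marker = dplyr::bind_rows(stats::setNames(mk, run_ids), .id = "run"),
      individual = dplyr::bind_rows(stats::setNames(ind, run_ids),
                                    .id = "run")),
    sds = sds, coverage = cov),
    class = "gt_consistency_report")
}

#' Inter-run genotype congruence
#'
#' Scores how consistently the same individuals are genotyped across
#' independent sequencing runs: individuals with a genotyping rate below
#' `min_rate` in any run are removed; for each run pair and individual,
#' congruence is the fraction of loci called in both runs whose unordered
#' allele pairs are identical (in percent). Summaries (median, mean, SD,
#' min-max) are reported overall and split by marker kind, a one-way ANOVA
#' tests whether mean individual congruence differs among run pairs, and --
#' when read-count tables are supplied -- a second ANOVA regresses
#' congruence on mean individual read coverage.
#'
#' @param runs A named list of >= 2 [gt_baseline()] objects on overlapping
#'   individuals and markers (names are run labels).
#' @param min_rate Minimum per-run genotyping rate (default 0.5).
#' @param read_counts Optional list of [gt_read_counts()] aligned with
#'   `runs`, enabling the coverage ANOVA.
#' @return A list of class `gt_congruence_report`: `per_individual`
#'   (tibble: `run1`, `run2`, `individual_id`, `kind`, `n_loci`,
#'   `congruence`), `summary` (Table-style layout per run pair x
#'   all/mhap/snp), `anova_pairs` (F, df, p), `anova_coverage` (or `NULL`).
#' @export
genotype_congruence <- function(runs, min_rate = 0.5, read_counts = NULL) {
  if (length(runs) < 2) stop("need >= 2 runs")
  if (is.null(names(runs))) names(runs) <- paste0("run", seq_along(runs))
  shared_ind <- Reduce(intersect,
                       lapply(runs, function(b) b$samples$individual_id))
  keep <- shared_ind
  for (b in runs) {
    gr <- genotyping_rate(b, "individual")
    ok <- gr$individual_id[gr$rate >= min_rate]
    keep <- intersect(keep, ok)
  }
  if (length(keep) < 2) stop("fewer than 2 shared individuals pass the rate filter")
  rows <- list()
  rn <- names(runs)
  for (i in seq_along(runs)[-length(runs)]) {
    for (k in seq((i + 1), length(runs))) {
      b1 <- runs[[i]]; b2 <- runs[[k]]
      shared_mk <- intersect(b1$markers$marker_id, b2$markers$marker_id)
      if (!length(shared_mk)) stop("runs ", rn[i], " and ", rn[k],
                                   " share no markers")
      s1 <- subset_baseline(b1, shared_mk, keep)
      s2 <- subset_baseline(b2, shared_mk, keep)
      # compare as allele strings so differing allele-list orders don't matter
      al1 <- s1$markers$alleles; al2 <- s2$markers$alleles
      m <- length(shared_mk); n <- length(keep)
      same <- matrix(NA, n, m)
      for (j in seq_len(m)) {
        g1a <- al1[[j]][s1$a1[, j]]; g1b <- al1[[j]][s1$a2[, j]]
        g2a <- al2[[j]][s2$a1[, j]]; g2b <- al2[[j]][s2$a2[, j]]
        co <- !is.na(g1a) & !is.na(g2a)
        eq <- (g1a == g2a & g1b == g2b) | (g1a == g2b & g1b == g2a)
        same[co, j] <- eq[co]
      }
      kindv <- s1$markers$kind
      for (kv in list(c("all", "snp", "mhap"))[[1]]) {
        cols <- if (kv == "all") seq_len(m) else which(kindv == kv)
        if (!length(cols)) next
        sm <- same[, cols, drop = FALSE]
        n_co <- rowSums(!is.na(sm))
        congr <- ifelse(n_co > 0, 100 * rowMeans(sm, na.rm = TRUE), NA_real_)
        rows[[length(rows) + 1]] <- tibble::tibble(
          run1 = rn[i], run2 = rn[k], individual_id = keep, kind = kv,
          n_loci = n_co, congruence = congr)
      }
    }
  }
  per_ind <- dplyr::bind_rows(rows)
  summary_tb <- dplyr::summarise(
    dplyr::group_by(per_ind, .data$run1, .data$run2, .data$kind),
    median = stats::median(.data$congruence, na.rm = TRUE),
    mean = mean(.data$congruence, na.rm = TRUE),
    sd = stats::sd(.data$congruence, na.rm = TRUE),
    min = min(.data$congruence, na.rm = TRUE),
    max = max(.data$congruence, na.rm = TRUE),
    .groups = "drop")
  all_rows <- per_ind[per_ind$kind == "all" & !is.na(per_ind$congruence), ]
  all_rows$pair <- paste(all_rows$run1, all_rows$run2, sep = " vs ")
  anova_pairs <- tibble::tibble(F = NA_real_, df1 = NA_integer_,
                                df2 = NA_integer_, p = NA_real_)
  if (length(unique(all_rows$pair)) >= 2) {
    an <- stats::anova(stats::aov(congruence ~ pair, data = all_rows))
    anova_pairs <- tibble::tibble(F = an$`F value`[1], df1 = an$Df[1],
                                  df2 = an$Df[2], p = an$`Pr(>F)`[1])
  }
  anova_coverage <- NULL
  if (!is.null(read_counts)) {
    covs <- lapply(read_counts, function(rc) {
      d <- dplyr::summarise(
        dplyr::group_by(tibble::as_tibble(rc), .data$individual_id),
        reads = sum(.data$primer_reads), .groups = "drop")
      d
    })
    covtab <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(covs), .data$individual_id),
      mean_reads = mean(.data$reads), .groups = "drop")
    all_rows$mean_reads <- covtab$mean_reads[
      match(all_rows$individual_id, covtab$individual_id)]
    fit2 <- stats::aov(congruence ~ mean_reads, data = all_rows)
    an2 <- stats::anova(fit2)
    anova_coverage <- tibble::tibble(F = an2$`F value`[1], df1 = an2$Df[1],
                                     df2 = an2$Df[2], p = an2$`Pr(>F)`[1])
  }
  structure(list(per_individual = per_ind, summary = summary_tb,
                 anova_pairs = anova_pairs,
                 anova_coverage = anova_coverage),
            class = "gt_congruence_report")
}

#' @export
print.gt_congruence_report <- function(x, ...) {
  cat("<gt_congruence_report>\n")
  print(x$summary)
  cat("run-pair ANOVA: F(", x$anova_pairs$df1, ",", x$anova_pairs$df2,
      ") = ", format(x$anova_pairs$F, digits = 3), ", p = ",
      format(x$anova_pairs$p, digits = 3), "\n", sep = "")
  invisible(x)
}
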