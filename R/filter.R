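#' Screen candidate markers for panel inclusion
#'
#' Applies the sequential candidate-marker quality rules: (1) per-marker
#' missingness strictly greater than `max_missing` fails; (2) the pooled
#' inbreeding coefficient must lie strictly inside `fis_bounds`; (3) every
#' constituent SNP position must lie strictly inside `pos_window` on the
#' forward read (markers lacking position metadata fail this rule with an
#' explicit reason); (4) the allele count must be strictly less than
#' `max_alleles`. Rules are applied in that order: a marker is only
#' evaluated against a rule if it survived the previous ones, so the
#' per-rule removal counts are monotonically non-increasing and sum with
#' the survivors to the input count.
#'
#' Markers with an undefined inbreeding coefficient (monomorphic in the
#' pooled sample) pass the Fis rule: the rule cannot exclude what it cannot
#' measure.
#'
#' @param baseline A [gt_baseline()] of candidate markers.
#' @param fis_bounds Open interval for the pooled Fis (default (-0.2, 0.2)).
#' @param pos_window Open interval of admissible 1-based SNP positions on
#'   the forward read (default (17, 140)).
#' @param max_alleles Markers with this many or more alleles fail (default
#'   11, i.e. the rule is "alleles < 11").
#' @param max_missing Markers with missing fraction strictly above this
#'   fail (default 0.20; a fraction of exactly 0.20 passes).
#' @param fis_by `"pooled"` (default) computes Fis over all individuals;
#'   `"collection"` uses the maximum absolute per-collection Gis instead.
#' @return A list of class `gt_filter_report`: `report` (per-marker tibble
#'   with the measured values, per-rule flags, and `first_failed`), `counts`
#'   (per-rule tibble `rule`, `n_evaluated`, `n_removed`, `n_surviving`),
#'   and `baseline` (the filtered [gt_baseline()]).
#' @export
screen_markers <- function(baseline, fis_bounds = c(-0.2, 0.2),
                           pos_window = c(17, 140), max_alleles = 11,
                           max_missing = 0.20,
                           fis_by = c("pooled", "collection")) {
  fis_by <- match.arg(fis_by)
  mk <- baseline$markers
  m <- nrow(mk)
  miss <- unname(colMeans(is.na(baseline$a1)))
  if (fis_by == "pooled") {
    div <- diversity(baseline, group_by = "pooled")
    fis <- div$Gis[match(mk$marker_id, div$marker_id)]
  } else {
    div <- diversity(baseline, group_by = "collection")
    fis <- unname(vapply(mk$marker_id, function(id) {
      g <- div$Gis[div$marker_id == id]
      if (all(is.na(g))) NA_real_ else g[which.max(abs(g))]
    }, numeric(1)))
  }
  has_pos <- !vapply(mk$snp_positions, is.null, logical(1))
  pos_ok <- vapply(seq_len(m), function(j) {
    p <- mk$snp_positions[[j]]
    !is.null(p) && all(p > pos_window[1] & p < pos_window[2])
  }, logical(1))
  n_alleles <- lengths(mk$alleles)

  fail_miss <- miss > max_missing
  fail_fis <- !is.na(fis) & (fis <= fis_bounds[1] | fis >= fis_bounds[2])
  fail_pos <- !pos_ok
  fail_all <- n_alleles >= max_alleles

  alive <- rep(TRUE, m)
  rules <- c("missingness", "fis", "position", "allele_count")
  fails <- list(fail_miss, fail_fis, fail_pos, fail_all)
  first_failed <- rep(NA_character_, m)
  counts <- tibble::tibble(rule = rules, n_evaluated = 0L,
                           n_removed = 0L, n_surviving = 0L)
  flags <- matrix(NA, m, 4, dimnames = list(mk$marker_id, rules))
  for (k in seq_along(rules)) {
    counts$n_evaluated[k] <- sum(alive)
    hit <- alive & fails[[k]]
    flags[alive, k] <- !fails[[k]][alive]
    first_failed[hit] <- rules[k]
    counts$n_removed[k] <- sum(hit)
    alive <- alive & !hit
    counts$n_surviving[k] <- sum(alive)
  }
  report <- tibble::tibble(
    marker_id = mk$marker_id, kind = mk$kind,
    missing_frac = miss, fis = fis,
    has_position = has_pos, n_alleles = as.integer(n_alleles),
    pass_missingness = flags[, 1], pass_fis = flags[, 2],
    pass_position = flags[, 3], pass_allele_count = flags[, 4],
    first_failed = first_failed,
    reason = ifelse(!has_pos & !is.na(first_failed) &
                      first_failed == "position",
                    "no position metadata", NA_character_),
    pass = alive
  )
  structure(list(report = report, counts = counts,
                 baseline = subset_baseline(baseline, mk$marker_id[alive])),
            class = "gt_filter_report")
}

#' @export
print.gt_filter_report <- function(x, ...) {
  cat("<gt_filter_report> ", nrow(x$report), " markers in, ",
      sum(x$report$pass), " surviving\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Replace high-missingness microhaplotypes by their best constituent SNP
#'
#' Microhaplotype genotyping rates run below those of single SNPs; to keep
#' one entry per locus, any microhaplotype whose missing fraction exceeds
#' `max_missing` is replaced by the genotypes of its constituent SNP with
#' the highest pooled minor allele frequency (ties broken by the smaller
#' forward-read position). Constituent SNPs are matched in `snp_baseline`
#' by the naming convention `<mhap_id>_<position>`. A microhaplotype over
#' the cap with no constituent SNP available is dropped with a warning.
#'
#' @param mhap_baseline A [gt_baseline()] of microhaplotype loci.
#' @param snp_baseline A [gt_baseline()] holding the individual SNP calls,
#'   on the same individuals.
#' @param max_missing Missingness cap (strictly above fails, as in
#'   [screen_markers()]).
#' @return A list: `baseline` (the merged [gt_baseline()], one locus per
#'   retained input locus) and `actions` (tibble `marker_id`, `action` in
#'   kept/replaced/dropped, `replacement`).
#' @export
mhap_fallback <- function(mhap_baseline, snp_baseline, max_missing = 0.20) {
  if (!identical(mhap_baseline$samples$individual_id,
                 snp_baseline$samples$individual_id)) {
    ord <- match(mhap_baseline$samples$individual_id,
                 snp_baseline$samples$individual_id)
    if (anyNA(ord)) stop("snp_baseline lacks individuals present in mhap_baseline")
    snp_baseline <- subset_baseline(
      snp_baseline, individuals = mhap_baseline$samples$individual_id)
  }
  miss <- colMeans(is.na(mhap_baseline$a1))
  snp_maf <- .pooled_maf(snp_baseline)
  mk <- mhap_baseline$markers
  actions <- tibble::tibble(marker_id = mk$marker_id,
                            action = "kept", replacement = NA_character_)
  keep_cols <- list()
  for (j in seq_len(nrow(mk))) {
    if (miss[j] <= max_missing) {
      keep_cols[[length(keep_cols) + 1]] <- list(src = "mhap", j = j)
      next
    }
    pos <- mk$snp_positions[[j]]
    cand <- if (is.null(pos)) character(0) else
      paste0(mk$marker_id[j], "_", pos)
    hit <- cand %in% snp_baseline$markers$marker_id
    if (!any(hit)) {
      warning("mhap ", mk$marker_id[j],
              " over missingness cap with no constituent SNP: dropped")
      actions$action[j] <- "dropped"
      next
    }
    cand <- cand[hit]; cpos <- pos[hit]
    maf <- snp_maf[match(cand, names(snp_maf))]
    best <- which(maf == max(maf))
    if (length(best) > 1) best <- best[which.min(cpos[best])]
    actions$action[j] <- "replaced"
    actions$replacement[j] <- cand[best]
    keep_cols[[length(keep_cols) + 1]] <-
      list(src = "snp", j = match(cand[best], snp_baseline$markers$marker_id))
  }
  ids <- mhap_baseline$samples$individual_id
  if (!length(keep_cols)) {
    empty <- subset_baseline(mhap_baseline, character(0))
    return(list(baseline = empty, actions = actions))
  }
  mk_rows <- list(); a1 <- list(); a2 <- list()
  for (kc in keep_cols) {
    src <- if (kc$src == "mhap") mhap_baseline else snp_baseline
    mk_rows[[length(mk_rows) + 1]] <- src$markers[kc$j, ]
    a1[[length(a1) + 1]] <- src$a1[, kc$j]
    a2[[length(a2) + 1]] <- src$a2[, kc$j]
  }
  markers <- dplyr::bind_rows(mk_rows)
  class(markers) <- class(mhap_baseline$markers)
  merged <- structure(
    list(markers = markers, samples = mhap_baseline$samples,
         a1 = matrix(unlist(a1), ncol = length(a1),
                     dimnames = list(mhap_baseline$samples$individual_id,
                                     markers$marker_id)),
         a2 = matrix(unlist(a2), ncol = length(a2),
                     dimnames = list(mhap_baseline$samples$individual_id,
                                     markers$marker_id))),
    class = "gt_baseline")
  list(baseline = merged, actions = actions)
}

# pooled minor allele frequency per marker: frequency of the second most
# common allele (equals 1 - p_major for biallelic markers)
.pooled_maf <- function(baseline) {
  ac <- allele_counts(baseline, "pooled")
  maf <- vapply(ac$counts, function(x) {
    tot <- sum(x)
    if (tot == 0) return(NA_real_)
    p <- sort(colSums(x) / tot, decreasing = TRUE)
    if (length(p) < 2) 0 else p[2]
  }, numeric(1))
  stats::setNames(maf, baseline$markers$marker_id)
}
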