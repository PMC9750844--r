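#' Compose a panel scenario from FST and heterozygosity rankings
#'
#' Builds a marker panel as the union of the top `n_fst` candidates by
#' per-locus Weir-Cockerham theta and, from the remaining candidates, the
#' top `n_he` *microhaplotypes* by pooled observed heterozygosity
#' (high-theta markers drive stock identification; high-diversity
#' multiallelic markers drive kinship power). Selection is deterministic:
#' ties are broken by the higher secondary criterion, then by marker id;
#' a marker already selected by FST is skipped by the heterozygosity pass
#' and the next rank fills the slot.
#'
#' @param candidates Character vector of candidate marker ids.
#' @param per_locus_theta Named numeric: per-locus theta covering all
#'   candidates (e.g. `wc_fst(...)$per_locus`).
#' @param per_locus_het Named numeric: pooled observed heterozygosity
#'   covering all candidates.
#' @param n_fst,n_he Panel composition counts.
#' @param mhap_ids Marker ids eligible for the heterozygosity pass
#'   (normally the microhaplotype candidates). `NULL` makes all candidates
#'   eligible.
#' @param het_measure Label recorded in the scenario (`"Ho"` default).
#' @return A list of class `gt_panel_scenario`: `name`, `n_fst`, `n_he`,
#'   `selected` (ordered marker ids), `provenance` (tibble `marker_id`,
#'   `criterion`, `rank`).
#' @export
rank_and_compose <- function(candidates, per_locus_theta, per_locus_het,
                             n_fst, n_he, mhap_ids = NULL,
                             het_measure = "Ho") {
  candidates <- sort(unique(as.character(candidates)))
  if (n_fst + n_he > length(candidates)) {
    stop("insufficient candidates: need ", n_fst + n_he, ", have ",
         length(candidates))
  }
  th <- per_locus_theta[candidates]
  he <- per_locus_het[candidates]
  if (anyNA(names(th)) || anyNA(names(he))) {
    stop("ranking tables must cover all candidates")
  }
  th[is.na(th)] <- -Inf
  he[is.na(he)] <- -Inf
  # FST pass: theta desc, then het desc, then marker_id asc
  ord_f <- order(-th, -he, candidates)
  fst_pick <- candidates[ord_f][seq_len(n_fst)]
  # HE pass over remaining mhap-eligible candidates
  pool <- setdiff(candidates, fst_pick)
  if (!is.null(mhap_ids)) pool <- intersect(pool, mhap_ids)
  if (length(pool) < n_he) {
    stop("insufficient heterozygosity-eligible candidates: need ", n_he,
         ", have ", length(pool))
  }
  ord_h <- order(-he[pool], -th[pool], pool)
  he_pick <- pool[ord_h][seq_len(n_he)]
  prov <- tibble::tibble(
    marker_id = c(fst_pick, he_pick),
    criterion = rep(c("fst", "het"), c(n_fst, n_he)),
    rank = c(seq_len(n_fst), seq_len(n_he)))
  structure(list(name = sprintf("FST%d_mHE%d", n_fst, n_he),
                 n_fst = n_fst, n_he = n_he,
                 selected = prov$marker_id, provenance = prov,
                 het_measure = het_measure),
            class = "gt_panel_scenario")
}

#' @export
print.gt_panel_scenario <- function(x, ...) {
  cat("<gt_panel_scenario> ", x$name, ": ", length(x$selected),
      " markers (", x$n_fst, " by theta, ", x$n_he, " by ",
      x$het_measure, ")\n", sep = "")
  invisible(x)
}

#' Instantiate the five canonical FST/heterozygosity scenarios
#'
#' Convenience wrapper producing the standard composition sweep from
#' all-FST to all-heterozygosity panels for a given panel size.
#'
#' @param baseline A [gt_baseline()] of screened candidates.
#' @param panel_size Markers per panel (default 600).
#' @param group_by Grouping for the theta ranking (default `"collection"`).
#' @param compositions List of `c(n_fst, n_he)` pairs; defaults to the
#'   (1, 0), (0.75, 0.25), (0.5, 0.5), (0.25, 0.75), (0, 1) fractions of
#'   `panel_size`.
#' @return A named list of [rank_and_compose()] scenarios.
#' @export
standard_scenarios <- function(baseline, panel_size = 600,
                               group_by = "collection",
                               compositions = NULL) {
  if (is.null(compositions)) {
    fr <- c(1, 0.75, 0.5, 0.25, 0)
    compositions <- lapply(fr, function(f) {
      c(round(f * panel_size), panel_size - round(f * panel_size))
    })
  }
  fst <- wc_fst(baseline, group_by = group_by)
  th <- stats::setNames(fst$per_locus$theta, fst$per_locus$marker_id)
  div <- diversity(baseline, group_by = "pooled")
  he <- stats::setNames(div$Ho, div$marker_id)
  mh <- baseline$markers$marker_id[baseline$markers$kind == "mhap"]
  out <- lapply(compositions, function(co) {
    rank_and_compose(baseline$markers$marker_id, th, he,
                     n_fst = co[1], n_he = co[2], mhap_ids = mh)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Evaluate panel scenarios for stock identification and kinship power
#'
#' For each scenario: restricts the baseline to the panel, runs the
#' leave-one-out 100% mixture simulation over every reporting unit
#' (mean assignment accuracy), and estimates the full-sibling
#' false-positive rate at FNR = 0.01 by importance sampling from the
#' panel's allele frequencies. The two headline metrics mirror the
#' accuracy-vs-kinship-power trade-off that drives panel composition.
#'
#' @param scenarios A list of `gt_panel_scenario` objects (e.g. from
#'   [standard_scenarios()]).
#' @param baseline The candidate [gt_baseline()].
#' @param gsi_cfg List of overrides for [simulate_100pct_loo()]:
#'   `mixture_size`, `n_reps`, `pofz_threshold`.
#' @param kin_cfg List of overrides for [fpr_at_fnr()]: `n_sim`,
#'   `error_rate`, `fnr` (the FNR at which the headline FPR is read,
#'   default 0.01), `group`/`group_by` for the frequency source.
#' @param seed Integer seed.
#' @return A tibble of class `gt_scenario_comparison`: one row per
#'   scenario with `mean_accuracy`, `fs_fpr`, and `per_unit` detail in the
#'   attribute `"per_unit"`.
#' @export
evaluate_scenarios <- function(scenarios, baseline, gsi_cfg = list(),
                               kin_cfg = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gsi_cfg <- utils::modifyList(
    list(mixture_size = 100, n_reps = 5, pofz_threshold = 0.7), gsi_cfg)
  kin_cfg <- utils::modifyList(
    list(n_sim = 2000, error_rate = 0.005, fnr = 0.01,
         group = NULL, group_by = "lake"), kin_cfg)
  rows <- list(); detail <- list()
  for (sc in scenarios) {
    sub <- subset_baseline(baseline, sc$selected)
    rep_gsi <- simulate_100pct_loo(
      sub, mixture_size = gsi_cfg$mixture_size, n_reps = gsi_cfg$n_reps,
      pofz_threshold = gsi_cfg$pofz_threshold)
    acc <- mean(tapply(rep_gsi$summary$accuracy, rep_gsi$summary$unit,
                       mean, na.rm = TRUE))
    freqs <- baseline_frequencies(sub, group = kin_cfg$group,
                                  group_by = kin_cfg$group_by)
    fpr <- fpr_at_fnr(freqs, "FS", fnr_grid = kin_cfg$fnr,
                      n_sim = kin_cfg$n_sim,
                      error_rate = kin_cfg$error_rate)
    rows[[sc$name]] <- tibble::tibble(
      scenario = sc$name, n_fst = sc$n_fst, n_he = sc$n_he,
      mean_accuracy = acc, fs_fpr = fpr$fpr[1])
    detail[[sc$name]] <- rep_gsi$summary
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "per_unit") <- dplyr::bind_rows(detail, .id = "scenario")
  class(out) <- c("gt_scenario_comparison", class(out))
  out
}
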