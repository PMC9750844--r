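#' Construct a marker metadata table
#'
#' Markers are either biallelic SNPs or microhaplotypes (mhaps): short
#' amplicons containing two or more SNPs whose phased combination defines a
#' multiallelic marker. Allele identity is by exact string match after case
#' folding to upper case.
#'
#' @param marker_id Character vector of unique marker identifiers.
#' @param kind `"snp"` or `"mhap"`, recycled if length 1. If `NULL`, inferred
#'   from `n_snps` (mhap iff `n_snps > 1`).
#' @param n_snps Integer count of constituent SNPs per marker (default 1 for
#'   SNPs; mhaps must have > 1).
#' @param snp_positions List of integer vectors: 1-based base positions of
#'   each constituent SNP on the forward read. `NULL` entries allowed (no
#'   position metadata).
#' @param alleles List of character vectors: the ordered allele set per
#'   marker (nucleotides for SNPs, haplotype strings for mhaps).
#' @param permissive If `TRUE`, the biallelic-SNP and two-allele-minimum
#'   checks are skipped. Used when marker definitions are inferred from
#'   observed calls, where monomorphic or multiallelic single-position
#'   columns are legitimate data.
#' @return A tibble with class `gt_markers` and columns `marker_id`, `kind`,
#'   `n_snps`, `snp_positions` (list), `alleles` (list).
#' @export
gt_markers <- function(marker_id, kind = NULL, n_snps = NULL,
                       snp_positions = NULL, alleles = NULL,
                       permissive = FALSE) {
  marker_id <- as.character(marker_id)
  if (anyDuplicated(marker_id)) {
    stop("duplicated marker_id: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  }
  m <- length(marker_id)
  if (is.null(alleles)) stop("alleles must be supplied")
  alleles <- lapply(alleles, function(a) toupper(as.character(a)))
  if (is.null(n_snps)) {
    n_snps <- vapply(alleles, function(a) max(1L, nchar(a[1])), integer(1))
  }
  n_snps <- rep_len(as.integer(n_snps), m)
  if (is.null(kind)) kind <- ifelse(n_snps > 1L, "mhap", "snp")
  kind <- rep_len(as.character(kind), m)
  if (is.null(snp_positions)) snp_positions <- rep(list(NULL), m)
  snp_positions <- lapply(snp_positions, function(p) {
    if (is.null(p) || all(is.na(p))) NULL else as.integer(p)
  })

  for (j in seq_len(m)) {
    a <- alleles[[j]]
    if (anyDuplicated(a) || (!permissive && length(a) < 2)) {
      stop("marker ", marker_id[j],
           ": allele list must contain >= 2 unique entries")
    }
    if (!permissive && kind[j] == "snp" && length(a) != 2) {
      stop("marker ", marker_id[j], ": SNP markers must have exactly 2 alleles")
    }
    if ((kind[j] == "mhap") != (n_snps[j] > 1L)) {
      stop("marker ", marker_id[j],
           ": kind must be 'mhap' if and only if n_snps > 1")
    }
    if (!kind[j] %in% c("snp", "mhap")) {
      stop("marker ", marker_id[j], ": kind must be 'snp' or 'mhap'")
    }
  }
  out <- tibble::tibble(marker_id = marker_id, kind = kind, n_snps = n_snps,
                        snp_positions = snp_positions, alleles = alleles)
  class(out) <- c("gt_markers", class(out))
  out
}

#' Construct a sample metadata table
#'
#' Individuals are nested in collections (spawning-site samples), collections
#' in reporting units (management groupings used for stock identification),
#' and reporting units in lakes. The hierarchy must be functional: each
#' collection belongs to exactly one reporting unit and each reporting unit
#' to exactly one lake.
#'
#' @param individual_id,collection,reporting_unit,lake Character vectors of
#'   equal length (`reporting_unit` and `lake` default to `collection` /
#'   `reporting_unit` when a flat design is wanted).
#' @return A tibble with class `gt_samples`.
#' @export
gt_samples <- function(individual_id, collection,
                       reporting_unit = collection, lake = reporting_unit) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id)) {
    stop("duplicated individual_id: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  }
  out <- tibble::tibble(
    individual_id = individual_id,
    collection = as.character(collection),
    reporting_unit = rep_len(as.character(reporting_unit), length(individual_id)),
    lake = rep_len(as.character(lake), length(individual_id))
  )
  chk <- unique(out[, c("collection", "reporting_unit", "lake")])
  if (anyDuplicated(chk$collection)) {
    stop("hierarchy not functional: a collection maps to more than one reporting unit/lake")
  }
  chk2 <- unique(chk[, c("reporting_unit", "lake")])
  if (anyDuplicated(chk2$reporting_unit)) {
    stop("hierarchy not functional: a reporting unit maps to more than one lake")
  }
  class(out) <- c("gt_samples", class(out))
  out
}

#' Assemble a genotype baseline
#'
#' The central container: individuals x markers with an unordered allele pair
#' per call, or missing. Internally calls are stored as two integer matrices
#' of allele indices into each marker's allele list; a call is missing when
#' both indices are `NA`. Half-calls (one allele present, one missing) are
#' coerced to missing with a warning.
#'
#' @param markers A `gt_markers` table.
#' @param samples A `gt_samples` table.
#' @param calls1,calls2 Character (allele strings) or integer (allele index)
#'   matrices, individuals in rows (order of `samples`), markers in columns
#'   (order of `markers`). `NA` or `""` denotes missing.
#' @param strict If `TRUE`, an allele observed in the calls but absent from
#'   the marker's allele list is an error; if `FALSE` (default) it is
#'   appended to the allele list with a warning.
#' @return An object of class `gt_baseline`: a list with elements `markers`,
#'   `samples`, `a1`, `a2`.
#' @export
gt_baseline <- function(markers, samples, calls1, calls2, strict = FALSE) {
  stopifnot(inherits(markers, "gt_markers"), inherits(samples, "gt_samples"))
  n <- nrow(samples); m <- nrow(markers)
  calls1 <- as.matrix(calls1); calls2 <- as.matrix(calls2)
  if (!all(dim(calls1) == c(n, m)) || !all(dim(calls2) == c(n, m))) {
    stop("call matrices must be ", n, " individuals x ", m, " markers")
  }
  if (is.character(calls1)) {
    enc <- .encode_calls(markers, calls1, calls2, strict)
    markers <- enc$markers; a1 <- enc$a1; a2 <- enc$a2
  } else {
    a1 <- matrix(as.integer(calls1), n, m)
    a2 <- matrix(as.integer(calls2), n, m)
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-call(s) (one allele missing) set to MISSING")
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
  }
  A <- lengths(markers$alleles)
  bad <- which(colSums((a1 < 1L | a1 > rep(A, each = n)) |
                       (a2 < 1L | a2 > rep(A, each = n)), na.rm = TRUE) > 0)
  if (length(bad)) {
    stop("allele index out of range for marker(s): ",
         paste(markers$marker_id[bad], collapse = ", "))
  }
  dimnames(a1) <- dimnames(a2) <- list(samples$individual_id, markers$marker_id)
  structure(list(markers = markers, samples = samples, a1 = a1, a2 = a2),
            class = "gt_baseline")
}

# map character call matrices to allele indices, appending novel alleles
# (with a warning) unless strict
.encode_calls <- function(markers, c1, c2, strict) {
  n <- nrow(c1); m <- nrow(markers)
  c1[c1 %in% c("", "NA", "0")] <- NA_character_
  c2[c2 %in% c("", "NA", "0")] <- NA_character_
  c1 <- toupper(c1); c2 <- toupper(c2)
  a1 <- matrix(NA_integer_, n, m); a2 <- matrix(NA_integer_, n, m)
  appended <- character(0)
  for (j in seq_len(m)) {
    al <- markers$alleles[[j]]
    obs <- unique(stats::na.omit(c(c1[, j], c2[, j])))
    novel <- setdiff(obs, al)
    if (length(novel)) {
      if (strict) {
        stop("marker ", markers$marker_id[j],
             ": allele(s) not in marker definition: ",
             paste(novel, collapse = ", "))
      }
      al <- c(al, novel)
      markers$alleles[[j]] <- al
      appended <- c(appended, markers$marker_id[j])
    }
    a1[, j] <- match(c1[, j], al)
    a2[, j] <- match(c2[, j], al)
  }
  if (length(appended)) {
    warning("observed alleles appended to marker definition for: ",
            paste(unique(appended), collapse = ", "))
  }
  list(markers = markers, a1 = a1, a2 = a2)
}

#' @export
print.gt_baseline <- function(x, ...) {
  cat("<gt_baseline> ", nrow(x$samples), " individuals x ",
      nrow(x$markers), " markers\n", sep = "")
  cat("  kinds: ", sum(x$markers$kind == "snp"), " SNP, ",
      sum(x$markers$kind == "mhap"), " mhap\n", sep = "")
  cat("  collections: ", length(unique(x$samples$collection)),
      "; reporting units: ", length(unique(x$samples$reporting_unit)),
      "; lakes: ", length(unique(x$samples$lake)), "\n", sep = "")
  cat("  missing calls: ",
      format(100 * mean(is.na(x$a1)), digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Number of individuals / markers in a baseline
#' @param baseline A `gt_baseline`.
#' @return Integer count.
#' @export
n_individuals <- function(baseline) nrow(baseline$samples)

#' @rdname n_individuals
#' @export
n_markers <- function(baseline) nrow(baseline$markers)

#' Subset a baseline by markers and/or individuals
#'
#' @param baseline A `gt_baseline`.
#' @param markers Character vector of marker ids (kept in the given order),
#'   or `NULL` to keep all.
#' @param individuals Character vector of individual ids, or `NULL`.
#' @return A `gt_baseline`.
#' @export
subset_baseline <- function(baseline, markers = NULL, individuals = NULL) {
  mj <- if (is.null(markers)) seq_len(n_markers(baseline)) else {
    j <- match(markers, baseline$markers$marker_id)
    if (anyNA(j)) stop("unknown marker(s): ",
                       paste(markers[is.na(j)], collapse = ", "))
    j
  }
  ii <- if (is.null(individuals)) seq_len(n_individuals(baseline)) else {
    i <- match(individuals, baseline$samples$individual_id)
    if (anyNA(i)) stop("unknown individual(s): ",
                       paste(individuals[is.na(i)], collapse = ", "))
    i
  }
  mk <- baseline$markers[mj, ]
  class(mk) <- class(baseline$markers)
  sm <- baseline$samples[ii, ]
  class(sm) <- class(baseline$samples)
  structure(list(markers = mk, samples = sm,
                 a1 = baseline$a1[ii, mj, drop = FALSE],
                 a2 = baseline$a2[ii, mj, drop = FALSE]),
            class = "gt_baseline")
}

#' Genotyping rate by individual or marker
#'
#' Fraction of non-missing calls along the chosen axis. Individuals with a
#' rate below 0.5 are conventionally dropped before inter-run congruence
#' analyses.
#'
#' @param baseline A `gt_baseline`.
#' @param by `"individual"` or `"marker"`.
#' @return A tibble with the id column and `rate` in \[0, 1\].
#' @export
genotyping_rate <- function(baseline, by = c("individual", "marker")) {
  by <- match.arg(by)
  called <- !is.na(baseline$a1)
  if (by == "individual") {
    tibble::tibble(individual_id = baseline$samples$individual_id,
                   rate = unname(rowMeans(called)))
  } else {
    tibble::tibble(marker_id = baseline$markers$marker_id,
                   rate = unname(colMeans(called)))
  }
}

#' Per-group gene-copy allele counts
#'
#' Workhorse summary used by the diversity, differentiation, and stock
#' identification code: for every marker, the matrix of observed gene-copy
#' counts per group x allele, plus heterozygote-carriage counts needed by the
#' Weir-Cockerham variance components.
#'
#' @param baseline A `gt_baseline`.
#' @param group_by Grouping column of the sample metadata: `"collection"`,
#'   `"reporting_unit"`, `"lake"`, or `"pooled"` (a single group).
#' @return A list with `groups` (character), `counts` (list per marker of
#'   groups x alleles gene-copy count matrices), `het_counts` (same shape:
#'   number of individuals heterozygous *carrying* each allele), and
#'   `n_ind` (groups x markers matrix of genotyped individuals).
#' @export
allele_counts <- function(baseline,
                          group_by = c("collection", "reporting_unit",
                                       "lake", "pooled")) {
  group_by <- match.arg(group_by)
  g <- if (group_by == "pooled") rep("pooled", n_individuals(baseline))
       else baseline$samples[[group_by]]
  groups <- sort(unique(g))
  gi <- match(g, groups)
  r <- length(groups); m <- n_markers(baseline)
  A <- lengths(baseline$markers$alleles)
  counts <- vector("list", m); het_counts <- vector("list", m)
  n_ind <- matrix(0L, r, m, dimnames = list(groups, baseline$markers$marker_id))
  for (j in seq_len(m)) {
    a1 <- baseline$a1[, j]; a2 <- baseline$a2[, j]
    ok <- !is.na(a1)
    x <- matrix(0L, r, A[j], dimnames = list(groups, baseline$markers$alleles[[j]]))
    h <- matrix(0L, r, A[j], dimnames = dimnames(x))
    if (any(ok)) {
      t1 <- table(factor(gi[ok], levels = seq_len(r)),
                  factor(a1[ok], levels = seq_len(A[j])))
      t2 <- table(factor(gi[ok], levels = seq_len(r)),
                  factor(a2[ok], levels = seq_len(A[j])))
      x[] <- as.integer(t1 + t2)
      het <- ok & a1 != a2
      if (any(het)) {
        h1 <- table(factor(gi[het], levels = seq_len(r)),
                    factor(a1[het], levels = seq_len(A[j])))
        h2 <- table(factor(gi[het], levels = seq_len(r)),
                    factor(a2[het], levels = seq_len(A[j])))
        h[] <- as.integer(h1 + h2)
      }
      n_ind[, j] <- tabulate(gi[ok], nbins = r)
    }
    counts[[j]] <- x; het_counts[[j]] <- h
  }
  list(groups = groups, counts = counts, het_counts = het_counts, n_ind = n_ind)
}
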