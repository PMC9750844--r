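#' Read a wide genotype table plus sample metadata
#'
#' The wide dialect has one row per individual, a leading `individual_id`
#' column, then two columns per marker named `<marker>_1` and `<marker>_2`
#' (suffixes `.1`/`.2` also accepted). Blank, `NA`, or `0` cells denote
#' missing. TSV or CSV is autodetected from the header line; lines starting
#' with `#` are skipped.
#'
#' @param path Genotype file.
#' @param meta_path Metadata file with columns `individual_id`, `collection`,
#'   and optionally `reporting_unit` and `lake`.
#' @param markers Optional `gt_markers` table (e.g. from
#'   [read_marker_metadata()]). If `NULL`, marker definitions are inferred
#'   from the observed alleles.
#' @param strict Passed to [gt_baseline()]: disallow alleles absent from the
#'   supplied marker definitions.
#' @return A validated `gt_baseline`.
#' @export
read_genotype_table <- function(path, meta_path, markers = NULL,
                                strict = FALSE) {
  geno <- .read_delim_auto(path)
  meta <- .read_delim_auto(meta_path)
  if (!"individual_id" %in% names(geno)) {
    names(geno)[1] <- "individual_id"
  }
  ids <- as.character(geno$individual_id)
  if (anyDuplicated(ids)) {
    stop("duplicated individual_id in genotype file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  gcols <- setdiff(names(geno), "individual_id")
  base <- sub("[._][12]$", "", gcols)
  suf <- sub("^.*[._]([12])$", "\\1", gcols)
  suf[!grepl("[._][12]$", gcols)] <- ""
  mk_ids <- unique(base)
  for (mk in mk_ids) {
    here <- suf[base == mk]
    if (!setequal(here, c("1", "2"))) {
      stop("marker ", mk, ": expected exactly one allele1 and one allele2 column")
    }
  }
  c1 <- as.matrix(geno[, gcols[match(paste0(mk_ids, "_1"),
                                     paste0(base, "_", suf))], drop = FALSE])
  c2 <- as.matrix(geno[, gcols[match(paste0(mk_ids, "_2"),
                                     paste0(base, "_", suf))], drop = FALSE])
  mode(c1) <- "character"; mode(c2) <- "character"
  .assemble_baseline(ids, mk_ids, c1, c2, meta, markers, strict)
}

#' Read a long-format genotype table
#'
#' Compatibility hook for deposited-data layouts: columns `individual_id`,
#' `marker_id`, `allele1`, `allele2`, one row per call. Absent
#' (individual, marker) combinations are missing.
#'
#' @inheritParams read_genotype_table
#' @return A validated `gt_baseline`.
#' @export
read_genotype_long <- function(path, meta_path, markers = NULL,
                               strict = FALSE) {
  long <- .read_delim_auto(path)
  need <- c("individual_id", "marker_id", "allele1", "allele2")
  if (!all(need %in% names(long))) {
    stop("long genotype file must have columns: ", paste(need, collapse = ", "))
  }
  meta <- .read_delim_auto(meta_path)
  ids <- unique(as.character(long$individual_id))
  mk_ids <- unique(as.character(long$marker_id))
  key <- paste(long$individual_id, long$marker_id)
  if (anyDuplicated(key)) stop("duplicated (individual, marker) rows")
  i <- match(long$individual_id, ids); j <- match(long$marker_id, mk_ids)
  c1 <- matrix(NA_character_, length(ids), length(mk_ids))
  c2 <- matrix(NA_character_, length(ids), length(mk_ids))
  c1[cbind(i, j)] <- as.character(long$allele1)
  c2[cbind(i, j)] <- as.character(long$allele2)
  .assemble_baseline(ids, mk_ids, c1, c2, meta, markers, strict)
}

.assemble_baseline <- function(ids, mk_ids, c1, c2, meta, markers, strict) {
  if (!all(c("individual_id", "collection") %in% names(meta))) {
    stop("metadata must have columns individual_id and collection")
  }
  mi <- match(ids, as.character(meta$individual_id))
  if (anyNA(mi)) {
    stop("individual(s) in genotypes but not metadata: ",
         paste(ids[is.na(mi)], collapse = ", "))
  }
  meta <- meta[mi, ]
  samples <- gt_samples(
    ids, meta$collection,
    reporting_unit = if ("reporting_unit" %in% names(meta))
      meta$reporting_unit else meta$collection,
    lake = if ("lake" %in% names(meta)) meta$lake
      else if ("reporting_unit" %in% names(meta)) meta$reporting_unit
      else meta$collection
  )
  if (is.null(markers)) {
    markers <- .infer_markers(mk_ids, c1, c2)
  } else {
    mj <- match(mk_ids, markers$marker_id)
    if (anyNA(mj)) {
      stop("marker(s) in genotype file but not metadata: ",
           paste(mk_ids[is.na(mj)], collapse = ", "))
    }
    markers <- markers[mj, ]
    class(markers) <- unique(c("gt_markers", class(markers)))
  }
  gt_baseline(markers, samples, c1, c2, strict = strict)
}

# infer marker definitions from observed alleles: allele string width > 1
# implies a microhaplotype with one SNP per character position
.infer_markers <- function(mk_ids, c1, c2) {
  alleles <- lapply(seq_along(mk_ids), function(j) {
    a <- unique(toupper(stats::na.omit(c(c1[, j], c2[, j]))))
    a <- setdiff(a, c("", "NA", "0"))
    sort(a)
  })
  empty <- lengths(alleles) < 1
  if (any(empty)) {
    stop("no alleles observed for marker(s): ",
         paste(mk_ids[empty], collapse = ", "),
         "; supply marker metadata")
  }
  wid <- vapply(alleles, function(a) nchar(a[1]), integer(1))
  gt_markers(mk_ids, n_snps = wid,
             snp_positions = lapply(wid, function(w) seq_len(w)),
             alleles = alleles, permissive = TRUE)
}

#' Write a baseline to wide genotype + metadata files
#'
#' Writers emit a `#`-prefixed header line carrying the package version and
#' the seed used to produce the data (if any), so outputs are traceable.
#'
#' @param baseline A `gt_baseline`.
#' @param path,meta_path Output files (TSV).
#' @param seed Optional integer recorded in the header comment.
#' @return Invisibly, `baseline`.
#' @export
write_genotype_table <- function(baseline, path, meta_path = NULL,
                                 seed = NULL) {
  mk <- baseline$markers
  n <- n_individuals(baseline); m <- n_markers(baseline)
  out <- matrix("", n, 2 * m)
  for (j in seq_len(m)) {
    al <- mk$alleles[[j]]
    out[, 2 * j - 1] <- ifelse(is.na(baseline$a1[, j]), "", al[baseline$a1[, j]])
    out[, 2 * j] <- ifelse(is.na(baseline$a2[, j]), "", al[baseline$a2[, j]])
  }
  colnames(out) <- paste0(rep(mk$marker_id, each = 2), c("_1", "_2"))
  df <- data.frame(individual_id = baseline$samples$individual_id, out,
                   check.names = FALSE)
  .write_with_header(df, path, seed)
  if (!is.null(meta_path)) {
    .write_with_header(as.data.frame(baseline$samples), meta_path, seed)
  }
  invisible(baseline)
}

.write_with_header <- function(df, path, seed = NULL) {
  hdr <- paste0("# gtpanel ",
                as.character(utils::packageVersion("gtpanel")),
                if (!is.null(seed)) paste0(" seed=", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_delim_auto <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  utils::read.table(text = lines, sep = sep, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Read marker metadata
#'
#' Columns: `marker_id`, `kind`, `n_snps`, `snp_positions` (comma-separated
#' integers), `alleles` (comma-separated strings).
#'
#' @param path Delimited text file.
#' @return A `gt_markers` table.
#' @export
read_marker_metadata <- function(path) {
  df <- .read_delim_auto(path)
  gt_markers(
    df$marker_id,
    kind = if ("kind" %in% names(df)) df$kind else NULL,
    n_snps = if ("n_snps" %in% names(df)) as.integer(df$n_snps) else NULL,
    snp_positions = if ("snp_positions" %in% names(df))
      lapply(strsplit(df$snp_positions, ","), as.integer) else NULL,
    alleles = strsplit(df$alleles, ",")
  )
}

#' Construct a per-run read-count table
#'
#' Holds, for one sequencing run, the number of reads containing each
#' marker's primer sequence and the subset of those also containing its
#' diagnostic probe sequence, per individual, plus per-individual off-target
#' read totals (reads matching no marker).
#'
#' @param run_id Run label.
#' @param counts Tibble/data frame with columns `individual_id`, `marker_id`,
#'   `primer_reads`, `probe_reads`.
#' @param off_target Optional tibble with `individual_id`,
#'   `off_target_reads`.
#' @return A tibble of class `gt_read_counts` with attributes `run_id` and
#'   `off_target`.
#' @export
gt_read_counts <- function(run_id, counts, off_target = NULL) {
  need <- c("individual_id", "marker_id", "primer_reads", "probe_reads")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  counts <- tibble::as_tibble(counts)
  counts$primer_reads <- as.integer(counts$primer_reads)
  counts$probe_reads <- as.integer(counts$probe_reads)
  if (any(counts$primer_reads < 0 | counts$probe_reads < 0)) {
    stop("read counts must be >= 0")
  }
  if (any(counts$probe_reads > counts$primer_reads)) {
    stop("probe_reads must be <= primer_reads")
  }
  if (!is.null(off_target)) {
    off_target <- tibble::as_tibble(off_target)
    off_target$off_target_reads <- as.integer(off_target$off_target_reads)
    if (any(off_target$off_target_reads < 0)) stop("read counts must be >= 0")
  }
  structure(counts, run_id = as.character(run_id), off_target = off_target,
            class = c("gt_read_counts", class(counts)))
}

#' Read a read-count table
#' @param path Delimited file with columns `individual_id`, `marker_id`,
#'   `primer_reads`, `probe_reads`, optionally `off_target_reads`.
#' @param run_id Run label (defaults to the file name).
#' @return A `gt_read_counts`.
#' @export
read_read_counts <- function(path, run_id = basename(path)) {
  df <- .read_delim_auto(path)
  off <- NULL
  if ("off_target_reads" %in% names(df)) {
    off <- unique(df[, c("individual_id", "off_target_reads")])
  }
  gt_read_counts(run_id, df[, c("individual_id", "marker_id",
                                "primer_reads", "probe_reads")], off)
}

#' Write a read-count table
#' @param rc A `gt_read_counts`.
#' @param path Output TSV.
#' @param seed Optional integer recorded in the header comment.
#' @return Invisibly, `rc`.
#' @export
write_read_counts <- function(rc, path, seed = NULL) {
  df <- as.data.frame(rc)
  off <- attr(rc, "off_target")
  if (!is.null(off)) {
    df$off_target_reads <- off$off_target_reads[
      match(df$individual_id, off$individual_id)]
  }
  .write_with_header(df, path, seed)
  invisible(rc)
}
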