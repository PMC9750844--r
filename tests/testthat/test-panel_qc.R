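test_that("Shannon equitability closed forms and guards", {
  expect_equal(shannon_equitability(rep(100, 37)), 1)
  # one marker holds all reads among 500
  expect_equal(shannon_equitability(c(1e6, rep(0, 499))), 0)
  expect_equal(shannon_equitability(c(50, 25, 25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)) / log(3),
               tolerance = 1e-12)
  expect_equal(round(shannon_equitability(c(50, 25, 25)), 3), 0.946)
  expect_error(shannon_equitability(c(0, 0, 0)), "all-zero")
  expect_error(shannon_equitability(5), ">= 2 markers")
})

test_that("equitability is permutation-invariant and rises toward evenness", {
  set.seed(30)
  x <- stats::rpois(50, 100) + 1
  expect_equal(shannon_equitability(x), shannon_equitability(sample(x)))
  # shrinking the single largest share toward the mean strictly increases H
  x_max <- which.max(x)
  y <- x
  y[x_max] <- ceiling(mean(x))
  expect_gt(shannon_equitability(y), shannon_equitability(x))
})

test_that("a constructed 1000x over-amplifier is removed in one iteration", {
  rc <- simulate_read_counts(10, 101, sigma_marker = 0, sigma_indiv = 0,
                             marker_factors = c(1000, rep(1, 100)),
                             q = 0.9, seed = 31)
  rep_ <- optimize_pool(rc, target_H = 0.95)
  expect_equal(max(rep_$iterations$iteration), 1)
  expect_equal(rep_$removed$marker_id, "mk_0001")
  expect_lt(rep_$iterations$H[1], 0.5)
  expect_gt(rep_$H, 0.95)
})

test_that("an already-even pool needs zero iterations", {
  rc <- simulate_read_counts(10, 50, sigma_marker = 0, sigma_indiv = 0,
                             q = 0.9, seed = 32)
  rep_ <- optimize_pool(rc)
  expect_equal(max(rep_$iterations$iteration), 0)
  expect_equal(length(rep_$retained), 50)
})

test_that("a two-tier pool crosses the target in exactly two removals", {
  # X dominates round 1; Y only becomes an over-amplifier once X is gone
  counts <- tibble::tibble(
    individual_id = "i1",
    marker_id = c("X", "Y", sprintf("m%02d", 1:98)),
    primer_reads = as.integer(c(96000, 3000, rep(10, 98))),
    probe_reads = as.integer(c(90000, 2800, rep(9, 98))))
  rc <- gt_read_counts("opt", counts)
  rep_ <- optimize_pool(rc, target_H = 0.8)
  expect_equal(max(rep_$iterations$iteration), 2)
  expect_equal(rep_$removed$marker_id[rep_$removed$iteration == 1], "X")
  expect_equal(rep_$removed$marker_id[rep_$removed$iteration == 2], "Y")
  expect_lt(rep_$iterations$H[2], 0.8)
  expect_gt(rep_$H, 0.8)
  # pool size strictly decreases across iterations
  expect_true(all(diff(rep_$iterations$n_markers) < 0))
})

test_that("low on-target markers are culled by the dimer rule", {
  counts <- tibble::tibble(
    individual_id = "i1",
    marker_id = sprintf("m%02d", 1:40),
    primer_reads = rep(100L, 40),
    probe_reads = as.integer(c(rep(90, 38), 5, 5)))
  rc <- gt_read_counts("opt", counts)
  rep_ <- optimize_pool(rc, target_H = 1.1)  # force rule-driven stop
  expect_setequal(rep_$removed$marker_id, c("m39", "m40"))
  expect_true(all(rep_$removed$reason == "off_target"))
})

test_that("primer:probe consistency r = 1 on identical runs, NA at zero variance", {
  rc <- simulate_read_counts(20, 30, q = stats::runif(30, 0.3, 1), seed = 33)
  cons <- primer_probe_consistency(list(rc, rc))
  expect_equal(cons$marker_cor$r, 1, tolerance = 1e-12)
  expect_equal(cons$individual_cor$r, 1, tolerance = 1e-12)
  # probe == primer everywhere: proportion constant -> NA with a reason
  rc2 <- simulate_read_counts(20, 30, q = 1, seed = 34)
  cons2 <- primer_probe_consistency(list(rc2, rc2))
  expect_true(is.na(cons2$marker_cor$r))
  expect_match(cons2$marker_cor$note, "zero variance")
})

test_that("shared marker chemistry gives marker-wise but not individual-wise correlation", {
  q <- stats::runif(200, 0.2, 1)
  r1 <- simulate_read_counts(60, 200, q = q, seed = 35)
  r2 <- simulate_read_counts(60, 200, q = q, seed = 36)
  cons <- primer_probe_consistency(list(r1, r2))
  expect_gt(cons$marker_cor$r, 0.7)
  expect_lt(abs(cons$individual_cor$r), 0.3)
})

test_that("individual coverage is summed probe reads over panel size", {
  counts <- tibble::tibble(individual_id = rep(c("i1", "i2"), each = 10),
                           marker_id = rep(paste0("m", 1:10), 2),
                           primer_reads = rep(c(10L, 20L), each = 10),
                           probe_reads = rep(c(8L, 15L), each = 10))
  rc <- gt_read_counts("r", counts)
  rc2 <- gt_read_counts("r2",
                        dplyr::mutate(counts,
                                      probe_reads = pmin(probe_reads + c(1L, -1L),
                                                         primer_reads)))
  cons <- primer_probe_consistency(list(rc, rc2))
  cv <- cons$coverage[cons$coverage$run == "r", ]
  expect_equal(cv$coverage[cv$individual_id == "i1"], 8)   # 80 / 10
  expect_equal(cv$coverage[cv$individual_id == "i2"], 15)  # 150 / 10
})

test_that("congruence arithmetic: identical runs and an engineered 95%", {
  sim <- simulate_baseline(n_lakes = 1, collections_per_lake = 1,
                           n_per_collection = 10, n_snp = 60, n_mhap = 40,
                           missing_rate = 0, seed = 40)
  b <- sim$baseline
  cg <- genotype_congruence(list(runA = b, runB = b))
  all_rows <- cg$per_individual[cg$per_individual$kind == "all", ]
  expect_true(all(all_rows$congruence == 100))
  # flip exactly 5 of 100 calls for one individual
  b2 <- b
  for (j in 1:5) {
    al <- b$markers$alleles[[j]]
    cur <- b$a1[1, j]
    b2$a1[1, j] <- if (cur == 1L) 2L else 1L
    b2$a2[1, j] <- b2$a1[1, j]
  }
  cg2 <- genotype_congruence(list(runA = b, runB = b2))
  r1 <- cg2$per_individual[cg2$per_individual$kind == "all" &
                             cg2$per_individual$individual_id ==
                               b$samples$individual_id[1], ]
  expect_equal(r1$congruence, 95)
})

test_that("congruence is symmetric in run order and recombines by marker kind", {
  sim <- simulate_baseline(n_lakes = 1, collections_per_lake = 1,
                           n_per_collection = 12, n_snp = 30, n_mhap = 30,
                           missing_rate = 0.05, seed = 41)
  b <- sim$baseline
  b2 <- perturb_baseline(b, 0.05, seed = 42)
  c_ab <- genotype_congruence(list(A = b, B = b2))
  c_ba <- genotype_congruence(list(B = b2, A = b))
  a_all <- c_ab$per_individual[c_ab$per_individual$kind == "all", ]
  b_all <- c_ba$per_individual[c_ba$per_individual$kind == "all", ]
  expect_equal(a_all$congruence, b_all$congruence)
  # kind split recombines to the overall value as a weighted mean
  for (id in b$samples$individual_id[1:3]) {
    rows <- c_ab$per_individual[c_ab$per_individual$individual_id == id, ]
    w <- rows$n_loci[rows$kind != "all"]
    v <- rows$congruence[rows$kind != "all"]
    expect_equal(rows$congruence[rows$kind == "all"],
                 sum(w * v) / sum(w), tolerance = 1e-9)
  }
})

test_that("low-rate individuals are excluded before congruence scoring", {
  sim <- simulate_baseline(n_lakes = 1, collections_per_lake = 1,
                           n_per_collection = 8, n_snp = 40, n_mhap = 0,
                           missing_rate = 0, seed = 43)
  b <- sim$baseline
  b2 <- b
  # individual 1 loses 60% of calls in run B
  set.seed(50)
  drop <- sample(40, 24)
  b2$a1[1, drop] <- NA; b2$a2[1, drop] <- NA
  cg <- genotype_congruence(list(A = b, B = b2), min_rate = 0.5)
  expect_false(b$samples$individual_id[1] %in%
                 cg$per_individual$individual_id)
})

test_that("an error-prone run depresses congruence detectably by ANOVA", {
  sim <- simulate_baseline(n_lakes = 1, collections_per_lake = 1,
                           n_per_collection = 40, n_snp = 120, n_mhap = 80,
                           missing_rate = 0.02, seed = 44)
  b <- sim$baseline
  runs <- list(lab1 = perturb_baseline(b, 0.01, seed = 45),
               lab2 = perturb_baseline(b, 0.01, seed = 46),
               lab3 = perturb_baseline(b, 0.03, seed = 47))
  cg <- genotype_congruence(runs)
  expect_lt(cg$anova_pairs$p, 0.05)
  means <- tapply(cg$per_individual$congruence[
    cg$per_individual$kind == "all"],
    paste(cg$per_individual$run1, cg$per_individual$run2)[
      cg$per_individual$kind == "all"], mean, na.rm = TRUE)
  expect_equal(names(which.max(means)), "lab1 lab2")
})

test_that("SNP-only congruence beats mhaps when mhap error dominates", {
  sim <- simulate_baseline(n_lakes = 1, collections_per_lake = 1,
                           n_per_collection = 30, n_snp = 80, n_mhap = 80,
                           missing_rate = 0, seed = 48)
  b <- sim$baseline
  # perturb only the mhap markers in the second run
  b2 <- b
  mh <- which(b$markers$kind == "mhap")
  sub <- subset_baseline(b, b$markers$marker_id[mh])
  sub2 <- perturb_baseline(sub, 0.05, seed = 49)
  b2$a1[, mh] <- sub2$a1; b2$a2[, mh] <- sub2$a2
  cg <- genotype_congruence(list(A = b, B = b2))
  s <- cg$summary
  expect_gt(s$mean[s$kind == "snp"], s$mean[s$kind == "mhap"])
})
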