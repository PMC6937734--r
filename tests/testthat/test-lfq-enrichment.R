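# small raw table builder: values on the raw scale, 0 = missing
make_raw <- function(values, ids = sprintf("P%02d", seq_len(nrow(values))),
                     reverse = FALSE, contaminant = FALSE) {
  tab <- tibble::tibble(protein_id = ids,
                        reverse = rep_len(reverse, nrow(values)),
                        contaminant = rep_len(contaminant, nrow(values)))
  for (j in seq_len(ncol(values))) tab[[colnames(values)[j]]] <- values[, j]
  tab
}

test_that("preprocessing drops flagged rows, exclusions, and all-zero rows, and log2-transforms", {
  v <- matrix(c(
    8, 8, 8, 8,      # kept, log2 = 3
    4, 4, 4, 4,      # reverse -> dropped
    2, 2, 2, 2,      # IGHG1 -> dropped
    0, 0, 0, 0,      # all zero -> dropped
    0, 16, 16, 16    # kept with one missing
  ), ncol = 4, byrow = TRUE,
  dimnames = list(NULL, c("IP_1", "IP_2", "Ctrl_1", "Ctrl_2")))
  raw <- make_raw(v, ids = c("P1", "REV_X", "IGHG1_HUMAN", "P4", "P5"),
                  reverse = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  mat <- preprocess_intensities(raw)
  expect_equal(mat$protein_ids, c("P1", "P5"))
  expect_equal(unname(mat$log2["P1", ]), rep(3, 4))
  expect_true(is.na(mat$log2["P5", "IP_1"]))
  expect_equal(unname(mat$log2["P5", "IP_2"]), 4)
  expect_false(any(mat$imputed))
  # everything filtered -> error
  raw_all_rev <- make_raw(v[1:2, , drop = FALSE], reverse = TRUE)
  expect_error(preprocess_intensities(raw_all_rev), class = "retroproteo_empty_error")
})

test_that("group-missing imputation draws inside [mu-3sd, mu-2sd] per column and is seeded", {
  withr::with_seed(1, {
    v <- 2^matrix(rnorm(200 * 4, 20, 2), ncol = 4,
                  dimnames = list(NULL, c(paste0("IP_", 1:3), "Ctrl_1")))
  })
  v[1, 1:3] <- 0  # protein missing in every case replicate, observed in control
  raw <- make_raw(v)
  mat <- preprocess_intensities(raw)
  out1 <- impute_group_missing(mat, paste0("IP_", 1:3), seed = 99)
  out2 <- impute_group_missing(mat, paste0("IP_", 1:3), seed = 99)
  expect_identical(out1$log2, out2$log2)
  expect_true(all(out1$imputed["P01", paste0("IP_", 1:3)]))
  expect_false(out1$imputed["P01", "Ctrl_1"])
  for (j in 1:3) {
    col <- mat$log2[-1, paste0("IP_", j)]
    mu <- mean(col); s <- sd(col)
    val <- out1$log2["P01", paste0("IP_", j)]
    expect_gte(val, mu - 3 * s)
    expect_lte(val, mu - 2 * s)
  }
  # observed values are never altered
  expect_identical(out1$log2[-1, ], mat$log2[-1, ])
  expect_identical(out1$log2[, "Ctrl_1"], mat$log2[, "Ctrl_1"])
})

test_that("a zero-variance column imputes exactly at the column mean", {
  v <- 2^matrix(20, nrow = 5, ncol = 4,
                dimnames = list(NULL, c(paste0("IP_", 1:3), "Ctrl_1")))
  v[1, 1:3] <- 0
  mat <- preprocess_intensities(make_raw(v))
  out <- impute_group_missing(mat, paste0("IP_", 1:3), seed = 1)
  expect_equal(unname(out$log2["P01", paste0("IP_", 1:3)]), rep(20, 3))
})

test_that("group-missing imputation refuses columns with undefined sd", {
  v <- 2^matrix(20, nrow = 3, ncol = 3, dimnames = list(NULL, paste0("IP_", 1:3)))
  v[2:3, 2] <- 0  # column 2 has a single observed value
  mat <- preprocess_intensities(make_raw(v))
  expect_error(impute_group_missing(mat, paste0("IP_", 1:3)),
               class = "retroproteo_imputation_error")
})

test_that("the delta model recovers known replicate statistics", {
  # two proteins fully observed: deltas computable by hand
  v <- 2^matrix(c(20, 22, 21,
                  10, 10, 10,
                  18, 18, 18), ncol = 3, byrow = TRUE,
                dimnames = list(NULL, paste0("IP_", 1:3)))
  v[3, 1] <- 0  # third protein not fully observed
  mat <- preprocess_intensities(make_raw(v))
  model <- fit_delta_model(mat, paste0("IP_", 1:3))
  expect_equal(model$n_proteins, 2)
  hand_deltas <- c((20 - 22) / 21, (10 - 10) / 10,   # rep1 vs rep2
                   (20 - 21) / 20.5, (10 - 10) / 10, # rep1 vs rep3
                   (22 - 21) / 21.5, (10 - 10) / 10) # rep2 vs rep3
  expect_equal(model$mu_delta, mean(hand_deltas))
  expect_equal(model$sd_delta, sd(hand_deltas))
})

test_that("partial-missing imputation follows I_new = mean(observed) * |1 + delta|", {
  v <- 2^matrix(c(20, 22, 21,
                  19, 21, 20,
                  18, 20, 19,
                  21, 23, 22), ncol = 3, byrow = TRUE,
                dimnames = list(NULL, paste0("IP_", 1:3)))
  v[1, 3] <- 0  # one missing case replicate for the first protein
  mat <- preprocess_intensities(make_raw(v))
  # degenerate model: mu = 0, sd = 0 -> imputed value is exactly the observed mean
  model <- structure(list(mu_delta = 0, sd_delta = 0, mean_correlation = 0.9,
                          n_proteins = 3, group_cols = paste0("IP_", 1:3)),
                     class = "lfq_delta_model")
  out <- impute_partial_missing(mat, paste0("IP_", 1:3), model, seed = 1)
  expect_equal(unname(out$log2["P01", "IP_3"]), 21)
  expect_true(out$imputed["P01", "IP_3"])
  # a realistic small-sd model stays within the +/- 3 sd band of the formula
  s <- 0.01
  model2 <- structure(list(mu_delta = 0, sd_delta = s * 0.9 * sqrt(2),
                           mean_correlation = 0.9, n_proteins = 3,
                           group_cols = paste0("IP_", 1:3)),
                      class = "lfq_delta_model")
  out2 <- impute_partial_missing(mat, paste0("IP_", 1:3), model2, seed = 7)
  val <- unname(out2$log2["P01", "IP_3"])
  expect_gte(val, 21 * (1 - 3 * s))
  expect_lte(val, 21 * (1 + 3 * s))
})

test_that("partial-missing imputation rejects non-positive replicate correlation", {
  v <- 2^matrix(c(20, 22, 21, 19, 21, 20), ncol = 3, byrow = TRUE,
                dimnames = list(NULL, paste0("IP_", 1:3)))
  v[1, 3] <- 0
  mat <- preprocess_intensities(make_raw(v))
  model <- structure(list(mu_delta = 0, sd_delta = 0.1, mean_correlation = -0.2,
                          n_proteins = 3, group_cols = paste0("IP_", 1:3)),
                     class = "lfq_delta_model")
  expect_error(impute_partial_missing(mat, paste0("IP_", 1:3), model),
               class = "retroproteo_imputation_error")
})

test_that("imputation never alters observed values (mask disjointness)", {
  ip <- simulate_ipms_matrix(n_proteins = 150, n_spiked = 10, seed = 21)
  mat <- preprocess_intensities(ip$table)
  before <- mat$log2
  out <- impute_lfq(mat, ip$groups, seed = 2)
  obs <- !is.na(before)
  expect_identical(out$log2[obs], before[obs])
  expect_false(any(out$imputed & obs))
  expect_false(anyNA(out$log2[, unlist(ip$groups)]))
})

test_that("per-protein comparison matches the closed-form Welch t-test", {
  case <- c(24.1, 23.7, 24.4)
  ctrl <- c(21.0, 21.5, 20.8)
  v <- 2^rbind(c(case, ctrl), c(rep(20, 3), rep(20.2, 3)))
  colnames(v) <- c(paste0("IP_", 1:3), paste0("Ctrl_", 1:3))
  mat <- preprocess_intensities(make_raw(v))
  cmp <- lfq_compare(mat, paste0("IP_", 1:3), paste0("Ctrl_", 1:3))
  hand <- oracle_welch(case, ctrl)
  expect_equal(cmp$p_value[1], hand$p, tolerance = 1e-12)
  expect_equal(cmp$log2_fold_change[1], mean(case) - mean(ctrl))
  expect_equal(cmp$p_adjusted, p.adjust(cmp$p_value, "BH"))
})

test_that("identical case and control values give fold change 0 and p = 1", {
  v <- 2^matrix(20, nrow = 3, ncol = 6,
                dimnames = list(NULL, c(paste0("IP_", 1:3), paste0("Ctrl_", 1:3))))
  mat <- preprocess_intensities(make_raw(v))
  cmp <- lfq_compare(mat, paste0("IP_", 1:3), paste0("Ctrl_", 1:3))
  expect_equal(cmp$log2_fold_change, rep(0, 3))
  expect_equal(cmp$p_value, rep(1, 3))
  expect_false(any(cmp$significant))
})

test_that("fewer than two measured case replicates blocks significance", {
  withr::with_seed(3, {
    v <- 2^matrix(rnorm(40 * 6, 20, 1), ncol = 6,
                  dimnames = list(NULL, c(paste0("IP_", 1:3), paste0("Ctrl_", 1:3))))
  })
  v[1, 1:3] <- c(0, 0, 2^28)   # huge fold change but a single measured case value
  mat <- preprocess_intensities(make_raw(v))
  mat <- impute_lfq(mat, list(case = paste0("IP_", 1:3),
                              control = paste0("Ctrl_", 1:3)), seed = 5)
  cmp <- lfq_compare(mat, paste0("IP_", 1:3), paste0("Ctrl_", 1:3))
  expect_equal(cmp$n_nonimputed_case[1], 1L)
  expect_false(cmp$significant[1])
})

test_that("BH adjustment is monotone and bounded by 1", {
  ip <- simulate_ipms_matrix(n_proteins = 300, n_spiked = 15,
                             missing_max_rate = 0, seed = 8)
  mat <- preprocess_intensities(ip$table)
  cmp <- lfq_compare(mat, ip$groups$case, ip$groups$control)
  expect_true(all(cmp$p_adjusted <= 1))
  expect_true(all(cmp$p_adjusted >= cmp$p_value))
  o <- order(cmp$p_value)
  expect_true(all(diff(cmp$p_adjusted[o]) >= -1e-15))
})

test_that("integration counts comparisons passed and builds tiers from a plant", {
  mk <- function(sig) {
    out <- tibble::tibble(protein_id = paste0("P", 1:5),
                          log2_fold_change = 2, p_value = 0.001,
                          p_adjusted = 0.01, n_nonimputed_case = 3L,
                          significant = sig)
    class(out) <- c("lfq_comparison", class(out))
    out
  }
  comps <- list(a = mk(c(TRUE, TRUE, FALSE, FALSE, FALSE)),
                b = mk(c(TRUE, FALSE, TRUE, FALSE, FALSE)),
                c = mk(c(TRUE, TRUE, FALSE, FALSE, FALSE)))
  integ <- integrate_comparisons(comps)
  expect_equal(integ$proteins$n_significant[match(paste0("P", 1:5),
                                                  integ$proteins$protein_id)],
               c(3L, 2L, 1L, 0L, 0L))
  expect_equal(integ$tiers$n_proteins, c(3L, 2L, 1L))
  expect_equal(glance(integ)$pass_ge_2, 2L)
})

test_that("band ranking drops keratins, sub-trypsin ranks, homologues and weak ids", {
  ids <- tibble::tibble(
    protein_id = c("ALB", "KRT1", "TRYP_PIG", "MYH9", "ACTB"),
    log_e = c(-120, -80, -60, -40, -20),
    psm_count = c(100, 50, 30, 20, 10),
    is_keratin = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    is_human = TRUE,
    homology_group = NA_character_
  )
  got <- rank_band_ids(ids, trypsin_id = "TRYP_PIG")
  # trypsin is rank 3: ranks 4-5 removed, keratin removed
  expect_equal(got$protein_id, "ALB")

  # within-50%-PSM rule: 40 < 0.5 * 100 -> removed
  ids2 <- tibble::tibble(
    protein_id = c("TOP", "NEXT", "WEAK"),
    log_e = c(-90, -70, -50),
    psm_count = c(100, 60, 40),
    is_keratin = FALSE, is_human = TRUE,
    homology_group = NA_character_
  )
  got2 <- rank_band_ids(ids2, trypsin_id = "none")
  expect_equal(got2$protein_id, c("TOP", "NEXT"))

  # homology: a lower-ranked member of a retained group is removed
  ids3 <- ids2
  ids3$homology_group <- c("myosin", "myosin", NA)
  ids3$psm_count <- c(100, 60, 60)
  got3 <- suppressMessages(rank_band_ids(ids3, trypsin_id = "none"))
  expect_equal(got3$protein_id, c("TOP", "WEAK"))

  # idempotence and empty input
  expect_equal(suppressMessages(rank_band_ids(got3, trypsin_id = "none")), got3)
  expect_equal(nrow(rank_band_ids(ids2[0, ], trypsin_id = "none")), 0)
})
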