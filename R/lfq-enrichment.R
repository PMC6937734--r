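# Label-free quantitative IP-MS differential enrichment: preprocessing, the
# two missing-value imputation schemes (all-replicates-missing and
# partial-missing), per-comparison variance analysis, cross-comparison
# significance integration, and the gel-band identification ranking.
#
# Intensities live on the log2 scale from preprocess_intensities() onward;
# missingness is an explicit NA + mask, never a zero.

new_lfq_matrix <- function(log2_values, imputed, protein_ids, samples) {
  dimnames(log2_values) <- list(protein_ids, samples)
  dimnames(imputed) <- list(protein_ids, samples)
  structure(
    list(log2 = log2_values, imputed = imputed,
         protein_ids = protein_ids, samples = samples),
    class = "lfq_matrix"
  )
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples; %.1f%% missing, %.1f%% imputed\n",
              length(x$protein_ids), length(x$samples),
              100 * mean(is.na(x$log2)), 100 * mean(x$imputed)))
  invisible(x)
}

#' @method as_tibble lfq_matrix
#' @export
as_tibble.lfq_matrix <- function(x, ...) {
  tibble(
    protein_id = rep(x$protein_ids, times = length(x$samples)),
    sample = rep(x$samples, each = length(x$protein_ids)),
    log2_intensity = as.vector(x$log2),
    imputed = as.vector(x$imputed)
  )
}

#' @method tidy lfq_matrix
#' @export
tidy.lfq_matrix <- function(x, ...) as_tibble.lfq_matrix(x)

#' @method glance lfq_matrix
#' @export
glance.lfq_matrix <- function(x, ...) {
  tibble(n_proteins = length(x$protein_ids), n_samples = length(x$samples),
         pct_missing = 100 * mean(is.na(x$log2)),
         pct_imputed = 100 * mean(x$imputed))
}

#' Preprocess a raw intensity table for differential enrichment
#'
#' Removes rows flagged reverse or contaminant, rows whose protein id contains
#' any excluded identifier (the IP antibody heavy chain IGHG1 by default,
#' which co-elutes in every IP), log2-transforms the non-zero intensities,
#' converts zeros to explicit missing values, and drops proteins missing in
#' every sample.
#'
#' @param raw Tibble in the shape returned by [read_intensity_table()] or
#'   [simulate_ipms_matrix()].
#' @param exclusions Character vector of identifiers to exclude by substring
#'   match on the protein id (default `"IGHG1"`).
#' @return An `lfq_matrix`: log2 intensity matrix with NA for missing values
#'   and an (initially empty) imputation mask.
#' @export
preprocess_intensities <- function(raw, exclusions = "IGHG1") {
  samples <- setdiff(names(raw), c("protein_id", "reverse", "contaminant"))
  assert_that(length(samples) > 0, "no sample columns found")
  keep <- !raw$reverse & !raw$contaminant
  for (ex in exclusions) keep <- keep & !grepl(ex, raw$protein_id, fixed = TRUE)
  raw <- raw[keep, , drop = FALSE]
  m <- as.matrix(raw[samples])
  assert_that(all(m >= 0, na.rm = TRUE), "intensities must be non-negative")
  m[m == 0 | is.na(m)] <- NA
  m <- log2(m)
  observed <- rowSums(!is.na(m)) > 0
  m <- m[observed, , drop = FALSE]
  if (nrow(m) == 0) {
    abort("no proteins left after filtering", class = "retroproteo_empty_error")
  }
  new_lfq_matrix(m, matrix(FALSE, nrow(m), ncol(m)),
                 raw$protein_id[observed], samples)
}

check_group_cols <- function(mat, group_cols) {
  missing_cols <- setdiff(group_cols, mat$samples)
  assert_that(length(missing_cols) == 0,
              paste0("unknown sample column(s): ", paste(missing_cols, collapse = ", ")))
}

#' Impute proteins missing in every replicate of a group
#'
#' For proteins with no observed value in any replicate of the group, draws
#' each missing cell uniformly from `[mu_c - 3*sd_c, mu_c - 2*sd_c]`, where
#' `mu_c` and `sd_c` are the mean and standard deviation of the non-missing
#' log2 values of that replicate column. This places unquantified proteins in
#' the low-abundance tail, reflecting left-censored missingness.
#'
#' @param mat An `lfq_matrix`.
#' @param group_cols Sample columns forming the group (e.g. the case
#'   replicates).
#' @param seed Optional integer; when given, draws are made under this seed
#'   without disturbing the session RNG.
#' @return The updated `lfq_matrix` with the imputation mask set.
#' @export
impute_group_missing <- function(mat, group_cols, seed = NULL) {
  check_group_cols(mat, group_cols)
  draw <- function() {
    sub <- mat$log2[, group_cols, drop = FALSE]
    col_mu <- apply(sub, 2, mean, na.rm = TRUE)
    col_sd <- apply(sub, 2, sd, na.rm = TRUE)
    n_obs <- colSums(!is.na(sub))
    if (any(n_obs < 2)) {
      abort(paste0("column(s) with fewer than 2 observed values, sd undefined: ",
                   paste(group_cols[n_obs < 2], collapse = ", ")),
            class = "retroproteo_imputation_error")
    }
    target <- rowSums(!is.na(sub)) == 0
    for (j in seq_along(group_cols)) {
      lo <- col_mu[j] - 3 * col_sd[j]
      hi <- col_mu[j] - 2 * col_sd[j]
      vals <- runif(sum(target), lo, hi)
      mat$log2[target, group_cols[j]] <- vals
      mat$imputed[target, group_cols[j]] <- TRUE
    }
    mat
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Fit the replicate-delta model used for partial-missing imputation
#'
#' From proteins fully observed in the group, builds the distribution of
#' relative replicate differences `delta = (x_i - x_j) / mean(x_i, x_j)` over
#' all replicate pairs, and records the mean pairwise Pearson correlation
#' among the group's replicate columns (also computed on fully observed
#' proteins). Only non-imputed values enter the fit.
#'
#' @inheritParams impute_group_missing
#' @return Object of class `lfq_delta_model`: `mu_delta`, `sd_delta`,
#'   `mean_correlation`, `n_proteins`, `group_cols`.
#' @export
fit_delta_model <- function(mat, group_cols) {
  check_group_cols(mat, group_cols)
  sub <- mat$log2[, group_cols, drop = FALSE]
  sub[mat$imputed[, group_cols, drop = FALSE]] <- NA   # model fitted from observed values only
  full <- rowSums(is.na(sub)) == 0
  assert_that(sum(full) >= 2,
              "need at least 2 fully observed proteins to fit the delta model")
  sub <- sub[full, , drop = FALSE]
  k <- length(group_cols)
  deltas <- double()
  cors <- double()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      deltas <- c(deltas, (sub[, i] - sub[, j]) / ((sub[, i] + sub[, j]) / 2))
      cors <- c(cors, cor(sub[, i], sub[, j]))
    }
  }
  structure(
    list(mu_delta = mean(deltas), sd_delta = sd(deltas),
         mean_correlation = mean(cors), n_proteins = sum(full),
         group_cols = group_cols),
    class = "lfq_delta_model"
  )
}

#' @export
print.lfq_delta_model <- function(x, ...) {
  cat(sprintf("<lfq_delta_model> mu_delta %.4g, sd_delta %.4g, mean correlation %.3f (%d proteins)\n",
              x$mu_delta, x$sd_delta, x$mean_correlation, x$n_proteins))
  invisible(x)
}

#' @method glance lfq_delta_model
#' @export
glance.lfq_delta_model <- function(x, ...) {
  tibble(mu_delta = x$mu_delta, sd_delta = x$sd_delta,
         mean_correlation = x$mean_correlation, n_proteins = x$n_proteins)
}

#' Impute proteins partially missing within a group
#'
#' For proteins with at least one observed and at least one missing replicate
#' in the group, draws `delta_new` from
#' `Normal(mu_delta, sd_delta / (mean_correlation * sqrt(2)))` and sets the
#' imputed intensity to `mean(observed replicates) * abs(1 + delta_new)`.
#' Requires a positive mean replicate correlation (the scale is undefined
#' otherwise; near-zero correlations indicate the replicates do not agree well
#' enough to support this scheme).
#'
#' @inheritParams impute_group_missing
#' @param model An [fit_delta_model()] result for the same group.
#' @return The updated `lfq_matrix` with the imputation mask set.
#' @export
impute_partial_missing <- function(mat, group_cols, model, seed = NULL) {
  check_group_cols(mat, group_cols)
  assert_that(inherits(model, "lfq_delta_model"), "`model` must come from fit_delta_model()")
  if (model$mean_correlation <= 0) {
    abort(paste0("mean replicate correlation is ", signif(model$mean_correlation, 3),
                 " (<= 0): the imputation scale sd_delta/(correlation*sqrt(2)) is undefined. ",
                 "Check replicate agreement before imputing."),
          class = "retroproteo_imputation_error")
  }
  s <- model$sd_delta / (model$mean_correlation * sqrt(2))
  draw <- function() {
    sub <- mat$log2[, group_cols, drop = FALSE]
    n_missing <- rowSums(is.na(sub))
    target <- which(n_missing > 0 & n_missing < length(group_cols))
    for (i in target) {
      obs_mean <- mean(sub[i, ], na.rm = TRUE)
      for (j in which(is.na(sub[i, ]))) {
        delta_new <- rnorm(1, model$mu_delta, s)
        mat$log2[i, group_cols[j]] <- obs_mean * abs(1 + delta_new)
        mat$imputed[i, group_cols[j]] <- TRUE
      }
    }
    mat
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Run both imputation steps for each group
#'
#' Convenience wrapper: for every group, first imputes proteins missing in all
#' of the group's replicates ([impute_group_missing()]), then fits the delta
#' model and imputes partially missing proteins ([impute_partial_missing()]).
#' The delta model is fitted before any imputed value exists in the group.
#'
#' @param mat An `lfq_matrix`.
#' @param groups Named list of sample-column vectors (e.g.
#'   `list(case = ..., control = ...)`).
#' @param seed Optional integer seed controlling all draws.
#' @return The fully imputed `lfq_matrix`.
#' @export
impute_lfq <- function(mat, groups, seed = NULL) {
  run <- function() {
    for (g in names(groups)) {
      model <- fit_delta_model(mat, groups[[g]])
      mat <- impute_group_missing(mat, groups[[g]])
      mat <- impute_partial_missing(mat, groups[[g]], model)
    }
    mat
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Per-protein case-vs-control comparison
#'
#' Two-sample t-test (Welch by default) per protein on log2 intensities,
#' Benjamini-Hochberg adjustment across the proteins of this comparison, and
#' the significance call `p_adjusted <= alpha & log2_fold_change >=
#' lfc_threshold & n_nonimputed_case >= min_nonimputed`: a protein backed by
#' fewer than two measured (non-imputed) case intensities is never called
#' significant, however large its fold change.
#'
#' @param mat A fully imputed `lfq_matrix` (no NA among the used columns).
#' @param case_cols,control_cols Sample columns of the two sides.
#' @param label Comparison label carried into the result.
#' @param var_equal Use pooled-variance Student's t instead of Welch.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param lfc_threshold Minimum log2 fold change (default 1).
#' @param min_nonimputed Minimum measured case replicates (default 2).
#' @return Tibble of class `lfq_comparison`: `protein_id`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `n_nonimputed_case`,
#'   `significant`.
#' @export
lfq_compare <- function(mat, case_cols, control_cols, label = "comparison",
                        var_equal = FALSE, alpha = 0.05, lfc_threshold = 1,
                        min_nonimputed = 2L) {
  check_group_cols(mat, c(case_cols, control_cols))
  assert_that(length(case_cols) >= 2 && length(control_cols) >= 2,
              "need at least 2 samples per side")
  case <- mat$log2[, case_cols, drop = FALSE]
  ctrl <- mat$log2[, control_cols, drop = FALSE]
  assert_that(!anyNA(case) && !anyNA(ctrl),
              "missing values remain: run impute_lfq() first")
  p <- map_dbl(seq_len(nrow(case)), function(i) {
    x <- case[i, ]
    y <- ctrl[i, ]
    if (sd(x) == 0 && sd(y) == 0) {
      # degenerate: no variance on either side
      return(if (mean(x) == mean(y)) 1 else .Machine$double.xmin)
    }
    tryCatch(t.test(x, y, var.equal = var_equal)$p.value,
             error = function(e) if (mean(x) == mean(y)) 1 else .Machine$double.xmin)
  })
  lfc <- rowMeans(case) - rowMeans(ctrl)
  n_nonimp <- rowSums(!mat$imputed[, case_cols, drop = FALSE])
  out <- tibble(
    protein_id = mat$protein_ids,
    log2_fold_change = unname(lfc),
    p_value = p,
    p_adjusted = p.adjust(p, method = "BH"),
    n_nonimputed_case = as.integer(unname(n_nonimp))
  ) |>
    mutate(significant = .data$p_adjusted <= alpha &
             .data$log2_fold_change >= lfc_threshold &
             .data$n_nonimputed_case >= min_nonimputed)
  class(out) <- c("lfq_comparison", class(out))
  attr(out, "label") <- label
  attr(out, "case_cols") <- case_cols
  attr(out, "control_cols") <- control_cols
  out
}

#' @method tidy lfq_comparison
#' @export
tidy.lfq_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lfq_comparison")
  out
}

#' @method glance lfq_comparison
#' @export
glance.lfq_comparison <- function(x, ...) {
  tibble(label = attr(x, "label") %||% NA_character_,
         n_proteins = nrow(x),
         n_significant = sum(x$significant),
         min_p_adjusted = min(x$p_adjusted))
}

#' Integrate significance calls across comparisons
#'
#' Counts, per protein, in how many comparisons it was called significant, and
#' tabulates how many proteins pass at least 1, 2, ... comparisons.
#'
#' @param comparisons Named list of [lfq_compare()] results.
#' @return List of class `lfq_integration`: `proteins` (tibble `protein_id`,
#'   `n_significant`, one logical column per comparison) and `tiers` (tibble
#'   `min_comparisons`, `n_proteins`).
#' @export
integrate_comparisons <- function(comparisons) {
  assert_that(length(comparisons) >= 1, "need at least one comparison")
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons)))) {
    names(comparisons) <- paste0("comparison_", seq_along(comparisons))
  }
  long <- imap(comparisons, function(cmp, nm) {
    tibble(protein_id = cmp$protein_id, comparison = nm, significant = cmp$significant)
  }) |> bind_rows()
  wide <- long |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "significant",
                       values_fill = FALSE)
  counts <- rowSums(as.matrix(wide[names(comparisons)]))
  proteins <- wide |> mutate(n_significant = as.integer(counts)) |>
    select("protein_id", "n_significant", dplyr::everything())
  k <- length(comparisons)
  tiers <- tibble(
    min_comparisons = seq_len(k),
    n_proteins = map_int(seq_len(k), ~ sum(counts >= .x))
  )
  structure(list(proteins = proteins, tiers = tiers), class = "lfq_integration")
}

#' @export
print.lfq_integration <- function(x, ...) {
  cat("<lfq_integration>\n")
  for (i in seq_len(nrow(x$tiers))) {
    cat(sprintf("  >= %d comparison(s): %d proteins\n",
                x$tiers$min_comparisons[i], x$tiers$n_proteins[i]))
  }
  invisible(x)
}

#' @method tidy lfq_integration
#' @export
tidy.lfq_integration <- function(x, ...) x$proteins

#' @method glance lfq_integration
#' @export
glance.lfq_integration <- function(x, ...) {
  tidyr::pivot_wider(x$tiers, names_from = "min_comparisons",
                     values_from = "n_proteins", names_prefix = "pass_ge_")
}

#' Rank and filter gel-band protein identifications
#'
#' Orders candidate identifications for an excised gel band by ascending log
#' e-value (most significant first; ties by higher PSM count, then id), then
#' removes keratins, non-human proteins, and everything at or below trypsin's
#' rank (trypsin is the digestion enzyme, so anything it outranks is noise).
#' Among the remainder, entries are dropped when they share a homology group
#' with a retained higher-ranked protein or have fewer than half the PSMs of
#' the retained top entry. Applying the function to its own output is the
#' identity.
#'
#' @param ids Tibble with columns `protein_id`, `log_e`, `psm_count`,
#'   `is_keratin`, `is_human`, and `homology_group` (NA = no known homologue).
#' @param trypsin_id Protein id of the trypsin entry; when absent from `ids`,
#'   no trypsin cut is applied (with a message).
#' @return The filtered, ranked tibble.
#' @export
rank_band_ids <- function(ids, trypsin_id = "TRYP_PIG") {
  needed <- c("protein_id", "log_e", "psm_count", "is_keratin", "is_human",
              "homology_group")
  assert_that(all(needed %in% names(ids)),
              paste("`ids` must have columns:", paste(needed, collapse = ", ")))
  if (nrow(ids) == 0) return(ids)
  assert_that(all(is.finite(ids$log_e)) && all(ids$psm_count >= 1),
              "log_e must be finite and psm_count >= 1")
  ranked <- ids |> arrange(.data$log_e, desc(.data$psm_count), .data$protein_id)
  trypsin_rank <- which(ranked$protein_id == trypsin_id)
  if (length(trypsin_rank) == 0) {
    inform(paste0("trypsin id '", trypsin_id, "' not present; no trypsin cut applied"))
  } else {
    ranked <- ranked[seq_len(trypsin_rank[1] - 1L), , drop = FALSE]
  }
  ranked <- ranked |> filter(!.data$is_keratin, .data$is_human)
  if (nrow(ranked) <= 1) return(ranked)
  keep <- 1L
  for (i in 2:nrow(ranked)) {
    hg <- ranked$homology_group[i]
    homologous <- !is.na(hg) && hg %in% ranked$homology_group[keep]
    weak <- ranked$psm_count[i] < 0.5 * ranked$psm_count[keep[1]]
    if (!homologous && !weak) keep <- c(keep, i)
  }
  ranked[keep, , drop = FALSE]
}
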