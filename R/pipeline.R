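# Orchestration: YAML config loading with schema checks, stage dispatch, and a
# run manifest (config snapshot, seed, input digests, stage timings, outputs)
# written atomically at run end so a run can be reproduced bit for bit.

PIPELINE_STAGES <- c("simulate", "filter_psms", "epitope_scan", "orthogonalize",
                     "lfq_run", "band_rank")

validate_config <- function(config) {
  assert_that(is.list(config), "config must parse to a list")
  for (key in c("seed", "stages")) {
    if (is.null(config[[key]])) {
      abort(paste0("config schema violation: missing required key '", key, "'"),
            class = "retroproteo_config_error")
    }
  }
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    abort(paste0("config schema violation: unknown stage(s) '",
                 paste(bad, collapse = "', '"), "'"),
          class = "retroproteo_config_error")
  }
  if ("lfq_run" %in% config$stages) {
    for (key in c("case", "control")) {
      if (is.null(config$lfq[[key]])) {
        abort(paste0("config schema violation: missing required key 'lfq.", key, "'"),
              class = "retroproteo_config_error")
      }
    }
  }
  invisible(config)
}

write_manifest_atomically <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full pipeline from a YAML config
#'
#' Executes the configured stages in their declared order against one output
#' directory. A failing stage leaves earlier outputs intact and the manifest
#' records which stage failed. Every stochastic stage derives its seed from
#' the single run seed, so re-running with the same config reproduces all
#' outputs bit for bit.
#'
#' Config schema (YAML): top-level `seed` (integer) and `stages` (subset of
#' `simulate`, `filter_psms`, `epitope_scan`, `orthogonalize`, `lfq_run`,
#' `band_rank`), plus per-stage blocks: `simulate` (generator sizes),
#' `lfq` (`case`/`control` sample name lists and thresholds), `band_rank`
#' (`input` TSV and `trypsin_id`). Stages consume the files earlier stages
#' wrote into the run directory; `filter_psms`, `epitope_scan`,
#' `orthogonalize` and `lfq_run` accept explicit `*_input` paths when run
#' without `simulate`.
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory (default: `out_dir` key of the config, or a
#'   temp directory).
#' @param seed Optional override of the config seed.
#' @return Invisibly, the manifest list (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config_path, out_dir = NULL, seed = NULL) {
  assert_that(file.exists(config_path), paste0("config not found: ", config_path))
  config <- yaml::read_yaml(config_path)
  validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  out_dir <- out_dir %||% config$out_dir %||% tempfile("retroproteo_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    config = config,
    seed = config$seed,
    config_digest = unname(tools::md5sum(config_path)),
    stages = list(),
    outputs = character(),
    status = "running"
  )
  state <- new.env(parent = emptyenv())
  out_path <- function(name) file.path(out_dir, name)
  record_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
  }

  stage_fns <- list(
    simulate = function(cfg) {
      sim_cfg <- cfg$simulate %||% list()
      fam <- simulate_locus_family(
        n_loci = sim_cfg$n_loci %||% 20L,
        length = sim_cfg$locus_length %||% 300L,
        mutation_rate = sim_cfg$mutation_rate %||% 0.0125,
        indel_rate = sim_cfg$indel_rate %||% 0.05,
        seed = cfg$seed
      )
      state$family <- fam
      write_fasta(
        tibble(identifier = c("consensus", fam$loci$locus_id),
               description = c("family consensus", fam$loci$subfamily),
               residues = c(fam$consensus, fam$loci$protein)),
        out_path("locus_family.fasta"))
      record_output(out_path("locus_family.fasta"))

      peptides <- digest_protein(fam$consensus, max_missed_cleavages = 0) |>
        filter(nchar(.data$peptide) >= 7, nchar(.data$peptide) <= 25)
      peptides <- head(peptides, sim_cfg$n_spectra %||% 25L)
      sim <- simulate_spectra(peptides$peptide,
                              fragment_dropout = sim_cfg$fragment_dropout %||% 0.1,
                              noise_peaks = sim_cfg$noise_peaks %||% 10L,
                              seed = cfg$seed + 1L)
      state$spectra <- sim
      write_mgf(sim$spectra, out_path("spectra.mgf"))
      record_output(out_path("spectra.mgf"))

      ip <- simulate_ipms_matrix(
        n_proteins = sim_cfg$n_proteins %||% 200L,
        n_spiked = sim_cfg$n_spiked %||% 10L,
        effect_log2 = sim_cfg$effect_log2 %||% 2,
        within_sd = sim_cfg$within_sd %||% 0.5,
        seed = cfg$seed + 2L)
      state$ipms <- ip
      write_intensity_table(ip$table, out_path("intensities.tsv"))
      record_output(out_path("intensities.tsv"))
      jsonlite::write_json(list(spiked = ip$ledger$protein_id[ip$ledger$spiked]),
                           out_path("truth_ledger.json"), auto_unbox = FALSE)
      record_output(out_path("truth_ledger.json"))
    },
    filter_psms = function(cfg) {
      assert_that(!is.null(state$spectra), "filter_psms needs the simulate stage")
      ann <- annotate_psms(state$spectra$psms, state$spectra$spectra)
      res <- filter_psms(ann, config = filter_config())
      readr::write_tsv(res$retained |> select(-"assignments", -dplyr::any_of("modifications")),
                       out_path("psms_retained.tsv"), progress = FALSE)
      readr::write_tsv(res$rejections, out_path("psms_rejected.tsv"), progress = FALSE)
      record_output(out_path("psms_retained.tsv"))
      record_output(out_path("psms_rejected.tsv"))
      state$retained <- res$retained
    },
    epitope_scan = function(cfg) {
      assert_that(!is.null(state$family), "epitope_scan needs the simulate stage")
      fam <- state$family
      # scan three consensus windows as synthetic epitopes
      n <- nchar(fam$consensus)
      starts <- c(5L, n %/% 2L, n - 20L)
      epis <- tibble(name = paste0("window_", starts),
                     sequence = substr(rep(fam$consensus, 3), starts, starts + 7L),
                     reference_start = starts)
      scan <- epitope_scan(epis, fam$loci, fam$consensus)
      readr::write_tsv(scan, out_path("epitope_scan.tsv"), progress = FALSE)
      record_output(out_path("epitope_scan.tsv"))
    },
    orthogonalize = function(cfg) {
      assert_that(!is.null(state$family), "orthogonalize needs the simulate stage")
      fam <- state$family
      digests <- map(seq_len(nrow(fam$loci)), function(i) {
        digest_protein(fam$loci$protein[i], 0) |>
          filter(nchar(.data$peptide) >= 7) |>
          mutate(locus_id = fam$loci$locus_id[i])
      }) |> bind_rows()
      support <- digests |> distinct(.data$peptide, .data$locus_id)
      ortho <- orthogonalize_loci(support, fam$loci, fam$consensus)
      readr::write_tsv(tibble(locus_id = ortho$retained),
                       out_path("orthogonalized_loci.tsv"), progress = FALSE)
      readr::write_tsv(ortho$peptide_map, out_path("peptide_representatives.tsv"),
                       progress = FALSE)
      record_output(out_path("orthogonalized_loci.tsv"))
      record_output(out_path("peptide_representatives.tsv"))
    },
    lfq_run = function(cfg) {
      input <- cfg$lfq$input %||% out_path("intensities.tsv")
      raw <- read_intensity_table(input)
      mat <- preprocess_intensities(raw, exclusions = cfg$lfq$exclusions %||% "IGHG1")
      groups <- list(case = cfg$lfq$case, control = cfg$lfq$control)
      mat <- impute_lfq(mat, groups, seed = cfg$seed + 3L)
      cmp <- lfq_compare(mat, groups$case, groups$control,
                         label = cfg$lfq$label %||% "case_vs_control",
                         alpha = cfg$lfq$alpha %||% 0.05,
                         lfc_threshold = cfg$lfq$lfc_threshold %||% 1)
      readr::write_tsv(tidy(cmp), out_path("lfq_comparison.tsv"), progress = FALSE)
      record_output(out_path("lfq_comparison.tsv"))
      integration <- integrate_comparisons(setNames(list(cmp),
                                                    attr(cmp, "label")))
      readr::write_tsv(integration$tiers, out_path("lfq_tiers.tsv"), progress = FALSE)
      record_output(out_path("lfq_tiers.tsv"))
    },
    band_rank = function(cfg) {
      assert_that(!is.null(cfg$band_rank$input), "band_rank needs `band_rank.input`")
      ids <- readr::read_tsv(cfg$band_rank$input, show_col_types = FALSE, progress = FALSE)
      ranked <- rank_band_ids(ids, trypsin_id = cfg$band_rank$trypsin_id %||% "TRYP_PIG")
      readr::write_tsv(ranked, out_path("band_ids_ranked.tsv"), progress = FALSE)
      record_output(out_path("band_ids_ranked.tsv"))
    }
  )

  for (stage in config$stages) {
    t0 <- Sys.time()
    result <- tryCatch({
      stage_fns[[stage]](config)
      "ok"
    }, error = function(e) conditionMessage(e))
    manifest$stages[[stage]] <- list(
      status = if (identical(result, "ok")) "ok" else "failed",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      error = if (identical(result, "ok")) NULL else result
    )
    if (!identical(result, "ok")) {
      manifest$status <- paste0("failed at stage '", stage, "'")
      write_manifest_atomically(manifest, file.path(out_dir, "manifest.json"))
      abort(paste0("pipeline stage '", stage, "' failed: ", result),
            class = "retroproteo_pipeline_error")
    }
  }
  manifest$status <- "ok"
  manifest$output_digests <- as.list(tools::md5sum(manifest$outputs))
  write_manifest_atomically(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
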