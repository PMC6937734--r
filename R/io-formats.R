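# Readers/writers for the file dialects the pipeline touches. All parsing is
# isolated here; downstream code only ever sees tibbles (and never tests for
# zero as a missing-value sentinel -- zeros are converted at the boundary).

#' Read a FASTA file into a tibble of sequence entries
#'
#' One row per record. The identifier is the header token up to the first
#' whitespace and must be unique within the file; the remainder of the header
#' becomes the description. Sequences are uppercased and `*` stop symbols are
#' stripped (with a message).
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `identifier`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)),
                              class = "retroproteo_format_error")
  )
  if (length(set) == 0) {
    abort(paste0("empty FASTA file: ", path), class = "retroproteo_format_error")
  }
  headers <- names(set)
  identifier <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- identifier[duplicated(identifier)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", ")),
          class = "retroproteo_format_error")
  }
  residues <- toupper(as.character(set))
  if (any(grepl("*", residues, fixed = TRUE))) {
    inform("stripping '*' stop symbols from sequences")
    residues <- gsub("*", "", residues, fixed = TRUE)
  }
  assert_that(all(nzchar(residues)), "FASTA contains an empty sequence")
  tibble(identifier = identifier, description = description,
         residues = unname(residues))
}

#' Write sequence entries to a FASTA file
#'
#' @param entries Tibble with `identifier`, `residues` and optionally
#'   `description` columns, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for the sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path, width = 60L) {
  assert_that(all(c("identifier", "residues") %in% names(entries)),
              "`entries` must have columns `identifier` and `residues`")
  desc <- if ("description" %in% names(entries)) entries$description else ""
  headers <- ifelse(nzchar(desc), paste(entries$identifier, desc), entries$identifier)
  set <- Biostrings::BStringSet(entries$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# "3:15.9949:Oxidation;7:0.984016:Deamidation" -> tibble(position, mass_shift, name)
parse_modifications <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble(position = integer(), mass_shift = double(), name = character()))
  }
  parts <- strsplit(strsplit(text, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble(
    position = as.integer(map_chr(parts, 1)),
    mass_shift = as.double(map_chr(parts, 2)),
    name = map_chr(parts, function(p) if (length(p) >= 3) p[3] else NA_character_)
  )
}

#' Read a simplified tab-separated PSM report
#'
#' The dialect is one row per peptide-spectrum match with header columns
#' `spectrum`, `peptide`, `prev_aa`, `next_aa`, `proteins`, `evalue`,
#' `modifications` (extra columns are carried through). `proteins` is a
#' semicolon-joined assignment list; `modifications` holds semicolon-joined
#' `position:mass[:name]` triples; an empty or `-` flank means protein
#' terminus.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `spectrum_id`, `peptide`, `prev_aa`, `next_aa`,
#'   `assignments` (list of character vectors), `evalue`, and `modifications`
#'   (list of tibbles).
#' @export
read_psm_table <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("spectrum", "peptide", "prev_aa", "next_aa", "proteins", "evalue",
              "modifications")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("PSM table lacks required column(s): ", paste(missing_cols, collapse = ", ")),
          class = "retroproteo_format_error")
  }
  ev <- suppressWarnings(as.double(raw$evalue))
  bad <- which(is.na(ev) | ev < 0)
  if (length(bad) > 0) {
    abort(sprintf("unparsable or negative e-value '%s' at line %d of %s",
                  raw$evalue[bad[1]], bad[1] + 1L, path),
          class = "retroproteo_format_error")
  }
  assert_that(all(nchar(raw$peptide) >= 1), "every PSM needs a non-empty peptide")
  tibble(
    spectrum_id = raw$spectrum,
    peptide = toupper(raw$peptide),
    prev_aa = ifelse(is.na(raw$prev_aa) | !nzchar(raw$prev_aa), "-", raw$prev_aa),
    next_aa = ifelse(is.na(raw$next_aa) | !nzchar(raw$next_aa), "-", raw$next_aa),
    assignments = strsplit(raw$proteins, ";", fixed = TRUE),
    evalue = ev,
    modifications = map(raw$modifications, parse_modifications)
  )
}

#' Read a MaxQuant proteinGroups-style intensity table
#'
#' Expects a TSV with a `Protein IDs` column (semicolon-joined group members
#' are preserved verbatim), any number of `LFQ intensity <sample>` columns,
#' and optional `Reverse` / `Potential contaminant` columns whose `+` marker
#' sets the corresponding flag. Empty cells are read as 0, the MaxQuant
#' missing-value convention; [preprocess_intensities()] converts them to an
#' explicit mask immediately.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `protein_id`, logical `reverse` and `contaminant`
#'   columns, and one non-negative numeric column per sample (named by the
#'   `LFQ intensity ` suffix).
#' @export
read_intensity_table <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_that("Protein IDs" %in% names(raw), "missing 'Protein IDs' column")
  lfq_cols <- grep("^LFQ intensity ", names(raw), value = TRUE)
  if (length(lfq_cols) == 0) {
    abort("no 'LFQ intensity <sample>' columns found", class = "retroproteo_format_error")
  }
  samples <- sub("^LFQ intensity ", "", lfq_cols)
  flag <- function(col) {
    if (col %in% names(raw)) !is.na(raw[[col]]) & raw[[col]] == "+" else rep(FALSE, nrow(raw))
  }
  values <- map(lfq_cols, function(col) {
    v <- suppressWarnings(as.double(raw[[col]]))
    v[is.na(v)] <- 0
    assert_that(all(v >= 0), paste0("negative intensity in column '", col, "'"))
    v
  })
  out <- tibble(protein_id = raw[["Protein IDs"]],
                reverse = flag("Reverse"),
                contaminant = flag("Potential contaminant"))
  out[samples] <- values
  out
}

#' Write an intensity tibble back out in the proteinGroups dialect
#'
#' Inverse of [read_intensity_table()]; used by the synthetic generators to
#' produce on-disk fixtures.
#'
#' @param table Tibble in the shape returned by [read_intensity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path) {
  samples <- setdiff(names(table), c("protein_id", "reverse", "contaminant"))
  out <- tibble("Protein IDs" = table$protein_id,
                "Reverse" = ifelse(table$reverse, "+", ""),
                "Potential contaminant" = ifelse(table$contaminant, "+", ""))
  for (s in samples) out[[paste0("LFQ intensity ", s)]] <- table[[s]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Parses standard `BEGIN IONS`/`END IONS` blocks. No installed R package
#' reads MGF, so this parser is local; it captures `TITLE`, `PEPMASS` and
#' `CHARGE` when present and sorts peaks ascending by m/z.
#'
#' @param path Path to the MGF file.
#' @return A named list of spectra, one per block in file order. Each spectrum
#'   is a tibble with `mz`, `intensity` and attributes `title`,
#'   `precursor_mz`, `precursor_charge` (NA when absent). Names are the
#'   spectrum titles (or `spectrum_<i>` when untitled).
#' @export
read_mgf <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] != "BEGIN IONS") {
      abort(sprintf("unexpected content outside BEGIN IONS/END IONS block: '%s'", lines[i]),
            class = "retroproteo_format_error")
    }
    j <- i + 1L
    title <- NA_character_
    pepmass <- NA_real_
    charge <- NA_integer_
    mz <- double()
    intensity <- double()
    terminated <- FALSE
    while (j <= n) {
      ln <- lines[j]
      if (ln == "END IONS") {
        terminated <- TRUE
        break
      } else if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^PEPMASS=", ln)) {
        pepmass <- as.double(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
      } else if (grepl("^CHARGE=", ln)) {
        charge <- as.integer(sub("[+-]$", "", sub("^CHARGE=", "", ln)))
      } else if (grepl("^[A-Z]+=", ln)) {
        # other headers ignored
      } else {
        fields <- strsplit(ln, "[\t ]+")[[1]]
        mz <- c(mz, as.double(fields[1]))
        intensity <- c(intensity, if (length(fields) > 1) as.double(fields[2]) else 0)
      }
      j <- j + 1L
    }
    if (!terminated) {
      abort("unterminated BEGIN IONS block (missing END IONS)",
            class = "retroproteo_format_error")
    }
    ord <- order(mz)
    sp <- tibble(mz = mz[ord], intensity = intensity[ord])
    attr(sp, "title") <- title
    attr(sp, "precursor_mz") <- pepmass
    attr(sp, "precursor_charge") <- charge
    spectra[[length(spectra) + 1L]] <- sp
    i <- j + 1L
  }
  names(spectra) <- map_chr(seq_along(spectra), function(k) {
    t <- attr(spectra[[k]], "title")
    if (is.na(t)) paste0("spectrum_", k) else t
  })
  spectra
}

#' Write spectra to an MGF peak-list file
#'
#' @param spectra List of spectra as returned by [read_mgf()] or
#'   [simulate_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(spectra)) {
    sp <- spectra[[k]]
    writeLines("BEGIN IONS", con)
    title <- attr(sp, "title") %||% names(spectra)[k]
    if (!is.null(title) && !is.na(title)) writeLines(paste0("TITLE=", title), con)
    pm <- attr(sp, "precursor_mz")
    if (!is.null(pm) && !is.na(pm)) writeLines(sprintf("PEPMASS=%.6f", pm), con)
    ch <- attr(sp, "precursor_charge")
    if (!is.null(ch) && !is.na(ch)) writeLines(sprintf("CHARGE=%d+", ch), con)
    if (nrow(sp) > 0) {
      writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
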