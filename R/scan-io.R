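#' Write a scan table to tab-separated text
#'
#' One row per marker-architecture entry: markers with several architecture
#' labels (e.g. partial dominance, `{D-, A}`) produce stacked rows sharing
#' the marker fields. Columns: `Chr`, `MB` (1 decimal), `cM`, `Marker`, `P`,
#' `r2`, `Form`, `P_arch`, `HighPDAllele`, `FDR_pass`, `Locus`. A commented
#' header block records the cohort, trait, strains and the full scan
#' configuration with its hash, so every output is reproducible from its
#' header.
#'
#' @param scan A `pd_scan`.
#' @param out_path Output file path.
#' @param consensus Optional result of [consensus_loci()]; fills the `Locus`
#'   column from its marker assignments.
#' @return `out_path`, invisibly.
#' @export
write_scan_table <- function(scan, out_path, consensus = NULL) {
  stopifnot(inherits(scan, "pd_scan"))
  assignments <- if (!is.null(consensus)) attr(consensus, "assignments")
  header <- c(
    "# dispscan scan table",
    paste0("# cohort: ", scan$cohort),
    paste0("# trait: ", scan$trait),
    paste0("# strains: ", paste(scan$strains, collapse = ",")),
    paste0("# config: ", jsonlite::toJSON(
      scan$config[!map_lgl(scan$config, is.null)], auto_unbox = TRUE
    )),
    paste0("# config_hash: ", config_hash(scan$config))
  )
  tab <- scan$table
  if (nrow(tab) == 0L) {
    rows <- tibble(
      Chr = character(), MB = numeric(), cM = numeric(), Marker = character(),
      P = numeric(), r2 = numeric(), Form = character(), P_arch = numeric(),
      HighPDAllele = character(), FDR_pass = logical(), Locus = character()
    )
  } else {
    rows <- purrr::pmap(
      list(seq_len(nrow(tab))),
      function(i) {
        forms <- tab$forms[[i]]
        if (is.null(forms) || nrow(forms) == 0L) {
          forms <- tibble(form = ".", p_arch = NA_real_,
                          high_allele = NA_character_)
        }
        locus <- "."
        if (!is.null(assignments)) {
          hit <- assignments$locus[assignments$marker == tab$marker[i] &
                                     assignments$cohort == scan$cohort]
          if (length(hit)) locus <- hit[1]
        }
        tibble(
          Chr = as.character(tab$chr[i]),
          MB = round(tab$pos_bp[i] / 1e6, 1),
          cM = tab$pos_cm[i],
          Marker = tab$marker[i],
          P = tab$p_joint[i],
          r2 = tab$r2[i],
          Form = forms$form,
          P_arch = forms$p_arch,
          HighPDAllele = dplyr::coalesce(forms$high_allele, "."),
          FDR_pass = tab$reject[i],
          Locus = locus
        )
      }
    ) |> bind_rows()
  }
  readr::write_lines(header, out_path)
  readr::write_tsv(rows, out_path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(out_path)
}

#' Read a scan table written by [write_scan_table()]
#'
#' @param path Path to the TSV file.
#' @return Tibble of the table rows, with the header metadata attached as
#'   attributes `cohort`, `trait`, `strains`, `config_hash`.
#' @export
read_scan_table <- function(path) {
  hdr <- readr::read_lines(path, n_max = 50L, progress = FALSE)
  hdr <- hdr[startsWith(hdr, "# ")]
  grab <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  tab <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_types = readr::cols(
      Chr = readr::col_character(), MB = readr::col_double(),
      cM = readr::col_double(), Marker = readr::col_character(),
      P = readr::col_double(), r2 = readr::col_double(),
      Form = readr::col_character(), P_arch = readr::col_double(),
      HighPDAllele = readr::col_character(),
      FDR_pass = readr::col_logical(), Locus = readr::col_character()
    )
  )
  structure(tab,
            cohort = grab("cohort"), trait = grab("trait"),
            strains = strsplit(grab("strains") %||% "", ",")[[1]],
            config_hash = grab("config_hash"))
}
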