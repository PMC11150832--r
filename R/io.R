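## Readers and writers: Mascot Generic Format peak lists, delimited tables
## and the run configuration. All writers are deterministic given their
## input (stable row order, fixed 4-decimal m/z formatting).

#' Read a Mascot Generic Format (MGF) peak list
#'
#' Parses `BEGIN IONS`/`END IONS` blocks; `PEPMASS`, `RTINSECONDS`,
#' `CHARGE` and `TITLE` headers are honoured. Peaks are sorted by m/z. A
#' block without `PEPMASS` yields a spectrum with `NA` precursor, which is
#' unusable for MS2 annotation (annotation raises an error on it).
#'
#' @param path Path to an MGF file.
#' @return A list of `spectrum` objects (empty, with a warning, if the
#'   file holds no blocks).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    warning("empty MGF file: ", path)
    return(list())
  }
  spectra <- list()
  in_block <- FALSE
  title <- NA_character_; prec <- NA_real_; rt <- NA_real_
  mzs <- numeric(0); ints <- numeric(0); block_line <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("malformed MGF: nested BEGIN IONS at line ", i)
      in_block <- TRUE; block_line <- i
      title <- NA_character_; prec <- NA_real_; rt <- NA_real_
      mzs <- numeric(0); ints <- numeric(0)
    } else if (ln == "END IONS") {
      if (!in_block) stop("malformed MGF: END IONS without BEGIN at line ",
                          i)
      spectra[[length(spectra) + 1L]] <- new_spectrum(
        data.frame(mz = mzs, intensity = ints),
        precursor_mz = prec, retention_time = rt, level = 2L, id = title)
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") title <- val
      else if (key == "PEPMASS") {
        prec <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]][1]))
        if (is.na(prec)) stop("malformed PEPMASS at line ", i)
      } else if (key == "RTINSECONDS") {
        rt <- suppressWarnings(as.numeric(val)) / 60
      }
      ## CHARGE and other headers are accepted silently
    } else if (in_block) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) < 2 || anyNA(vals[1:2])) {
        stop("malformed peak line ", i, ": '", ln, "'")
      }
      mzs <- c(mzs, vals[1]); ints <- c(ints, vals[2])
    } else {
      stop("content outside BEGIN/END IONS block at line ", i)
    }
  }
  if (in_block) stop("malformed MGF: unterminated block starting at line ",
                     block_line)
  if (length(spectra) == 0) warning("MGF file holds no spectra: ", path)
  spectra
}

#' Write spectra to a Mascot Generic Format file
#'
#' @param spectra A list of `spectrum` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(sp$id)) writeLines(paste0("TITLE=", sp$id), con)
    if (!is.na(sp$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.4f", sp$precursor_mz), con)
    }
    if (!is.na(sp$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.2f", sp$retention_time * 60), con)
    }
    writeLines("CHARGE=1+", con)
    if (nrow(sp$peaks) > 0) {
      writeLines(sprintf("%.4f %.4f", sp$peaks$mz, sp$peaks$intensity),
                 con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a delimited table (comma or tab separated, header required)
#'
#' @param path Input path; the separator is sniffed from the header line.
#' @return A data.frame.
#' @export
read_table_auto <- function(path) {
  header <- readLines(path, n = 1)
  if (length(header) == 0) stop("empty table file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a delimited table
#'
#' @param df A data.frame.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_table_auto <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All defaults match the analysis conventions of the modelled workflow:
#' 3 ppm MS1 tolerance, 5 ppm MS2 tolerance, chains of 14-17 carbons,
#' 0-4 ether bonds, M+1 summing for cardiolipins.
#'
#' @return A named list (`run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    ms1_tol_ppm = 3,
    ms2_tol_ppm = 5,
    chain_lengths = 14:17,
    ether_counts = 0:4,
    include_lyso = TRUE,
    include_r6 = FALSE,
    quant_m1 = "sum",
    scenario = "mix",
    mix_weights = c(0.5, 0.5),
    seed = 1L,
    output_dir = "."
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_run_config()]. `write_run_config()` then `read_run_config()`
#' round-trips.
#'
#' @param path Path to a YAML (or plain `key: value`) file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(vals)) {
    v <- vals[[k]]
    if (is.numeric(cfg[[k]])) v <- as.numeric(v)
    if (is.integer(cfg[[k]])) v <- as.integer(v)
    cfg[[k]] <- v
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
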