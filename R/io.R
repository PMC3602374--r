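# Delimited-text formats.  Numbers are written with %.17g so every
# table round-trips through its reader bit-identically.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write / read a fluorescence transient as CSV
#'
#' Columns `flashlet_index`, `time_us`, `fluorescence`; the protocol and
#' acclimation state are stored in `#`-prefixed header comment lines
#' (schema `cyanophys-transient v1`), so the reader reconstructs the
#' full [frr_transient()].
#'
#' @param transient An [frr_transient()].
#' @param path File path.
#' @return `write_transient_csv` returns `path` invisibly;
#'   `read_transient_csv` returns an [frr_transient()].
#' @export
write_transient_csv <- function(transient, path) {
  stopifnot(inherits(transient, "frr_transient"))
  p <- transient$protocol
  hdr <- c(
    "# cyanophys-transient v1",
    sprintf(
      "# n_flashlets=%d flash_duration_us=%s dark_interval_us=%s wavelength_nm=%s flash_intensity=%s acclimation=%s",
      p$n_flashlets, fmt_num(p$flash_duration_us), fmt_num(p$dark_interval_us),
      fmt_num(p$wavelength_nm), fmt_num(p$flash_intensity),
      as.character(transient$acclimation)
    ),
    "flashlet_index,time_us,fluorescence"
  )
  rows <- sprintf("%d,%s,%s", seq_along(transient$values),
                  fmt_num(transient$times_us), fmt_num(transient$values))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_transient_csv
#' @export
read_transient_csv <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# cyanophys-transient", lines[1])) {
    stop_data("not a cyanophys transient file: ", path)
  }
  meta <- lines[2]
  get_field <- function(nm) {
    m <- regmatches(meta, regexpr(paste0(nm, "=[^ ]+"), meta))
    sub(paste0(nm, "="), "", m)
  }
  protocol <- flashlet_protocol(
    n_flashlets = as.integer(get_field("n_flashlets")),
    flash_duration_us = as.numeric(get_field("flash_duration_us")),
    dark_interval_us = as.numeric(get_field("dark_interval_us")),
    wavelength_nm = as.numeric(get_field("wavelength_nm")),
    flash_intensity = as.numeric(get_field("flash_intensity"))
  )
  acc <- get_field("acclimation")
  if (acc != "dark") acc <- as.numeric(acc)
  d <- utils::read.csv(textConnection(lines[-(1:2)]),
                       colClasses = c(flashlet_index = "integer",
                                      time_us = "numeric",
                                      fluorescence = "numeric"))
  frr_transient(d$time_us, d$fluorescence, protocol, acclimation = acc)
}

#' Write / read an immunoblot sheet as CSV
#'
#' Columns `lane`, `role` (`standard`/`sample`), `load_fmol`,
#' `ug_loaded`, `volume`, as produced by [simulate_blot()].
#'
#' @param blot Blot data frame.
#' @param path File path.
#' @export
write_blot_csv <- function(blot, path) {
  hdr <- c("# cyanophys-blot v1", "lane,role,load_fmol,ug_loaded,volume")
  rows <- sprintf("%d,%s,%s,%s,%s", blot$lane, blot$role,
                  fmt_num(blot$load_fmol), fmt_num(blot$ug_loaded),
                  fmt_num(blot$volume))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_blot_csv
#' @export
read_blot_csv <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# cyanophys-blot", lines[1])) {
    stop_data("not a cyanophys blot file: ", path)
  }
  utils::read.csv(textConnection(lines[-1]),
                  colClasses = c(lane = "integer", role = "character",
                                 load_fmol = "numeric",
                                 ug_loaded = "numeric",
                                 volume = "numeric"))
}

#' Write / read a long-format replicate table as TSV
#'
#' Columns `quantity`, `strain`, `time_h`, `replicate`, `value` — the
#' exchange format between the quantitation stages and the time-course
#' statistics.
#'
#' @param d Long-format data frame with those columns.
#' @param path File path.
#' @export
write_long_tsv <- function(d, path) {
  hdr <- c("# cyanophys-long v1",
           "quantity\tstrain\ttime_h\treplicate\tvalue")
  rows <- sprintf("%s\t%s\t%s\t%s\t%s", d$quantity, d$strain,
                  fmt_num(d$time_h), as.character(d$replicate),
                  fmt_num(d$value))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_long_tsv
#' @export
read_long_tsv <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# cyanophys-long", lines[1])) {
    stop_data("not a cyanophys long-format file: ", path)
  }
  utils::read.delim(textConnection(lines[-1]),
                    colClasses = c(quantity = "character",
                                   strain = "character",
                                   time_h = "numeric",
                                   replicate = "character",
                                   value = "numeric"))
}

#' Build a time course from a long-format table
#'
#' @param d Long-format data frame (`time_h`, `value`, optionally
#'   `quantity`/`strain` already filtered to one series).
#' @inheritParams time_course
#' @return A [time_course()].
#' @export
as_time_course <- function(d, quantity = NA, strain = NA, units = NA) {
  tp <- sort(unique(d$time_h))
  time_course(tp, lapply(tp, function(t) d$value[d$time_h == t]),
              quantity = quantity, strain = strain, units = units)
}

#' Read a generator scenario from YAML
#'
#' A scenario describes a full synthetic experiment: strains, their
#' generator parameter blocks, timepoints, replicate counts and the
#' root seed.  See [default_scenario()] for the reference structure.
#'
#' @param path YAML file path.
#' @return A scenario list.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  if (is.null(sc$seed)) stop_data("scenario must set a seed for synthetic runs")
  if (is.null(sc$timepoints_h) || length(sc$timepoints_h) < 2) {
    stop_data("scenario must list at least 2 timepoints")
  }
  if (!0 %in% sc$timepoints_h) stop_data("scenario must include timepoint 0")
  if (is.null(sc$strains) || !length(sc$strains)) {
    stop_data("scenario must define at least one strain block")
  }
  need <- c("name", "n_replicates", "growth", "frr", "pe", "subunits",
            "blot")
  for (st in sc$strains) {
    missing <- setdiff(need, names(st))
    if (length(missing)) {
      stop_data("strain block ", st$name %||% "?", " missing: ",
                paste(missing, collapse = ", "))
    }
  }
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
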