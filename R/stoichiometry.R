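# Chlorophylls bound per monomer of each complex: 12 per IsiA, 100 per
# PSI, 36 per PSII.
CHL_PER_ISIA <- 12
CHL_PER_PSI <- 100
CHL_PER_PSII <- 36
# AtpB (beta) subunits per ATP synthase complex; also its number of
# catalytic sites.
ATPB_PER_COMPLEX <- 3

#' Photosystem and complex stoichiometries from subunit abundances
#'
#' Computes molar ratios between thylakoid complexes from marker-subunit
#' abundances (fmol per ug total protein), treating each marker as a 1:1
#' proxy for its complex: PsaC for PSI, PsbA (D1) for PSII, PetC
#' (Rieske) for cytochrome b6f, and AtpB (beta) for ATP synthase with 3
#' AtpB per complex.  All ratios are normalised to PSII (PsbA).  Note
#' that PsbA content includes subunits engaged in the PSII repair cycle
#' and is therefore an upper bound on active PSII centres; the ratios
#' carry that assumption.
#'
#' @param quants Named numeric vector of subunit abundances in
#'   fmol per ug total protein; recognised names are `PsbA`, `PsaC`,
#'   `PetC`, `AtpB`, `IsiA`.  `PsbA` is mandatory and must be > 0.
#'   Missing subunits yield `NA` (absent, not zero) ratios.
#' @param timepoint,strain Optional metadata carried into the report.
#' @return A `stoichiometry_report` list: `psi_per_psii`,
#'   `isia_per_psi`, `cytb6f_per_psii`, `atpsynthase_per_psii`
#'   (complexes per PSII), `catalytic_sites_per_psii`
#'   (= 3 x complexes, exactly), plus metadata.  Values are unrounded;
#'   rounding to the conventional printed precision happens only in
#'   `format()`/`print()`.
#' @export
#' @examples
#' complex_ratios(c(PsbA = 40, PsaC = 92, AtpB = 55.2, IsiA = 10))
complex_ratios <- function(quants, timepoint = NA, strain = NA) {
  q <- function(nm) {
    if (nm %in% names(quants) && !is.na(quants[[nm]])) quants[[nm]] else NA_real_
  }
  psbA <- q("PsbA")
  if (is.na(psbA)) stop_data("PsbA abundance is required")
  if (psbA <= 0) stop_data("undefined PSII-normalised ratio: PsbA is 0")
  if (any(quants < 0, na.rm = TRUE)) stop_data("abundances must be >= 0")
  psaC <- q("PsaC"); petC <- q("PetC"); atpB <- q("AtpB"); isiA <- q("IsiA")
  atps <- (atpB / ATPB_PER_COMPLEX) / psbA
  structure(
    list(
      psi_per_psii = psaC / psbA,
      isia_per_psi = if (!is.na(isiA) && !is.na(psaC)) {
        if (psaC > 0) isiA / psaC else NA_real_
      } else NA_real_,
      cytb6f_per_psii = petC / psbA,
      atpsynthase_per_psii = atps,
      catalytic_sites_per_psii = ATPB_PER_COMPLEX * atps,
      timepoint = timepoint, strain = strain
    ),
    class = "stoichiometry_report"
  )
}

# Printed precision convention: 1 decimal for ratios >= 1, 2 decimals
# below 1; catalytic sites to 1 decimal unless below 1.
round_ratio <- function(x, digits_ge1 = 1, digits_lt1 = 2) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) >= 1, round(x, digits_ge1), round(x, digits_lt1)))
}

#' @export
format.stoichiometry_report <- function(x, ...) {
  c(
    psi_per_psii = round_ratio(x$psi_per_psii),
    isia_per_psi = round_ratio(x$isia_per_psi),
    cytb6f_per_psii = round_ratio(x$cytb6f_per_psii),
    atpsynthase_per_psii = round_ratio(x$atpsynthase_per_psii),
    catalytic_sites_per_psii = round(x$catalytic_sites_per_psii, 1)
  )
}

#' @export
print.stoichiometry_report <- function(x, ...) {
  v <- format(x)
  cat("Complex stoichiometries (mol/mol, PSII-normalised):\n")
  cat(sprintf("  PSI : PSII            %s\n", v[["psi_per_psii"]]))
  cat(sprintf("  IsiA : PSI            %s\n", v[["isia_per_psi"]]))
  cat(sprintf("  Cyt b6f : PSII        %s\n", v[["cytb6f_per_psii"]]))
  cat(sprintf("  ATP synthase : PSII   %s (%s catalytic sites)\n",
              v[["atpsynthase_per_psii"]],
              v[["catalytic_sites_per_psii"]]))
  invisible(x)
}

#' IsiA per PSI molar ratio
#'
#' @param isia IsiA abundance, fmol per ug (>= 0).
#' @param psaC PsaC abundance (PSI proxy), fmol per ug (> 0).
#' @return IsiA per PSI monomer, mol/mol.
#' @export
#' @examples
#' isia_per_psi(18, 3)                 # a full 18mer ring on a trimer
isia_per_psi <- function(isia, psaC) {
  if (isia < 0) stop_data("isia must be >= 0")
  if (!(psaC > 0)) stop_data("psaC must be > 0")
  isia / psaC
}

#' Convert an IsiA-per-PSI-trimer ratio to per PSI monomer
#'
#' PSI occurs as trimers in many cyanobacteria; structural ratios are
#' often quoted per trimer (e.g. an 18mer IsiA ring around a PSI trimer
#' is 6 IsiA per PSI monomer).
#'
#' @param per_trimer IsiA per PSI trimer, mol/mol.
#' @return IsiA per PSI monomer (per_trimer / 3).
#' @export
per_trimer_to_per_monomer <- function(per_trimer) {
  if (any(per_trimer < 0)) stop_data("ratio must be >= 0")
  per_trimer / 3
}

#' Chlorophyll-allocation budget
#'
#' Partitions cellular chlorophyll (fmol chl per ug total protein) among
#' the three major chlorophyll-binding pools using fixed binding
#' stoichiometries: 12 chl per IsiA monomer, 100 per PSI monomer (via
#' PsaC) and 36 per PSII monomer (via PsbA, or PsbD as an alternate
#' PSII proxy).
#'
#' @param quants Named numeric vector with `IsiA`, `PsaC` and `PsbA`
#'   (or `PsbD` when `use_psbd = TRUE`), fmol per ug total protein.
#' @param use_psbd Use PsbD instead of PsbA as the PSII proxy.
#' @param timepoint,strain Optional metadata.
#' @return A `chlorophyll_budget` list: `chl_isia`, `chl_psi`,
#'   `chl_psii` and `total` (their exact sum), all in
#'   fmol chl per ug total protein.
#' @export
#' @examples
#' chlorophyll_budget(c(IsiA = 662, PsaC = 40, PsbA = 38))
chlorophyll_budget <- function(quants, use_psbd = FALSE,
                               timepoint = NA, strain = NA) {
  psii_proxy <- if (use_psbd) "PsbD" else "PsbA"
  need <- c("IsiA", "PsaC", psii_proxy)
  missing <- setdiff(need, names(quants))
  if (length(missing)) {
    stop_data("missing subunit abundances: ", paste(missing, collapse = ", "))
  }
  if (any(quants[need] < 0, na.rm = TRUE)) stop_data("abundances must be >= 0")
  chl_isia <- CHL_PER_ISIA * quants[["IsiA"]]
  chl_psi <- CHL_PER_PSI * quants[["PsaC"]]
  chl_psii <- CHL_PER_PSII * quants[[psii_proxy]]
  structure(
    list(
      chl_isia = chl_isia, chl_psi = chl_psi, chl_psii = chl_psii,
      total = chl_isia + chl_psi + chl_psii,
      psii_proxy = psii_proxy, timepoint = timepoint, strain = strain
    ),
    class = "chlorophyll_budget"
  )
}

#' @export
print.chlorophyll_budget <- function(x, ...) {
  cat("Chlorophyll budget (fmol chl / ug total protein):\n")
  cat(sprintf("  IsiA pool   %8.1f\n", x$chl_isia))
  cat(sprintf("  PSI pool    %8.1f\n", x$chl_psi))
  cat(sprintf("  PSII pool   %8.1f  (proxy: %s)\n", x$chl_psii, x$psii_proxy))
  cat(sprintf("  total       %8.1f\n", x$total))
  invisible(x)
}
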