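#' Reference synthetic scenario
#'
#' A two-strain iron-depletion experiment over 0/48/96/120 h with 6
#' (first strain) or 5 (second strain) replicate cultures, emulating
#' the conditions the analysis chain is designed for: exponential
#' growth at 0.019 / 0.016 h^-1 slowing after 72 h; large red-light
#' sigma_PSII (381 / 412 A^2) versus small blue-light sigma (79 / 71
#' A^2); IsiA induction following a logistic to a plateau near 662
#' fmol/ug while PSI (PsaC) declines; and a P-E response whose Pmax
#' and EK decline over the depletion (96 to 59 and 90 to 65 for the
#' first strain).  Subunit trajectories other than IsiA interpolate
#' linearly between their start and end values.
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @return A scenario list accepted by [run_pipeline()].
#' @export
default_scenario <- function(seed = 1) {
  strain <- function(name, n, mu, sig_red, sig_blue, pe0, pe1, subunits) {
    list(
      name = name, n_replicates = n,
      growth = list(mu = mu, A0 = 0.10, onset_h = 72, tau_h = 48,
                    noise_sd = 0.02),
      frr = list(Fo = 1.0, Fm = 3.0, sigma_red = sig_red,
                 sigma_blue = sig_blue, noise_sd = 0.01,
                 actinic = c(66, 262)),
      pe = list(Pmax_start = pe0[1], EK_start = pe0[2],
                Pmax_end = pe1[1], EK_end = pe1[2],
                irradiances = c(0, 25, 50, 66, 100, 150, 262, 400)),
      subunits = subunits,
      # standards are prepared at loads appropriate for each protein:
      # the ladder is this relative series scaled to the target's
      # maximal abundance over the time course
      blot = list(standard_rel = c(0.05, 0.25, 1, 2), ug_loaded = 1,
                  noise_cv = 0.05)
    )
  }
  list(
    timepoints_h = c(0, 48, 96, 120),
    seed = seed,
    strains = list(
      strain("PCC7942", 6, 0.019, 381, 79, c(96, 90), c(59, 65),
             list(
               PsbA = list(start = 40, end = 38),
               PsbD = list(start = 40, end = 38),
               PsaC = list(start = 92, end = 16),
               PetC = list(start = 10, end = 7),
               AtpB = list(start = 2.4, end = 3.4),
               IsiA = list(logistic = list(A = 662, k = 0.10, t0 = 24))
             )),
      strain("PCC6803", 5, 0.016, 412, 71, c(179, 100), c(157, 90),
             list(
               PsbA = list(start = 40, end = 40),
               PsbD = list(start = 40, end = 40),
               PsaC = list(start = 80, end = 40),
               PetC = list(start = 12, end = 8),
               AtpB = list(start = 55.2, end = 27.6),
               IsiA = list(start = 24, end = 480)
             ))
    )
  )
}

# Ground-truth subunit abundance at time t from a trajectory block.
subunit_truth <- function(block, t, t_max) {
  if (!is.null(block$logistic)) {
    g <- block$logistic
    g$A / (1 + exp(-g$k * (t - g$t0)))
  } else {
    block$start + (block$end - block$start) * t / t_max
  }
}

#' Run the full analysis chain on a synthetic scenario
#'
#' Generates every input the pipeline consumes (growth series, dark and
#' light-step FRR transients at red and blue wavelengths, P-E driven
#' light-step series, immunoblots for six subunits), runs each analysis
#' stage on the generated data, and collects the summary tables:
#' growth rates, sigma_PSII (red/blue) and Fv/Fm, light-step qP and
#' Phi_PSII, electron-transport light-response points per PSII and per
#' ug protein, P-E fits, subunit time courses, complex stoichiometries,
#' the chlorophyll budget, and Dunnett tables for IsiA and PsaC.
#' Deterministic given the scenario seed.  A stage that fails is
#' recorded in `$errors` with its stage name and the pipeline
#' continues, leaving that output absent.
#'
#' @param scenario A scenario list ([default_scenario()] or
#'   [read_scenario()]).
#' @param out_dir Optional directory; when given, every table is
#'   written as TSV plus a `summary.json`, and a `run_log.json` records
#'   the scenario parameters and output checksums.
#' @return A `pipeline_result` list of data frames: `growth`, `sigma`,
#'   `light_steps`, `etr_points`, `pe_fits`, `subunits`, `ratios`,
#'   `budget`, `dunnett`, plus `errors`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(default_scenario(seed = 1))
#' res$pe_fits
#' }
run_pipeline <- function(scenario = default_scenario(), out_dir = NULL) {
  scenario <- validate_scenario(scenario)
  seed <- scenario$seed
  tps <- scenario$timepoints_h
  t_max <- max(tps)

  tabs <- list(growth = NULL, sigma = NULL, light_steps = NULL,
               etr_points = NULL, pe_fits = NULL, subunits = NULL,
               ratios = NULL, budget = NULL, dunnett = NULL)
  errors <- list()
  try_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[length(errors) + 1]] <<- list(stage = stage,
                                            message = conditionMessage(e))
      NULL
    })
  }

  for (st in scenario$strains) {
    nm <- st$name
    n_rep <- st$n_replicates

    ## -- growth ------------------------------------------------------
    g <- try_stage(paste0(nm, "/growth"), {
      fits <- lapply(seq_len(n_rep), function(r) {
        d <- simulate_growth_series(
          st$growth$mu, st$growth$A0, st$growth$onset_h,
          times_h = seq(0, t_max, by = 12), tau_h = st$growth$tau_h %||% 48,
          noise_sd = st$growth$noise_sd,
          seed = child_seed(seed, paste0(nm, "growth", r))
        )
        growth_rate(d$time_h, d$a750)
      })
      data.frame(
        strain = nm,
        mu = mean(vapply(fits, `[[`, numeric(1), "mu")),
        mu_sem = stats::sd(vapply(fits, `[[`, numeric(1), "mu")) /
          sqrt(n_rep),
        n = n_rep
      )
    })
    tabs$growth <- rbind(tabs$growth, g)

    ## -- dark sigma, red and blue ------------------------------------
    for (band in c("red", "blue")) {
      s_true <- if (band == "red") st$frr$sigma_red else st$frr$sigma_blue
      wl <- if (band == "red") 625 else 455
      sg <- try_stage(paste0(nm, "/sigma-", band), {
        pr <- flashlet_protocol(wavelength_nm = wl)
        rows <- lapply(tps, function(t) {
          per_rep <- vapply(seq_len(n_rep), function(r) {
            tr <- simulate_frr_transient(
              induction_params(st$frr$Fo, st$frr$Fm, s_true),
              pr, noise_sd = st$frr$noise_sd,
              seed = child_seed(seed, paste0(nm, band, t, r))
            )
            fit <- fit_dark_transient(tr)
            c(fit$sigma, fit$FvFm, fit$Fo)
          }, numeric(3))
          data.frame(
            strain = nm, band = band, time_h = t,
            sigma = mean(per_rep[1, ]),
            sigma_sem = stats::sd(per_rep[1, ]) / sqrt(n_rep),
            FvFm = mean(per_rep[2, ]), Fo = mean(per_rep[3, ]), n = n_rep
          )
        })
        do.call(rbind, rows)
      })
      tabs$sigma <- rbind(tabs$sigma, sg)
    }

    ## -- light steps + ETR + P-E at first and last timepoint ---------
    pe_truth <- function(t) {
      w <- t / t_max
      c(Pmax = st$pe$Pmax_start + (st$pe$Pmax_end - st$pe$Pmax_start) * w,
        EK = st$pe$EK_start + (st$pe$EK_end - st$pe$EK_start) * w)
    }
    psbA_truth <- function(t) subunit_truth(st$subunits$PsbA, t, t_max)

    for (t in c(0, t_max)) {
      res_t <- try_stage(paste0(nm, "/etr-t", t), {
        tru <- pe_truth(t)
        pr <- flashlet_protocol()
        sig <- st$frr$sigma_red
        Fo <- st$frr$Fo; Fm <- st$frr$Fm
        pts <- lapply(st$pe$irradiances, function(I) {
          if (I == 0) {
            return(data.frame(strain = nm, time_h = t, irradiance = 0,
                              sigma_prime = sig, qP = 1,
                              etr_psii = 0, etr_psii_sem = 0,
                              etr_protein = 0))
          }
          qP_true <- tru[["Pmax"]] * tanh(I / tru[["EK"]]) /
            (sig * PHOTON_CONV * I)
          qP_true <- min(qP_true, 1)
          # replicate cultures: one light-step measurement each,
          # averaged as in the study design
          per_rep <- vapply(seq_len(n_rep), function(r) {
            tr <- simulate_light_step(
              induction_params(Fo, Fm, sig, C0 = 1 - qP_true),
              pr, noise_sd = st$frr$noise_sd,
              seed = child_seed(seed, paste0(nm, "ls", t, I, "r", r)),
              actinic = I
            )
            fit <- fit_light_transient(tr, Fo_dark = Fo)
            c(fit$sigma_prime, fit$qP,
              etr_per_psii(fit$sigma_prime, I, fit$qP))
          }, numeric(3))
          e_psii <- mean(per_rep[3, ])
          data.frame(
            strain = nm, time_h = t, irradiance = I,
            sigma_prime = mean(per_rep[1, ]), qP = mean(per_rep[2, ]),
            etr_psii = e_psii,
            etr_psii_sem = stats::sd(per_rep[3, ]) / sqrt(n_rep),
            etr_protein = etr_per_protein(e_psii, psbA_truth(t))
          )
        })
        do.call(rbind, pts)
      })
      tabs$etr_points <- rbind(tabs$etr_points, res_t)
      if (!is.null(res_t)) {
        pf <- try_stage(paste0(nm, "/pe-t", t), {
          fit <- fit_pe_curve(res_t$irradiance, res_t$etr_psii)
          data.frame(strain = nm, time_h = t, Pmax = fit$Pmax,
                     Pmax_se = fit$Pmax_se, EK = fit$EK, EK_se = fit$EK_se,
                     alpha = fit$alpha, converged = fit$converged)
        })
        tabs$pe_fits <- rbind(tabs$pe_fits, pf)
      }
    }

    ## -- qP / Phi_PSII at the scenario's actinic levels --------------
    ls <- try_stage(paste0(nm, "/light-steps"), {
      pr <- flashlet_protocol()
      rows <- lapply(st$frr$actinic, function(I) {
        tru <- pe_truth(0)
        qP_true <- min(tru[["Pmax"]] * tanh(I / tru[["EK"]]) /
                         (st$frr$sigma_red * PHOTON_CONV * I), 1)
        tr <- simulate_light_step(
          induction_params(st$frr$Fo, st$frr$Fm, st$frr$sigma_red,
                           C0 = 1 - qP_true),
          pr, noise_sd = st$frr$noise_sd,
          seed = child_seed(seed, paste0(nm, "qp", I)), actinic = I
        )
        fit <- fit_light_transient(tr, Fo_dark = st$frr$Fo)
        data.frame(strain = nm, actinic = I, Fs = fit$Fs,
                   Fm_prime = fit$Fm_prime, sigma_prime = fit$sigma_prime,
                   qP = fit$qP, Phi_PSII = fit$Phi_PSII)
      })
      do.call(rbind, rows)
    })
    tabs$light_steps <- rbind(tabs$light_steps, ls)

    ## -- immunoblots -------------------------------------------------
    sub <- try_stage(paste0(nm, "/blots"), {
      rows <- list()
      for (target in names(st$subunits)) {
        peak <- max(vapply(tps, function(t) {
          subunit_truth(st$subunits[[target]], t, t_max)
        }, numeric(1)))
        ladder <- st$blot$standard_rel * peak * st$blot$ug_loaded
        for (t in tps) {
          truth <- subunit_truth(st$subunits[[target]], t, t_max)
          for (r in seq_len(n_rep)) {
            blot <- simulate_blot(
              ladder, truth,
              ug_loaded = st$blot$ug_loaded, noise_cv = st$blot$noise_cv,
              seed = child_seed(seed, paste0(nm, target, t, r))
            )
            rows[[length(rows) + 1]] <- data.frame(
              quantity = target, strain = nm, time_h = t, replicate = r,
              value = quantify_blot(blot)
            )
          }
        }
      }
      do.call(rbind, rows)
    })
    tabs$subunits <- rbind(tabs$subunits, sub)

    if (!is.null(sub)) {
      ## -- stoichiometry and budget per timepoint --------------------
      means_at <- function(t) {
        d <- sub[sub$time_h == t, ]
        tapply(d$value, d$quantity, mean)
      }
      ra <- try_stage(paste0(nm, "/ratios"), {
        rows <- lapply(tps, function(t) {
          m <- means_at(t)
          rep <- complex_ratios(m, timepoint = t, strain = nm)
          data.frame(strain = nm, time_h = t,
                     psi_per_psii = rep$psi_per_psii,
                     isia_per_psi = rep$isia_per_psi,
                     cytb6f_per_psii = rep$cytb6f_per_psii,
                     atpsynthase_per_psii = rep$atpsynthase_per_psii,
                     catalytic_sites_per_psii = rep$catalytic_sites_per_psii)
        })
        do.call(rbind, rows)
      })
      tabs$ratios <- rbind(tabs$ratios, ra)

      bu <- try_stage(paste0(nm, "/budget"), {
        rows <- lapply(tps, function(t) {
          b <- chlorophyll_budget(means_at(t), timepoint = t, strain = nm)
          data.frame(strain = nm, time_h = t, chl_isia = b$chl_isia,
                     chl_psi = b$chl_psi, chl_psii = b$chl_psii,
                     total = b$total)
        })
        do.call(rbind, rows)
      })
      tabs$budget <- rbind(tabs$budget, bu)

      ## -- Dunnett time-course statistics ----------------------------
      du <- try_stage(paste0(nm, "/dunnett"), {
        rows <- lapply(c("IsiA", "PsaC"), function(target) {
          d <- sub[sub$quantity == target, ]
          res <- anova_dunnett(as_time_course(d, quantity = target,
                                              strain = nm))
          cbind(strain = nm, quantity = target,
                anova_F = res$anova_F, anova_p = res$anova_p,
                res$comparisons)
        })
        do.call(rbind, rows)
      })
      tabs$dunnett <- rbind(tabs$dunnett, du)
    }
  }

  tabs$errors <- errors
  class(tabs) <- "pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in setdiff(names(tabs), "errors")) {
      if (is.null(tabs[[nm]])) next
      path <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(tabs[[nm]], path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, path)
    }
    jsonlite::write_json(
      tabs[setdiff(names(tabs), c("errors"))],
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
    jsonlite::write_json(
      list(seed = seed, timepoints_h = tps,
           strains = vapply(scenario$strains, `[[`, character(1), "name"),
           outputs = as.list(tools::md5sum(files)),
           errors = errors),
      file.path(out_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  tabs
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result with tables:\n")
  for (nm in setdiff(names(x), "errors")) {
    cat(sprintf("  %-12s %s\n", nm,
                if (is.null(x[[nm]])) "<absent>"
                else paste0(nrow(x[[nm]]), " rows")))
  }
  if (length(x$errors)) {
    cat("Stage errors:\n")
    for (e in x$errors) cat("  ", e$stage, ": ", e$message, "\n", sep = "")
  }
  invisible(x)
}
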