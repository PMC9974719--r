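#' Evaluate dose plans: dose points, CI, HI, coverage, constraints
#'
#' Computes, for every plan and every structure of interest, the DVH dose
#' points D2%, D98%, D50%, Dmean, Dmax (plus D0.1cc for OARs), the coverage
#' of each target at its local prescription (baseline for PTV and PTV-SUB,
#' boost for the PTV-ASL in dose-painting plans), a per-plan conformity
#' index for the PTV at the baseline prescription, the PTV's homogeneity
#' index as the headline HI (per-structure HIs are carried alongside), OAR
#' constraint verdicts, and pairwise percent-change tables across plan
#' variants.
#'
#' @param doses named list of dose [volume_grid()]s, e.g.
#'   `list(plan1 = ..., plan2 = ..., plan3 = ...)`.
#' @param structures named list of [structure_mask()]s containing the
#'   targets (`ptv`, `ptv_sub`, `ptv_asl`) and the constraint structures.
#' @param rx a [plan_prescription()].
#' @param constraints an [oar_constraint_table()].
#' @param bin_width_gy DVH bin width (default 0.1 Gy).
#' @param ci_reference_fraction CI reference dose as a fraction of the
#'   baseline prescription (default 1; set 0.95 for the 95%-isodose
#'   convention).
#' @return An object of class `plan_metrics_report`: list with `metrics`
#'   (data frame, one row per plan x structure), `plan_summary` (CI, HI,
#'   PTV coverage per plan), `percent_change` (pairwise percent changes of
#'   every metric), `constraints` (verdicts per plan) and `rx`.
#' @export
evaluate_plans <- function(doses, structures, rx,
                           constraints = oar_constraint_table(),
                           bin_width_gy = 0.1, ci_reference_fraction = 1) {
  stopifnot(length(doses) >= 1, !is.null(names(doses)))
  targets <- intersect(c("ptv", "ptv_sub", "ptv_asl"), names(structures))
  oars <- intersect(constraints$structure, names(structures))
  eval_structs <- c(targets, oars)

  rows <- list()
  for (plan in names(doses)) {
    dose <- doses[[plan]]
    boosted <- identical(attr(dose, "variant"), "plan2") ||
      identical(attr(dose, "variant"), "plan3")
    boosted <- boosted && !isTRUE(attr(dose, "fallback"))
    for (s in eval_structs) {
      m <- structures[[s]]
      if (!any(m$data)) next
      dvh <- compute_dvh(dose, m, bin_width_gy)
      d2 <- dose_at_volume(dvh, 0.02)
      d98 <- dose_at_volume(dvh, 0.98)
      d50 <- dose_at_volume(dvh, 0.50)
      local_rx <- if (s == "ptv_asl" && boosted) rx$boost_dose_gy
                  else rx$baseline_dose_gy
      rows[[length(rows) + 1L]] <- data.frame(
        plan = plan, structure = s,
        volume_cc = volume_cc(m),
        D2 = d2, D98 = d98, D50 = d50,
        Dmean = mean(dose$data[m$data]),
        Dmax = max(dose$data[m$data]),
        D0.1cc = if (s %in% oars)
          dose_at_absolute_volume(dvh, 0.1) else NA_real_,
        coverage = if (s %in% targets)
          coverage(dose, m, local_rx) else NA_real_,
        HI = if (s %in% targets && d50 > 0)
          homogeneity_index(d2, d98, d50) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)

  ci_ref <- ci_reference_fraction * rx$baseline_dose_gy
  plan_summary <- do.call(rbind, lapply(names(doses), function(plan) {
    ptv_row <- metrics[metrics$plan == plan & metrics$structure == "ptv", ]
    data.frame(plan = plan,
               CI = conformity_index(doses[[plan]], structures$ptv, ci_ref),
               HI = ptv_row$HI,
               ptv_coverage = ptv_row$coverage,
               Dmax = max(doses[[plan]]$data),
               stringsAsFactors = FALSE)
  }))

  constraint_rows <- do.call(rbind, lapply(names(doses), function(plan) {
    cbind(plan = plan,
          check_constraints(doses[[plan]], structures, constraints))
  }))

  pc <- list()
  metric_cols <- c("D2", "D98", "D50", "Dmean", "Dmax", "D0.1cc", "coverage")
  plans <- names(doses)
  if (length(plans) >= 2) {
    for (i in seq_along(plans)) for (j in seq_along(plans)) {
      if (j <= i) next
      a <- metrics[metrics$plan == plans[i], ]
      b <- metrics[metrics$plan == plans[j], ]
      common <- intersect(a$structure, b$structure)
      for (s in common) {
        va <- a[a$structure == s, metric_cols]
        vb <- b[b$structure == s, metric_cols]
        pc[[length(pc) + 1L]] <- data.frame(
          comparison = paste(plans[j], "vs", plans[i]),
          structure = s, metric = metric_cols,
          from = as.numeric(va), to = as.numeric(vb),
          percent_change = 100 * (as.numeric(vb) - as.numeric(va)) /
            as.numeric(va),
          stringsAsFactors = FALSE)
      }
    }
  }
  percent_change <- if (length(pc)) do.call(rbind, pc) else NULL

  structure(list(metrics = metrics, plan_summary = plan_summary,
                 percent_change = percent_change,
                 constraints = constraint_rows, rx = rx),
            class = "plan_metrics_report")
}

#' @export
print.plan_metrics_report <- function(x, digits = 3, ...) {
  cat("Plan quality summary\n")
  print(format(x$plan_summary, digits = digits), row.names = FALSE)
  cat("\nPer-structure dose points (Gy)\n")
  print(format(x$metrics, digits = digits), row.names = FALSE)
  cat("\nOAR constraints\n")
  print(format(x$constraints, digits = digits), row.names = FALSE)
  invisible(x)
}
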