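## MM-GBSA aggregation arithmetic: snapshot differencing and component
## decomposition.  No force-field or solvation computation happens here --
## inputs are per-snapshot free energies or per-complex component tables
## produced upstream (e.g. by Amber's MMPBSA.py).

#' Mean MM-GBSA binding free energy over snapshots
#'
#' `dG_i = G_com,i - G_rec,i - G_lig,i`; reports the mean and its standard
#' error over snapshots.
#'
#' @param snapshots data.frame with numeric columns `G_com`, `G_rec`,
#'   `G_lig` (kcal/mol), one row per snapshot.
#' @return list of class `mmgbsa_mean`: `mean`, `se`, `n`, `dG` (per-snapshot
#'   vector).
#' @export
mmgbsa_mean <- function(snapshots) {
  need <- c("G_com", "G_rec", "G_lig")
  if (!is.data.frame(snapshots) || !all(need %in% names(snapshots)))
    stop2("snapshots must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (!nrow(snapshots)) stop2("empty snapshot table")
  if (!all(vapply(snapshots[need], function(x) all(is.finite(x)), NA)))
    stop2("non-finite snapshot energies")
  dG <- snapshots$G_com - snapshots$G_rec - snapshots$G_lig
  n <- length(dG)
  se <- if (n > 1) stats::sd(dG) / sqrt(n) else 0
  structure(list(mean = mean(dG), se = se, n = n, dG = dG),
            class = "mmgbsa_mean")
}

#' Combine MM-GBSA energy components
#'
#' `dG_gas = dE_vdW + dE_Ele`; `dG_bind = dG_gas + dE_Sol`.  Reported values
#' are rounded to 2 decimals, half away from zero.
#'
#' @param dE_vdW,dE_Ele,dE_Sol van der Waals, electrostatic and (polar +
#'   non-polar) solvation components, kcal/mol.
#' @param complex_id optional label.
#' @return list of class `energy_components` with fields `dE_vdW`, `dE_Ele`,
#'   `dE_Sol`, `dG_gas`, `dG_bind` (rounded for reporting) and `dG_gas_raw`,
#'   `dG_bind_raw` (unrounded).
#' @export
combine_components <- function(dE_vdW, dE_Ele, dE_Sol, complex_id = "") {
  for (nm in c("dE_vdW", "dE_Ele", "dE_Sol"))
    assert_scalar_number(get(nm), nm)
  gas <- dE_vdW + dE_Ele
  bind <- gas + dE_Sol
  structure(list(complex_id = complex_id,
                 dE_vdW = dE_vdW, dE_Ele = dE_Ele, dE_Sol = dE_Sol,
                 dG_gas = round_half_away(gas, 2),
                 dG_bind = round_half_away(bind, 2),
                 dG_gas_raw = gas, dG_bind_raw = bind),
            class = "energy_components")
}

#' Audit a printed component table for internal consistency
#'
#' Recomputes `dG_gas` and `dG_bind` from the component triples and compares
#' them with the printed aggregates, recording (not hiding) rounding
#' discrepancies.
#'
#' @param components data.frame with columns `complex`, `dE_vdW`, `dE_Ele`,
#'   `dE_Sol` and optionally `dG_gas_printed`, `dG_bind_printed`.
#' @param tol_gas,tol_bind tolerances absorbing the source's internal
#'   pre-rounding (0.01 / 0.02 kcal/mol).
#' @return data.frame with recomputed values, deviations from the printed
#'   ones (`NA` if not supplied) and a `consistent` flag.
#' @export
audit_components <- function(components, tol_gas = 0.01, tol_bind = 0.02) {
  rows <- lapply(seq_len(nrow(components)), function(i) {
    r <- components[i, ]
    ec <- combine_components(r$dE_vdW, r$dE_Ele, r$dE_Sol, r$complex)
    gp <- if ("dG_gas_printed" %in% names(r)) r$dG_gas_printed else NA_real_
    bp <- if ("dG_bind_printed" %in% names(r)) r$dG_bind_printed else NA_real_
    data.frame(complex = r$complex, dG_gas = ec$dG_gas, dG_bind = ec$dG_bind,
               dG_gas_printed = gp, dG_bind_printed = bp,
               dev_gas = if (is.na(gp)) NA_real_ else abs(ec$dG_gas - gp),
               dev_bind = if (is.na(bp)) NA_real_ else abs(ec$dG_bind - bp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$consistent <- (is.na(out$dev_gas) | out$dev_gas <= tol_gas + 1e-9) &
    (is.na(out$dev_bind) | out$dev_bind <= tol_bind + 1e-9)
  out
}

#' Read an MM-GBSA energy CSV (auto-detected layout)
#'
#' Two layouts are recognised by header: per-snapshot
#' (`complex_id, frame, G_com, G_rec, G_lig`) and per-complex components
#' (`complex, dE_vdW, dE_Ele, dE_Sol, ...`).
#'
#' @param path CSV file.
#' @return data.frame with attribute `"layout"` set to `"snapshots"` or
#'   `"components"`.
#' @export
read_energy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (all(c("G_com", "G_rec", "G_lig") %in% names(df))) {
    attr(df, "layout") <- "snapshots"
  } else if (all(c("dE_vdW", "dE_Ele", "dE_Sol") %in% names(df))) {
    attr(df, "layout") <- "components"
  } else {
    stop2("unrecognised energy CSV header in %s", path)
  }
  df
}
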