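#' A-priori planning sweep over applicator parameters
#'
#' Runs one forward treatment per point of the Cartesian product of
#' sector angle, active element count, surface intensity, heating time
#' and perfusion on a generic homogeneous model, tabulating the
#' ablation-zone dimensions at the 240 and 600 min CEM43 contours.  This
#' is the engine behind lookup-table ("a priori") planning: each row's
#' dose and end-of-sonication temperature clouds can be exported as NRRD
#' volumes for interactive overlay on anatomy.
#'
#' Per-case failures are caught, flagged in the `status` column and the
#' sweep continues.  Rows are computed in a deterministic order but are
#' independent, so the table content does not depend on execution order.
#'
#' @param sectors sector angles, degrees (default `c(360, 180, 90)`).
#' @param nElements element counts (1-4).
#' @param intensities surface intensities, W/cm2 (bracket 8-20 for
#'   prostate planning).
#' @param heatingTimes sonication times, min (default `c(5, 7.5, 10)`).
#' @param perfusions blood perfusion values, kg/m3/s (default
#'   `c(0, 2.5, 5)`).
#' @param model generic scene (default [makeGenericModel()]:
#'   6 cm prostate cube at 0.5 mm).
#' @param frequency operating frequency, MHz (default 7.5).
#' @param cooldown cooldown, min (default 2).
#' @param dt solver step, s (default 0.1).
#' @param outDir optional directory: when given, per-case NRRD dose /
#'   temperature clouds and the lookup CSV are written there.
#' @param quiet suppress per-case progress messages.
#' @return data.frame lookup table: sweep coordinates, `d1_cm`, `d2_cm`,
#'   `d3_cm`, `volume_cm3` at both thresholds (suffix `_240` / `_600`),
#'   `Tmax_C`, `status` and NRRD paths when exported.
#' @export
runSweep <- function(sectors = c(360, 180, 90), nElements = 1:4,
                     intensities = c(8, 12, 16, 20),
                     heatingTimes = c(5, 7.5, 10),
                     perfusions = c(0, 2.5, 5),
                     model = makeGenericModel(), frequency = 7.5,
                     cooldown = 2, dt = 0.1, outDir = NULL, quiet = FALSE) {
  stopifnot(all(sectors > 0 & sectors <= 360), all(nElements %in% 1:4),
            all(intensities > 0), all(heatingTimes > 0), all(perfusions >= 0))
  cases <- expand.grid(sector = sectors, elements = nElements,
                       I0 = intensities, time_min = heatingTimes,
                       perfusion = perfusions, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    tag <- sprintf("s%03d_n%d_I%04.1f_t%04.1f_w%03.1f", cs$sector, cs$elements,
                   cs$I0, cs$time_min, cs$perfusion)
    row <- cbind(cs, d1_cm_240 = NA_real_, d2_cm_240 = NA_real_,
                 d3_cm_240 = NA_real_, volume_cm3_240 = NA_real_,
                 d1_cm_600 = NA_real_, d2_cm_600 = NA_real_,
                 d3_cm_600 = NA_real_, volume_cm3_600 = NA_real_,
                 Tmax_C = NA_real_, status = "ok",
                 dose_nrrd = NA_character_, temperature_nrrd = NA_character_)
    res <- tryCatch({
      ap <- placeApplicator(cs$elements, I0 = cs$I0, frequency = frequency,
                            sector = cs$sector, center = gridCenter(model@grid))
      runTreatment(model, ap,
                   solverConfig(heatingTime = cs$time_min, cooldown = cooldown,
                                dt = dt),
                   perfusion = cs$perfusion)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- conditionMessage(res)
      if (!quiet) message(sprintf("[%d/%d] %s FAILED: %s", i, nrow(cases), tag,
                                  row$status))
    } else {
      met <- ablationMetrics(res)
      for (th in c(240, 600)) {
        mr <- met[met$threshold == th, ]
        for (f in c("d1_cm", "d2_cm", "d3_cm", "volume_cm3"))
          row[[paste0(f, "_", th)]] <- mr[[f]]
      }
      row$Tmax_C <- max(res@endOfHeating@values)
      if (!is.null(outDir)) {
        dp <- file.path(outDir, paste0(tag, "_dose.nrrd"))
        tp <- file.path(outDir, paste0(tag, "_temperature.nrrd"))
        writeNRRD(res@dose, dp)
        writeNRRD(res@endOfHeating, tp)
        row$dose_nrrd <- dp
        row$temperature_nrrd <- tp
      }
      if (!quiet) message(sprintf("[%d/%d] %s: d1 %.2f cm, d3 %.2f cm",
                                  i, nrow(cases), tag, row$d1_cm_240,
                                  row$d3_cm_240))
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outDir))
    write.csv(out, file.path(outDir, "lookup_table.csv"), row.names = FALSE)
  out
}

#' Pivot a sweep table to the nominal (low-high) perfusion presentation
#'
#' Lookup tables are conventionally printed with the dimensions at the
#' nominal (middle) perfusion and the zero-to-high perfusion range in
#' parentheses.  This reshapes the long [runSweep()] output accordingly.
#'
#' @param table a [runSweep()] result containing at least two perfusion
#'   levels per configuration.
#' @param nominal the perfusion treated as nominal (default: the median
#'   level present).
#' @return data.frame with one row per (sector, elements, I0, time) and
#'   formatted `d1`/`d2`/`d3`/`volume` columns at both dose thresholds.
#' @export
formatLookupTable <- function(table, nominal = NULL) {
  perf <- sort(unique(table$perfusion))
  nominal <- nominal %||% perf[ceiling(length(perf) / 2)]
  keys <- unique(table[, c("sector", "elements", "I0", "time_min")])
  fmt <- function(nom, lo, hi) sprintf("%.1f (%.1f-%.1f)", nom, hi, lo)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- table$sector == k$sector & table$elements == k$elements &
      table$I0 == k$I0 & table$time_min == k$time_min
    sub <- table[sel, ]
    nom <- sub[sub$perfusion == nominal, ]
    lo <- sub[which.max(sub$perfusion), ]   # high perfusion -> small zone
    hi <- sub[which.min(sub$perfusion), ]   # zero perfusion -> large zone
    out <- k
    for (th in c(240, 600)) for (f in c("d1_cm", "d2_cm", "d3_cm", "volume_cm3")) {
      cn <- paste0(f, "_", th)
      out[[cn]] <- fmt(nom[[cn]], lo[[cn]], hi[[cn]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
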