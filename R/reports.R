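# Cell-formatting conventions shared by all reports: counts as
# "n (p%)" with the percentage rounded half away from zero to an
# integer, continuous values as "mean +/- SD", p-values to 3 decimals.

#' Report cell formatting
#'
#' @param k,n count and denominator.
#' @param x numeric vector.
#' @param digits decimals for mean and SD.
#' @param p p-value.
#' @return A formatted string.
#' @name reportFormat
NULL

#' @rdname reportFormat
#' @export
formatCount <- function(k, n) {
  sprintf("%d (%d%%)", k, as.integer(roundHalfUp(100 * k / n)))
}

#' @rdname reportFormat
#' @export
formatMeanSD <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          mean(x), sd(x))
}

#' @rdname reportFormat
#' @export
formatP <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' @rdname reportFormat
#' @export
formatCI <- function(est, ci, digits = 2) {
  fmt <- paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f]")
  sprintf(fmt, est, ci[1], ci[2])
}

#' Build the four cohort reports
#'
#' Generates CSV reports of the study's shape from a cohort table:
#' demographics and pressures by group (`table1.csv`), group
#' differences of the continuous hemodynamic metrics with pooled-t 95%
#' CIs (`table2.csv`), baseline-to-follow-up paired comparisons per
#' group (`table3.csv`), and per-region abnormality incidence with
#' exact McNemar p-values (`table4.csv`). All cells are computed from
#' the data actually supplied.
#'
#' @param tbl data.frame with one row per subject and session: columns
#'   `subject`, `group` (`"native"`/`"RR"`), `session`
#'   (`"baseline"`/`"followup"`), `age`, `sex` (`"female"`/`"male"`),
#'   `sbp`, `dbp`, `hr`, `pwv_mps`, continuous metric columns starting
#'   with `velocity_` or `wss_`, and logical flag columns starting with
#'   `flag_`.
#' @param outDir output directory for `table1.csv` ... `table4.csv`.
#' @return Invisibly, a list of the four data.frames.
#' @export
buildReports <- function(tbl, outDir) {
  need <- c("subject", "group", "session", "age", "sex", "sbp", "dbp",
            "hr", "pwv_mps")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L)
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  groups <- c("native", "RR")
  safeP <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  base <- tbl[tbl$session == "baseline", ]
  fup <- tbl[tbl$session == "followup", ]
  metricCols <- grep("^(velocity|wss)_", names(tbl), value = TRUE)
  metricCols <- c(metricCols, "pwv_mps")
  flagCols <- grep("^flag_", names(tbl), value = TRUE)

  # ---- table 1: demographics by group at baseline ----
  bg <- lapply(groups, function(g) base[base$group == g, ])
  names(bg) <- groups
  map1 <- lapply(bg, function(d) meanArterialPressure(d$sbp, d$dbp))
  sexTab <- vapply(bg, function(d) c(sum(d$sex == "female"), nrow(d)), numeric(2))
  t1 <- data.frame(
    variable = c("n", "Age (years)", "Sex (female)", "Systolic BP (mmHg)",
                 "Diastolic BP (mmHg)", "MAP (mmHg)", "Heart rate (bpm)"),
    native = c(nrow(bg$native), formatMeanSD(bg$native$age, 0),
               formatCount(sexTab[1, 1], sexTab[2, 1]),
               formatMeanSD(bg$native$sbp, 0), formatMeanSD(bg$native$dbp, 0),
               formatMeanSD(map1$native, 0), formatMeanSD(bg$native$hr, 0)),
    RR = c(nrow(bg$RR), formatMeanSD(bg$RR$age, 0),
           formatCount(sexTab[1, 2], sexTab[2, 2]),
           formatMeanSD(bg$RR$sbp, 0), formatMeanSD(bg$RR$dbp, 0),
           formatMeanSD(map1$RR, 0), formatMeanSD(bg$RR$hr, 0)),
    p = c("", formatP(safeP(unpairedT(bg$native$age, bg$RR$age)$p)),
          formatP(safeP(fisherExact(sexTab[1, 1], sexTab[2, 1] - sexTab[1, 1],
                                    sexTab[1, 2], sexTab[2, 2] - sexTab[1, 2]))),
          formatP(safeP(unpairedT(bg$native$sbp, bg$RR$sbp)$p)),
          formatP(safeP(unpairedT(bg$native$dbp, bg$RR$dbp)$p)),
          formatP(safeP(unpairedT(map1$native, map1$RR)$p)),
          formatP(safeP(unpairedT(bg$native$hr, bg$RR$hr)$p))))

  # ---- table 2: native vs RR differences per session ----
  rows2 <- list()
  for (ses in c("baseline", "followup")) {
    d <- tbl[tbl$session == ses, ]
    for (mc in metricCols) {
      xa <- d[[mc]][d$group == "native"]; xb <- d[[mc]][d$group == "RR"]
      if (all(is.na(xa)) || all(is.na(xb))) next
      ut <- tryCatch(unpairedT(xa, xb), error = function(e) NULL)
      rows2[[length(rows2) + 1L]] <- data.frame(
        session = ses, metric = mc,
        native = formatMeanSD(xa), RR = formatMeanSD(xb),
        difference = if (is.null(ut)) "NA"
                     else formatCI(ut$difference, ut$ci),
        p = if (is.null(ut)) "NA" else formatP(ut$p))
    }
  }
  t2 <- do.call(rbind, rows2)

  # ---- table 3: baseline vs follow-up within group ----
  rows3 <- list()
  for (g in groups) {
    b <- base[base$group == g, ]; f <- fup[fup$group == g, ]
    f <- f[match(b$subject, f$subject), ]
    for (mc in metricCols) {
      ok <- !is.na(b[[mc]]) & !is.na(f[[mc]])
      if (sum(ok) < 2L) next
      pt <- tryCatch(pairedT(b[[mc]][ok], f[[mc]][ok]),
                     error = function(e) NULL)
      if (is.null(pt)) next
      rows3[[length(rows3) + 1L]] <- data.frame(
        group = g, metric = mc,
        baseline = formatMeanSD(b[[mc]][ok]),
        followup = formatMeanSD(f[[mc]][ok]),
        change = if (pt$undefined) sprintf("%.2f [-]", pt$change)
                 else formatCI(pt$change, pt$ci),
        p = formatP(pt$p))
    }
  }
  t3 <- do.call(rbind, rows3)

  # ---- table 4: abnormality incidence V1 vs V2 ----
  rows4 <- list()
  for (g in groups) {
    b <- base[base$group == g, ]; f <- fup[fup$group == g, ]
    f <- f[match(b$subject, f$subject), ]
    for (fc in flagCols) {
      fb <- b[[fc]]; ff <- f[[fc]]
      ok <- !is.na(fb) & !is.na(ff)
      if (!any(ok)) next
      fb <- fb[ok]; ff <- ff[ok]
      disc_b <- sum(fb & !ff)
      disc_c <- sum(!fb & ff)
      rows4[[length(rows4) + 1L]] <- data.frame(
        group = g, metric = sub("^flag_", "", fc),
        V1 = formatCount(sum(fb), length(fb)),
        V2 = formatCount(sum(ff), length(ff)),
        p = formatP(mcnemarExact(disc_b, disc_c)))
    }
  }
  t4 <- do.call(rbind, rows4)

  tabs <- list(table1 = t1, table2 = t2, table3 = t3, table4 = t4)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    utils::write.csv(tabs[[nm]], file.path(outDir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(tabs)
}
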