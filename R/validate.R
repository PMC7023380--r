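#' Fit a calibration line
#'
#' Ordinary least squares of measured on spiked values.
#'
#' @param spiked,measured numeric vectors (mg/kg); alternatively `spiked`
#'   may be a data.frame with columns `spiked` and `measured`
#' @return list of class `CalibrationFit`: `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `n`, `flags`
#' @export
fitCalibration <- function(spiked, measured = NULL) {
  if (is.data.frame(spiked)) {
    measured <- spiked$measured
    spiked <- spiked$spiked
  }
  ok <- is.finite(spiked) & is.finite(measured)
  spiked <- spiked[ok]; measured <- measured[ok]
  n <- length(spiked)
  if (n < 2) stop("at least 2 calibration levels required", call. = FALSE)
  if (length(unique(spiked)) < 2)
    stop("degenerate design: all spiked values identical", call. = FALSE)
  fit <- stats::lm(measured ~ spiked)
  s <- suppressWarnings(summary(fit))  # noiseless data: perfect-fit warning
  flags <- character(0)
  if (n == 2) flags <- "under_determined"
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (n == 2) 1 else s$r.squared,
                 residual_sd = if (n > 2) s$sigma else NA_real_,
                 n = n, flags = flags),
            class = "CalibrationFit")
}

#' Detection and determination limits by the DIN 32645 calibration-line method
#'
#' From an unweighted calibration line in the lower working range: with
#' residual standard deviation `s_y`, slope `b`, `n` levels, mean spiked
#' level `x_bar` and `Q_x = sum((x - x_bar)^2)`, the detection limit is
#'
#' `LOD = s_y / b * t(n - 2, 1 - alpha) * sqrt(1 + 1/n + x_bar^2 / Q_x)`
#'
#' and the determination (quantification) limit is `k` times the analogous
#' expression evaluated at its own leverage, solved by the standard
#' fixed-point iteration
#' `LOQ = k * s_y / b * t * sqrt(1 + 1/n + (LOQ - x_bar)^2 / Q_x)`.
#' Defaults follow the norm's customary choices: one-sided `alpha = 0.01`
#' and `k = 3` (33% relative result uncertainty at the determination limit).
#'
#' @param spiked,measured calibration data in the lower working range
#'   (mg/kg); a data.frame with `spiked`/`measured` columns is also accepted
#' @param alpha one-sided significance level
#' @param k_loq relative-uncertainty factor
#' @param max_iter,tol fixed-point iteration controls
#' @return list of class `AnalyticalLimits`: `lod_mg_kg`, `loq_mg_kg`,
#'   `range_mg_kg`, `alpha`, `k_loq`, `n`, plus the line statistics
#' @export
din32645Limits <- function(spiked, measured = NULL, alpha = 0.01, k_loq = 3,
                           max_iter = 100, tol = 1e-12) {
  if (is.data.frame(spiked)) {
    measured <- spiked$measured
    spiked <- spiked$spiked
  }
  n <- length(spiked)
  if (n < 5)
    stop("DIN 32645 calibration-line method needs at least 5 levels",
         call. = FALSE)
  cal <- fitCalibration(spiked, measured)
  if (!is.finite(cal$slope) || cal$slope <= 0)
    stop("unusable calibration: slope must be positive", call. = FALSE)
  sy <- cal$residual_sd
  b <- cal$slope
  xbar <- mean(spiked)
  qx <- sum((spiked - xbar)^2)
  tval <- stats::qt(1 - alpha, df = n - 2)
  lod <- sy / b * tval * sqrt(1 + 1 / n + xbar^2 / qx)
  loq <- k_loq * lod
  for (i in seq_len(max_iter)) {
    loq_new <- k_loq * sy / b * tval * sqrt(1 + 1 / n + (loq - xbar)^2 / qx)
    if (abs(loq_new - loq) < tol * max(loq, 1)) { loq <- loq_new; break }
    loq <- loq_new
  }
  structure(list(lod_mg_kg = lod, loq_mg_kg = loq,
                 range_mg_kg = range(spiked), alpha = alpha, k_loq = k_loq,
                 n = n, slope = b, intercept = cal$intercept,
                 residual_sd = sy, r_squared = cal$r_squared),
            class = "AnalyticalLimits")
}

#' Recovery in percent
#'
#' Per spiking level, `100 * (mean measured at the level - matrix blank) /
#' spiked`; levels are aggregated by the mean of per-level recoveries
#' (`aggregate = "median"` for the robust alternative). Specification:
#' 90-110%.
#'
#' @param spiked,measured paired values (mg/kg), one or more per level
#' @param blank matrix blank value subtracted from measurements (default 0)
#' @param aggregate `"mean"` or `"median"` across levels
#' @return list of class `Recovery`: `recovery_pct`, `per_level`
#'   (data.frame), `in_spec` (90-110 band)
#' @export
recovery <- function(spiked, measured, blank = 0, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (any(!is.finite(spiked)) || any(spiked <= 0))
    stop("spiked values must be positive", call. = FALSE)
  per <- tapply(measured - blank, spiked, mean)
  lev <- as.numeric(names(per))
  rec <- 100 * as.numeric(per) / lev
  val <- if (aggregate == "mean") mean(rec) else stats::median(rec)
  structure(list(recovery_pct = val,
                 per_level = data.frame(spiked = lev, recovery_pct = rec),
                 in_spec = val >= 90 && val <= 110),
            class = "Recovery")
}

#' Precision as coefficient of variation, percent
#'
#' `100 * sd / mean` over replicate measurements (sample standard
#' deviation). Specification: CV < 15%.
#'
#' @param values replicate measurements (>= 2)
#' @return list of class `PrecisionCV`: `cv_pct`, `n`, `in_spec`
#' @export
precisionCV <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("at least 2 replicates required", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("undefined CV: mean is zero", call. = FALSE)
  cv <- 100 * stats::sd(values) / m
  structure(list(cv_pct = cv, n = length(values), in_spec = cv < 15),
            class = "PrecisionCV")
}

#' Three-factor ANOVA for method robustness
#'
#' Main-effects linear model of a response (typically per-cell recovery or
#' measured content) on NMR device, coffee type and shaking time, with
#' type-II sums of squares (via `car::Anova`), which coincide with the
#' sequential ones on a balanced design and remain valid when cells are
#' missing (a warning is raised then).
#'
#' @param data data.frame with columns `device`, `coffee_type`,
#'   `shaking_min` and the response
#' @param response name of the response column
#' @param alpha significance level for the per-factor calls
#' @return data.frame, one row per factor: `factor`, `df`, `F`, `p`,
#'   `significant`
#' @export
factorialAnova <- function(data, response = "recovery_pct", alpha = 0.05) {
  need <- c("device", "coffee_type", "shaking_min", response)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data
  d$device <- factor(d$device)
  d$coffee_type <- factor(d$coffee_type)
  d$shaking_min <- factor(d$shaking_min)
  factors <- c("device", "coffee_type", "shaking_min")
  factors <- factors[vapply(factors, function(f) nlevels(d[[f]]) >= 2,
                            logical(1))]
  if (!length(factors))
    stop("no factor varies in the supplied design", call. = FALSE)
  n_cells <- prod(vapply(factors, function(f) nlevels(d[[f]]), numeric(1)))
  if (nrow(unique(d[factors])) < n_cells)
    warning("unbalanced design: empty cells; type-II sums of squares used")
  fml <- stats::reformulate(factors, response = response)
  fit <- stats::lm(fml, data = d)
  a <- car::Anova(fit, type = 2)
  keep <- rownames(a) != "Residuals"
  data.frame(factor = rownames(a)[keep], df = a$Df[keep],
             F = a$`F value`[keep], p = a$`Pr(>F)`[keep],
             significant = a$`Pr(>F)`[keep] < alpha,
             stringsAsFactors = FALSE)
}

#' Assemble the validation report
#'
#' From quantified design measurements (see [quantifyDesign()]): per
#' (analyte, matrix) recovery and CV with specification flags, linearity per
#' analyte in the decaffeinated-arabica matrix, DIN 32645 limits from the
#' lower working range of that matrix, and the three-factor robustness ANOVA
#' on per-cell recoveries.
#'
#' @param measurements data.frame with columns `array`, `device`,
#'   `coffee_type`, `shaking_min`, `analyte`, `blank`, `spiked_mg_kg`,
#'   `measured_mg_kg`
#' @param alpha_anova significance level for the ANOVA calls
#' @param alpha_din,k_loq DIN 32645 parameters
#' @param lower_range_max_mg_kg upper bound of the lower working range used
#'   for the limits
#' @return list of class `ValidationReport` with elements
#'   `recovery_precision` (data.frame), `linearity` (data.frame), `limits`
#'   (data.frame), `anova` (data.frame, per analyte and factor)
#' @export
buildValidationReport <- function(measurements, alpha_anova = 0.05,
                                  alpha_din = 0.01, k_loq = 3,
                                  lower_range_max_mg_kg = 400) {
  empty <- structure(list(
    recovery_precision = data.frame(), linearity = data.frame(),
    limits = data.frame(), anova = data.frame()), class = "ValidationReport")
  if (is.null(measurements) || !nrow(measurements)) return(empty)
  m <- measurements[!measurements$blank, ]
  analytes <- unique(m$analyte)

  rp <- list()
  for (an in analytes) for (mx in unique(m$coffee_type)) {
    sub <- m[m$analyte == an & m$coffee_type == mx, ]
    bl <- measurements[measurements$blank & measurements$analyte == an &
                         measurements$coffee_type == mx, "measured_mg_kg"]
    blank_val <- if (length(bl)) mean(bl) else 0
    rec <- recovery(sub$spiked_mg_kg, sub$measured_mg_kg, blank = blank_val)
    cv <- precisionCV(100 * (sub$measured_mg_kg - blank_val) /
                        sub$spiked_mg_kg)
    rp[[paste(an, mx)]] <- data.frame(
      analyte = an, matrix = mx, recovery_pct = rec$recovery_pct,
      recovery_in_spec = rec$in_spec, cv_pct = cv$cv_pct,
      cv_in_spec = cv$in_spec, stringsAsFactors = FALSE)
  }

  lin <- list(); lim <- list(); anv <- list()
  for (an in analytes) {
    cal_m <- m[m$analyte == an & m$coffee_type == "arabica_decaf", ]
    if (nrow(cal_m) >= 3) {
      f <- fitCalibration(cal_m$spiked_mg_kg, cal_m$measured_mg_kg)
      lin[[an]] <- data.frame(analyte = an, slope = f$slope,
                              intercept = f$intercept, r_squared = f$r_squared,
                              range_low = min(cal_m$spiked_mg_kg),
                              range_high = max(cal_m$spiked_mg_kg),
                              stringsAsFactors = FALSE)
      low <- cal_m[cal_m$spiked_mg_kg <= lower_range_max_mg_kg, ]
      if (nrow(low) >= 5 && length(unique(low$spiked_mg_kg)) >= 3) {
        l <- tryCatch(din32645Limits(low$spiked_mg_kg, low$measured_mg_kg,
                                     alpha = alpha_din, k_loq = k_loq),
                      error = function(e) NULL)
        if (!is.null(l))
          lim[[an]] <- data.frame(analyte = an, lod_mg_kg = l$lod_mg_kg,
                                  loq_mg_kg = l$loq_mg_kg,
                                  range_low = l$range_mg_kg[1],
                                  range_high = l$range_mg_kg[2],
                                  stringsAsFactors = FALSE)
      }
    }
    sub <- m[m$analyte == an, ]
    cells <- stats::aggregate(
      list(recovery_pct = 100 * sub$measured_mg_kg / sub$spiked_mg_kg),
      by = sub[c("array", "device", "coffee_type", "shaking_min")], FUN = mean)
    if (nrow(cells) >= 8) {
      a <- factorialAnova(cells, "recovery_pct", alpha = alpha_anova)
      a$analyte <- an
      anv[[an]] <- a[, c("analyte", "factor", "df", "F", "p", "significant")]
    }
  }
  rbind0 <- function(l) if (length(l)) do.call(rbind, c(l, list(
    make.row.names = FALSE))) else data.frame()
  structure(list(recovery_precision = rbind0(rp), linearity = rbind0(lin),
                 limits = rbind0(lim), anova = rbind0(anv)),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  star <- function(ok) ifelse(ok, "", " *")
  cat("== Recovery / precision (spec: 90-110% / CV < 15%) ==\n")
  if (nrow(x$recovery_precision)) {
    r <- x$recovery_precision
    for (i in seq_len(nrow(r)))
      cat(sprintf("  %-16s %-14s recovery %6.1f%%%s  CV %6.1f%%%s\n",
                  r$analyte[i], r$matrix[i], r$recovery_pct[i],
                  star(r$recovery_in_spec[i]), r$cv_pct[i],
                  star(r$cv_in_spec[i])))
  } else cat("  (none)\n")
  cat("== Linearity (decaf. arabica) ==\n")
  if (nrow(x$linearity)) {
    l <- x$linearity
    for (i in seq_len(nrow(l)))
      cat(sprintf("  %-16s slope %.3f  R^2 %.4f  range %.1f-%.1f mg/kg\n",
                  l$analyte[i], l$slope[i], l$r_squared[i], l$range_low[i],
                  l$range_high[i]))
  } else cat("  (none)\n")
  cat("== DIN 32645 limits ==\n")
  if (nrow(x$limits)) {
    l <- x$limits
    for (i in seq_len(nrow(l)))
      cat(sprintf("  %-16s LOD %8.2f  LOQ %8.2f mg/kg  (range %.1f-%.1f)\n",
                  l$analyte[i], l$lod_mg_kg[i], l$loq_mg_kg[i],
                  l$range_low[i], l$range_high[i]))
  } else cat("  (none)\n")
  cat("== Robustness ANOVA (alpha 0.05) ==\n")
  if (nrow(x$anova)) {
    a <- x$anova
    for (i in seq_len(nrow(a)))
      cat(sprintf("  %-16s %-12s F %8.2f  p %.4f%s\n", a$analyte[i],
                  a$factor[i], a$F[i], a$p[i],
                  ifelse(a$significant[i], "  (significant)", "")))
  } else cat("  (none)\n")
  invisible(x)
}
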