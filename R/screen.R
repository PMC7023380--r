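#' Default authenticity and compliance rules
#'
#' The guidance-value rules applied to quantified contents (mg/kg):
#' \itemize{
#'   \item \code{omc_arabica}: declared 100% arabica with OMC strictly above
#'     50 mg/kg is suspicious (robusta admixture); 50 exactly is consistent.
#'   \item \code{caffeine_decaf}: declared decaffeinated coffee must stay
#'     strictly below 1000 mg/kg caffeine (German coffee regulation);
#'     1000 or more is out of spec.
#'   \item \code{kahweol_robusta}: declared 100% robusta with kahweol at or
#'     above 300 mg/kg suggests arabica character; disabled by default.
#' }
#' Green (raw) coffee results are always capped at `indicative_only`
#' regardless of rules, since the method is not validated for that matrix.
#'
#' @return data.frame with columns `rule`, `declared_type`, `analyte`,
#'   `threshold_mg_kg`, `trigger` (`"gt"` strictly above, `"ge"` at or
#'   above), `verdict`, `enabled`
#' @export
screeningRules <- function() {
  data.frame(
    rule = c("omc_arabica", "caffeine_decaf", "kahweol_robusta"),
    declared_type = c("arabica_100", "decaffeinated", "robusta_100"),
    analyte = c("omc", "caffeine", "kahweol"),
    threshold_mg_kg = c(50, 1000, 300),
    trigger = c("gt", "ge", "ge"),
    verdict = c("suspicious", "out_of_spec", "suspicious"),
    enabled = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Screen a quantified sample against its declaration
#'
#' Evaluates the enabled rules that apply to the declared coffee type.
#' Verdict precedence: `out_of_spec` over `suspicious` over `consistent`;
#' a `green` declaration caps the verdict at `indicative_only`. A rule whose
#' analyte is missing from `contents` is skipped with a warning, never
#' silently passed.
#'
#' @param contents named numeric vector of analyte contents in mg/kg
#' @param declared_type one of `"arabica_100"`, `"robusta_100"`, `"blend"`,
#'   `"decaffeinated"`, `"green"`
#' @param sample_id identifier carried into the report
#' @param rules rules table, see [screeningRules()]
#' @return list of class `ScreeningReport`: `sample_id`, `contents_mg_kg`,
#'   `verdict`, `triggered_rules`, `skipped_rules`, `notes`
#' @export
classifySample <- function(contents, declared_type, sample_id = "sample",
                           rules = screeningRules()) {
  types <- c("arabica_100", "robusta_100", "blend", "decaffeinated", "green")
  if (!declared_type %in% types)
    stop("declared_type must be one of: ", paste(types, collapse = ", "),
         call. = FALSE)
  triggered <- character(0)
  skipped <- character(0)
  notes <- character(0)
  verdict <- "consistent"
  rank <- c(consistent = 0, suspicious = 1, out_of_spec = 2)
  applicable <- rules[rules$enabled & rules$declared_type == declared_type, ]
  for (i in seq_len(nrow(applicable))) {
    r <- applicable[i, ]
    val <- if (r$analyte %in% names(contents)) contents[[r$analyte]] else NA
    if (!is.finite(val)) {
      skipped <- c(skipped, r$rule)
      warning(sprintf("rule '%s' skipped: no %s content available", r$rule,
                      r$analyte))
      next
    }
    hit <- switch(r$trigger, gt = val > r$threshold_mg_kg,
                  ge = val >= r$threshold_mg_kg)
    if (hit) {
      triggered <- c(triggered, r$rule)
      if (rank[r$verdict] > rank[verdict]) verdict <- r$verdict
      notes <- c(notes, sprintf(
        "%s: %s %.1f mg/kg vs guidance %.0f -- requires confirmatory analysis",
        r$rule, r$analyte, val, r$threshold_mg_kg))
    }
  }
  if (declared_type == "green") {
    verdict <- "indicative_only"
    notes <- c(notes,
               "green coffee: method not validated, results indicative only")
  }
  structure(list(sample_id = sample_id, contents_mg_kg = contents,
                 declared_type = declared_type, verdict = verdict,
                 triggered_rules = triggered, skipped_rules = skipped,
                 notes = notes),
            class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat(sprintf("Sample '%s' (declared %s): %s\n", x$sample_id,
              x$declared_type, toupper(x$verdict)))
  if (length(x$triggered_rules))
    cat("  triggered:", paste(x$triggered_rules, collapse = ", "), "\n")
  for (n in x$notes) cat("  -", n, "\n")
  invisible(x)
}

#' Quality-control check of the control solution
#'
#' Integrates the configured control window and checks the integral against
#' an inclusive tolerance band; run after each measurement series as a
#' safeguard that the analyses were performed properly.
#'
#' @param spectrum control-solution spectrum
#' @param window integration window (ppm)
#' @param band `c(low, high)` acceptance band for the integral (inclusive)
#' @param method integration method (default `"sum"`)
#' @return list: `pass` (logical), `integral`, `band`
#' @export
qcControlCheck <- function(spectrum, window, band, method = "sum") {
  ir <- integrateWindow(spectrum, window, method)
  band <- sort(as.numeric(band))
  list(pass = ir$raw_area >= band[1] && ir$raw_area <= band[2],
       integral = ir$raw_area, band = band)
}

#' Run the screening pipeline over a batch
#'
#' For each input -- an [NMRSpectrum-class] object or a spectrum file path --
#' quantifies all analytes and screens the contents against the sample's
#' declaration. A failure in one sample is recorded and does not abort the
#' batch.
#'
#' @param inputs list of spectra and/or file paths
#' @param declared_types character vector of declarations (recycled if
#'   length 1)
#' @param cal an [EreticCalibration-class]
#' @param analytes analyte table
#' @param rules screening rules
#' @param method integration method
#' @param limits optional limits table passed to [quantifySample()]
#' @return list of class `PipelineResult`: `quantification` (data.frame over
#'   all samples), `screening` (data.frame: sample, declared, verdict,
#'   triggered), `reports` (list of `ScreeningReport`), `errors` (named
#'   character), `exit_status` (1 if any sample is suspicious or out of
#'   spec, else 0)
#' @export
runPipeline <- function(inputs, declared_types, cal,
                        analytes = coffeeAnalytes(), rules = screeningRules(),
                        method = "linefit", limits = NULL) {
  n <- length(inputs)
  if (n == 0)
    return(structure(list(quantification = data.frame(),
                          screening = data.frame(), reports = list(),
                          errors = character(0), exit_status = 0L),
                     class = "PipelineResult"))
  declared_types <- rep_len(declared_types, n)
  ids <- names(inputs)
  if (is.null(ids)) ids <- sprintf("sample%02d", seq_len(n))
  quant <- list(); screens <- list(); reports <- list()
  errors <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      sp <- inputs[[i]]
      if (is.character(sp)) sp <- readSpectrum(sp)
      q <- quantifySample(sp, analytes, cal, method = method, limits = limits)
      contents <- stats::setNames(q$content_mg_kg, q$analyte)
      rep_i <- classifySample(contents, declared_types[i], sample_id = ids[i],
                              rules = rules)
      q$sample_id <- ids[i]
      list(q = q, rep = rep_i)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[ids[i]] <- conditionMessage(res)
      next
    }
    quant[[ids[i]]] <- res$q
    reports[[ids[i]]] <- res$rep
    screens[[ids[i]]] <- data.frame(
      sample_id = ids[i], declared_type = declared_types[i],
      verdict = res$rep$verdict,
      triggered = paste(res$rep$triggered_rules, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  screening <- if (length(screens)) do.call(rbind, c(screens, list(
    make.row.names = FALSE))) else data.frame()
  flagged <- length(screening) && nrow(screening) &&
    any(screening$verdict %in% c("suspicious", "out_of_spec"))
  structure(list(
    quantification = if (length(quant)) do.call(rbind, c(quant, list(
      make.row.names = FALSE))) else data.frame(),
    screening = screening, reports = reports, errors = errors,
    exit_status = if (flagged) 1L else 0L), class = "PipelineResult")
}
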