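# alamarBlue viability, 4PL dose-response fitting, IC_x extraction, SDR.

# Molar extinction coefficients of oxidized alamarBlue used by the standard
# two-wavelength percent-reduction formula.
.AB_C570 <- 117216
.AB_C600 <- 80586

#' Percent cell viability from alamarBlue absorbances
#'
#' Two-wavelength percent difference in reduction of the alamarBlue reagent
#' between treated and untreated wells:
#' \deqn{100 (117216 A_{570}^{test} - 80586 A_{600}^{test}) /
#'       (117216 A_{570}^{untr} - 80586 A_{600}^{untr})}
#' The result is invariant to a common rescaling of all four absorbances.
#'
#' @param test570,test600 absorbances of the treated well at 570/600 nm.
#' @param untreated570,untreated600 absorbances of the untreated well.
#' @return Percent viability (100 = untreated level). Vectorized.
#' @export
percent_viability <- function(test570, test600, untreated570, untreated600) {
  if (any(c(test570, test600, untreated570, untreated600) <= 0))
    stop("assay error: non-positive absorbance")
  den <- .AB_C570 * untreated570 - .AB_C600 * untreated600
  if (any(den <= 0))
    stop("assay error: non-positive untreated-well denominator")
  100 * (.AB_C570 * test570 - .AB_C600 * test600) / den
}

#' Read / write a plate absorbance table
#'
#' TSV with columns `line_id`, `drug` (`imatinib`, `omacetaxine`, `none`),
#' `dose_molar`, `replicate`, `abs570`, `abs600`. Untreated wells have
#' `drug = "none"` and `dose_molar = 0`.
#'
#' @param path file path.
#' @return data.frame of plate records.
#' @export
read_plates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  req <- c("line_id", "drug", "dose_molar", "replicate", "abs570", "abs600")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("plate format error: missing column(s) ", paste(miss, collapse = ", "))
  df$line_id <- as.character(df$line_id)
  df$drug <- as.character(df$drug)
  df
}

#' @rdname read_plates
#' @param plates data.frame of plate records.
#' @export
write_plates <- function(plates, path) {
  utils::write.table(plates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average triplicate absorbances and convert to viability points
#'
#' Replicate absorbances are averaged before the viability equation (the
#' assay's order of operations), each treated mean being referenced to the
#' same line's mean untreated absorbances.
#'
#' @param plates data.frame as from [read_plates()].
#' @return data.frame with `line_id`, `drug`, `dose_molar`, `viability`
#'   (one row per line/drug/dose).
#' @export
average_replicates <- function(plates) {
  treated <- plates[plates$drug != "none" & plates$dose_molar > 0, , drop = FALSE]
  if (nrow(treated) == 0) stop("missing-data error: no treated plate records")
  untr <- plates[plates$drug == "none" & plates$dose_molar == 0, , drop = FALSE]
  ukey <- split(untr, untr$line_id)
  grp <- split(treated,
               list(treated$line_id, treated$drug, treated$dose_molar),
               drop = TRUE)
  out <- lapply(grp, function(g) {
    u <- ukey[[g$line_id[1]]]
    if (is.null(u) || nrow(u) == 0)
      stop("missing-control error: no untreated wells for line ", g$line_id[1])
    data.frame(line_id = g$line_id[1], drug = g$drug[1],
               dose_molar = g$dose_molar[1],
               viability = percent_viability(mean(g$abs570), mean(g$abs600),
                                             mean(u$abs570), mean(u$abs600)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$line_id, out$drug, out$dose_molar), , drop = FALSE]
}

# 4PL on log10 dose: viability(x) = bottom + (top-bottom)/(1 + 10^(hill*(x-m)))
four_pl <- function(x, bottom, top, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (x - log_ic50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `viability = bottom + (top - bottom) / (1 + 10^(hill (x - log_ic50)))`
#' with `x = log10(dose)`. `hill > 0` gives an inhibitory (decreasing) curve.
#' A heuristic start (midpoint crossing, hill = 1) is refined by
#' Levenberg-Marquardt under box constraints; if it fails or fits poorly, a
#' deterministic multi-start grid over `log_ic50` spanning the observed dose
#' range and `hill in {0.5, 1, 2}` is searched and the best SSE kept.
#'
#' @param dose doses (molar, > 0), at least 4 distinct values.
#' @param viability percent viability per dose.
#' @param fixed_top optionally fix the top asymptote (e.g. 100).
#' @return Object of class `dose_response_fit`: list with `bottom`, `top`,
#'   `log_ic50`, `hill`, `sse`, `converged`, `n`.
#' @export
fit_4pl <- function(dose, viability, fixed_top = NULL) {
  if (length(dose) != length(viability)) stop("argument error: length mismatch")
  if (length(unique(dose)) < 4)
    stop("argument error: need >= 4 distinct doses for a 4PL fit")
  if (any(dose <= 0)) stop("argument error: doses must be positive")
  if (diff(range(viability)) < 1e-8)
    stop("fit error: constant viability, no dose response to fit")
  x <- log10(dose)
  df <- data.frame(x = x, v = viability)

  free_top <- is.null(fixed_top)
  lower <- c(bottom = 0,   top = 50 + 1e-6, log_ic50 = min(x) - 2, hill = 1e-3)
  upper <- c(bottom = 100 - 1e-6, top = 150, log_ic50 = max(x) + 2, hill = 10)

  one_fit <- function(start) {
    form <- if (free_top)
      v ~ bottom + (top - bottom) / (1 + 10^(hill * (x - log_ic50)))
    else
      v ~ bottom + (fixed_top - bottom) / (1 + 10^(hill * (x - log_ic50)))
    keep <- if (free_top) names(lower) else setdiff(names(lower), "top")
    tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start[keep],
                        lower = lower[keep], upper = upper[keep],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  # heuristic start: log_ic50 at the dose whose viability is nearest midway
  vmid <- (max(viability) + min(viability)) / 2
  start0 <- c(bottom = max(min(viability), 0),
              top = min(max(viability), 150),
              log_ic50 = x[which.min(abs(viability - vmid))], hill = 1)
  start0["top"] <- max(start0["top"], 50 + 1e-3)
  fits <- list(one_fit(start0))
  best <- best_of(fits)
  if (is.null(best) || stats::deviance(best) > length(x) * 25) {
    grid <- expand.grid(log_ic50 = seq(min(x), max(x), length.out = 7),
                        hill = c(0.5, 1, 2))
    for (r in seq_len(nrow(grid))) {
      s <- start0
      s["log_ic50"] <- grid$log_ic50[r]; s["hill"] <- grid$hill[r]
      fits <- c(fits, list(one_fit(s)))
    }
    best <- best_of(fits)
  }
  if (is.null(best))
    stop("fit error: 4PL did not converge from any start (n=", length(x),
         ", viability range ", paste(round(range(viability), 1), collapse = "-"), ")")
  cf <- stats::coef(best)
  structure(list(bottom = unname(cf["bottom"]),
                 top = if (free_top) unname(cf["top"]) else fixed_top,
                 log_ic50 = unname(cf["log_ic50"]),
                 hill = unname(cf["hill"]),
                 sse = stats::deviance(best),
                 converged = TRUE, n = length(x)),
            class = "dose_response_fit")
}

best_of <- function(fits) {
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(NULL)
  fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: bottom %.2f, top %.2f, log10 IC50 %.3f, hill %.3f (SSE %.3g, n=%d)\n",
              x$bottom, x$top, x$log_ic50, x$hill, x$sse, x$n))
  invisible(x)
}

#' Inhibitory concentration IC_x from a fitted curve
#'
#' IC_x is the dose at which fitted viability equals `100 - threshold`
#' (threshold = percent inhibition), solved in closed form on the 4PL curve.
#'
#' @param fit a `dose_response_fit`.
#' @param threshold percent inhibition in (0, 100); vectorized.
#' @return dose(s) in molar units.
#' @export
inhibitory_concentration <- function(fit, threshold) {
  if (any(threshold <= 0 | threshold >= 100))
    stop("argument error: threshold must be in (0, 100)")
  target <- 100 - threshold
  if (any(target <= fit$bottom | target >= fit$top))
    stop("unattainable-threshold error: target viability ",
         paste(round(target[target <= fit$bottom | target >= fit$top], 1),
               collapse = ", "),
         " outside fitted asymptotes (", round(fit$bottom, 1), ", ",
         round(fit$top, 1), ")")
  x <- fit$log_ic50 + log10((fit$top - target) / (target - fit$bottom)) / fit$hill
  10^x
}

#' Sensitivity of drug response (SDR)
#'
#' Slope of the ordinary least-squares regression of percent viability on
#' log10(dose); more negative means a more sensitive cell line.
#'
#' @param dose doses (molar, > 0), at least 3 points.
#' @param viability percent viability per dose.
#' @return list with `slope` (percent viability per log10 molar), `intercept`,
#'   `n_points`.
#' @export
sdr <- function(dose, viability) {
  if (length(dose) < 3) stop("argument error: SDR needs >= 3 points")
  if (any(dose <= 0)) stop("argument error: doses must be positive")
  x <- log10(dose)
  if (diff(range(x)) < 1e-12) stop("singular-design error: all doses identical")
  fit <- stats::lm(viability ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_points = length(dose))
}
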