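# Packaged molar masses (g/mol): free 6-aminohexanoic acid, the PA 6 repeat
# unit (condensation subtracts one water), and water.
M_6AHA <- 131.17
M_REPEAT <- 113.16
M_WATER <- 18.015
# Enzyme molar mass implied by the 50 nM = 1.90 mg/L assay conditions.
MW_ENZYME <- 38000

#' Convert a molar enzyme concentration to a mass concentration
#' @param nM Enzyme concentration in nmol/L.
#' @param mw Molar mass in g/mol.
#' @return Concentration in mg/L.
#' @export
enzyme_mg_per_L <- function(nM, mw = MW_ENZYME) nM * mw * 1e-6

#' Convert a mass-based specific activity to 6-AHA-equivalent micromoles
#' @param x Activity in mg (6-AHA eq.) per hour per mg enzyme.
#' @param molar_mass Product molar mass in g/mol.
#' @return Activity in umol per hour per mg enzyme.
#' @export
activity_mg_to_umol <- function(x, molar_mass = M_6AHA) x / molar_mass * 1000

#' Quantify released amines from a photometric calibration
#'
#' Fits a straight line (free intercept) through calibration standards of
#' known amine concentration and inverse-maps sample absorbances onto it.
#' Samples outside the calibrated range are flagged; readings mapping below
#' zero are floored at zero and flagged.
#'
#' @param absorbance Numeric sample absorbances.
#' @param standards Data frame with columns `conc_uM` and `absorbance`
#'   (at least three points spanning the sample range).
#' @param min_r2 Minimum calibration R-squared (error below it).
#' @return Tibble with `absorbance`, `conc_uM`, `flag`
#'   (`"ok"`, `"below_range"`, `"above_range"`, `"floored"`).
#' @export
calibrate_and_quantify <- function(absorbance, standards, min_r2 = 0.98) {
  if (nrow(standards) < 3) stop("need at least 3 calibration standards")
  fit <- stats::lm(absorbance ~ conc_uM, data = standards)
  ss_tot <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  if (is.na(r2) || r2 < min_r2) {
    stop("calibration R-squared ", round(r2, 4), " below ", min_r2)
  }
  b <- stats::coef(fit)[[1]]; m <- stats::coef(fit)[[2]]
  conc <- (absorbance - b) / m
  rng <- range(standards$conc_uM)
  flag <- dplyr::case_when(
    conc < 0 ~ "floored",
    conc < rng[1] ~ "below_range",
    conc > rng[2] ~ "above_range",
    TRUE ~ "ok"
  )
  tibble::tibble(absorbance = absorbance, conc_uM = pmax(conc, 0), flag = flag)
}

#' Background-correct a measurement series
#'
#' Pointwise subtraction of a blank series (non-enzymatic amine release:
#' extraction of unpolymerised monomers and spontaneous hydrolysis) from a
#' sample series on a shared time grid. Negative corrected values are
#' floored at zero; their count is attached and reported with a warning.
#'
#' @param sample,blank Data frames with columns `time_h` and `amine_uM`.
#' @return Tibble `time_h`, `amine_uM` (corrected) with attribute
#'   `n_floored`.
#' @export
background_correct <- function(sample, blank) {
  if (nrow(sample) != nrow(blank) ||
      !isTRUE(all.equal(sample$time_h, blank$time_h))) {
    stop("sample and blank series must share the same time grid")
  }
  corr <- sample$amine_uM - blank$amine_uM
  n_floored <- sum(corr < 0)
  if (n_floored > 0) {
    warning(n_floored, " corrected value(s) below zero were floored")
  }
  out <- tibble::tibble(time_h = sample$time_h, amine_uM = pmax(corr, 0))
  attr(out, "n_floored") <- n_floored
  out
}

#' Specific activity from screening records
#'
#' Specific activity = released 6-AHA equivalents (umol per litre of
#' reaction) divided by incubation time and enzyme mass concentration,
#' i.e. umol/(h * mg enzyme). When both a molar and a mass enzyme
#' concentration are present their consistency is checked (within 2 percent
#' via the enzyme molar mass).
#'
#' @param records Data frame with columns `amine_uM`, `time_h`, and
#'   `enzyme_mg_per_L` (or `enzyme_nM`); optional `replicate`.
#' @param mw Enzyme molar mass in g/mol (used when only `enzyme_nM` given).
#' @return Tibble with `mean`, `sem`, `n` (replicates).
#' @export
specific_activity <- function(records, mw = MW_ENZYME) {
  rec <- tibble::as_tibble(records)
  if (!"enzyme_mg_per_L" %in% names(rec)) {
    if (!"enzyme_nM" %in% names(rec)) {
      stop("records need 'enzyme_mg_per_L' or 'enzyme_nM'")
    }
    rec$enzyme_mg_per_L <- enzyme_mg_per_L(rec$enzyme_nM, mw)
  } else if ("enzyme_nM" %in% names(rec)) {
    implied <- enzyme_mg_per_L(rec$enzyme_nM, mw)
    if (any(abs(implied - rec$enzyme_mg_per_L) / rec$enzyme_mg_per_L > 0.02)) {
      stop("molar and mass enzyme concentrations disagree by more than 2%")
    }
  }
  if (any(rec$time_h <= 0)) stop("incubation time must be positive")
  if (any(rec$enzyme_mg_per_L <= 0)) stop("enzyme concentration must be positive")
  # umol/L released over mg/L enzyme: volume cancels
  act <- rec$amine_uM / (rec$time_h * rec$enzyme_mg_per_L)
  if ("replicate" %in% names(rec)) {
    act <- tapply(act, rec$replicate, mean)
  }
  aggregate_replicas(as.numeric(act))
}

#' Fold-change of a variant over its parent with error propagation
#'
#' Ratio of means with first-order standard-error propagation:
#' sem = ratio * sqrt((sem_v / v)^2 + (sem_p / p)^2). The rounded value
#' follows the one-decimal, half-up reporting convention.
#'
#' @param variant,parent Numeric length-2 vectors `c(mean, sem)` or one-row
#'   data frames with `mean` and `sem`.
#' @return Tibble with `fold`, `sem`, `fold_rounded`.
#' @export
fold_change <- function(variant, parent) {
  get2 <- function(x) {
    if (is.data.frame(x)) c(x$mean[1], x$sem[1])
    else if (is.list(x)) c(x[["mean"]][1], x[["sem"]][1])
    else unname(x[1:2])
  }
  v <- get2(variant); p <- get2(parent)
  if (is.na(p[1]) || p[1] <= 0) stop("parent mean activity must be positive")
  ratio <- v[1] / p[1]
  sem <- ratio * sqrt((v[2] / v[1])^2 + (p[2] / p[1])^2)
  tibble::tibble(fold = ratio, sem = sem,
                 fold_rounded = floor(ratio * 10 + 0.5) / 10)
}

#' Fit Michaelis-Menten kinetics (conventional or inverse)
#'
#' Nonlinear least squares of v = Vmax * x / (Km + x). Under conventional
#' conditions (convMM, enzyme saturated by substrate) x is the substrate
#' loading in g/L and Km is a half-saturation loading; under inverse
#' conditions (invMM, excess solid substrate titrated with enzyme) x is the
#' enzyme concentration and Km reflects the density of targetable attack
#' sites. Initialised at Vmax = max(v), Km = median(x), with restarts.
#'
#' @param data Data frame with columns `x` and `rate`.
#' @param model `"convMM"` or `"invMM"`.
#' @return Object of class `pa_mm_fit` with `coef` (tibble of estimates and
#'   standard errors), `r2`, `model`, `fit`.
#' @export
fit_mm <- function(data, model = c("convMM", "invMM")) {
  model <- match.arg(model)
  data <- tibble::as_tibble(data)
  if (length(unique(data$x)) < 4) stop("need at least 4 distinct x values")
  starts <- list(
    list(Vmax = max(data$rate), Km = stats::median(data$x)),
    list(Vmax = 2 * max(data$rate), Km = max(data$x)),
    list(Vmax = max(data$rate), Km = stats::quantile(data$x, 0.25)[[1]])
  )
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rate ~ Vmax * x / (Km + x), data = data, start = s,
                        lower = c(Vmax = 0, Km = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("Michaelis-Menten fit did not converge after restarts; x range [",
         min(data$x), ", ", max(data$x), "], rate range [",
         min(data$rate), ", ", max(data$rate), "]")
  }
  sm <- summary(fit)
  est <- sm$coefficients
  pred <- stats::predict(fit)
  ss_res <- sum((data$rate - pred)^2)
  ss_tot <- sum((data$rate - mean(data$rate))^2)
  structure(list(
    coef = tibble::tibble(term = rownames(est), estimate = unname(est[, 1]),
                          std_error = unname(est[, 2])),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    model = model, fit = fit, data = data
  ), class = "pa_mm_fit")
}

#' @export
print.pa_mm_fit <- function(x, ...) {
  cat("<pa_mm_fit>", x$model, "\n")
  print(x$coef)
  cat("R-squared:", round(x$r2, 4), "\n")
  invisible(x)
}

#' Tidy coefficients of a Michaelis-Menten fit
#' @param x A `pa_mm_fit`.
#' @param ... Unused.
#' @return Tibble of terms, estimates and standard errors.
#' @export
#' @exportS3Method generics::tidy
tidy.pa_mm_fit <- function(x, ...) x$coef

#' One-row summary of a Michaelis-Menten fit
#' @param x A `pa_mm_fit`.
#' @param ... Unused.
#' @return One-row tibble with Vmax, Km and fit statistics.
#' @export
#' @exportS3Method generics::glance
glance.pa_mm_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 vmax = x$coef$estimate[x$coef$term == "Vmax"],
                 km = x$coef$estimate[x$coef$term == "Km"],
                 r_squared = x$r2, n = nrow(x$data))
}

#' Degree of depolymerization and product composition
#'
#' DoD (percent w/w) is the repeat-unit mass released as soluble products
#' over the initial polymer loading:
#' 100 * sum(n_i * u_i * M_repeat) / (loading * V), with n_i the product
#' amount (umol), u_i its repeat-unit count (1 for 6-AHA and the PA 6,6
#' monomer, 2 for the 6-AHA dimer) and M_repeat = 113.16 g/mol. The monomer
#' fraction is the share of released repeat-unit mass carried by fully
#' depolymerised monomer. `basis = "free-monomer"` instead weighs products
#' by their free molar masses (hydrolysis adds back water).
#'
#' @param products Data frame with columns `amount_umol`, `repeat_units`
#'   and optional `monomer` (logical: fully depolymerised product; default
#'   `repeat_units == 1`) and optional `time_h`.
#' @param loading_g_per_L Substrate loading in g/L.
#' @param volume_L Reaction volume (amounts are umol in this volume).
#' @param basis `"repeat"` (default) or `"free-monomer"`.
#' @return Tibble of class `pa_depolymerization` with one row per time point
#'   (`time_h`, `dod_pct`, `monomer_fraction_pct`, `released_mg`).
#' @export
degree_of_depolymerization <- function(products, loading_g_per_L,
                                       volume_L = 1,
                                       basis = c("repeat", "free-monomer")) {
  basis <- match.arg(basis)
  if (loading_g_per_L <= 0) stop("substrate loading must be positive")
  pr <- tibble::as_tibble(products)
  if (any(pr$amount_umol < 0)) stop("product amounts must be non-negative")
  if (!"monomer" %in% names(pr)) pr$monomer <- pr$repeat_units == 1
  if (!"time_h" %in% names(pr)) pr$time_h <- 0
  unit_mass <- function(u) {
    if (basis == "repeat") u * M_REPEAT else u * M_6AHA - (u - 1) * M_WATER
  }
  out <- pr |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      released_mg = sum(.data$amount_umol * unit_mass(.data$repeat_units)) * 1e-3,
      monomer_fraction_pct = {
        tot <- sum(.data$amount_umol * .data$repeat_units)
        if (tot > 0) 100 * sum(.data$amount_umol * .data$repeat_units *
                                 .data$monomer) / tot else NA_real_
      },
      .groups = "drop") |>
    dplyr::mutate(dod_pct = 100 * (.data$released_mg / 1000) /
                    (loading_g_per_L * volume_L)) |>
    dplyr::select("time_h", "dod_pct", "monomer_fraction_pct", "released_mg") |>
    dplyr::arrange(.data$time_h)
  if (any(diff(out$dod_pct) < -1e-9)) {
    warning("degree of depolymerization decreases within the series")
  }
  class(out) <- c("pa_depolymerization", class(out))
  out
}

#' Extract a melting temperature from a thermal melt curve
#'
#' Tm is located at the maximum of the smoothed first derivative of the
#' signal with respect to temperature and, by default, refined by a
#' two-state Boltzmann fit
#' S(T) = low + (high - low) / (1 + exp((Tm - T) / slope)).
#'
#' @param curve Data frame with columns `temperature_C` and `signal`.
#' @param refine Refine the derivative estimate with a Boltzmann fit.
#' @param span Half-width (grid points) of the moving-average smoother.
#' @return Object of class `pa_tm_fit` with `tm` (deg C), `se`, `method`.
#' @export
extract_tm <- function(curve, refine = TRUE, span = 2) {
  cv <- tibble::as_tibble(curve)[order(curve$temperature_C), ]
  t <- cv$temperature_C; s <- cv$signal
  if (length(t) < 5) stop("melt curve too short")
  if (any(diff(t) <= 0)) stop("temperature grid must be strictly increasing")
  k <- 2 * span + 1
  sm <- stats::filter(s, rep(1 / k, k), sides = 2)
  pad <- span
  sm[seq_len(pad)] <- s[seq_len(pad)]
  sm[(length(s) - pad + 1):length(s)] <- s[(length(s) - pad + 1):length(s)]
  ds <- diff(as.numeric(sm)) / diff(t)
  tmid <- (t[-1] + t[-length(t)]) / 2
  imax <- which.max(abs(ds))
  if (imax <= 1 || imax >= length(ds)) {
    stop("no transition within the scanned range (derivative peaks at a ",
         "grid boundary)")
  }
  tm0 <- tmid[imax]
  tm <- tm0; se <- (t[2] - t[1]) / 2; method <- "derivative"
  if (refine) {
    lo <- min(s); hi <- max(s)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        signal ~ low + (high - low) / (1 + exp((tm - temperature_C) / slope)),
        data = cv,
        start = list(low = lo, high = hi, tm = tm0, slope = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- summary(fit)$coefficients
      tm <- co["tm", 1]; se <- co["tm", 2]; method <- "boltzmann"
      if (tm < min(t) || tm > max(t)) {
        stop("fitted melting temperature outside the scanned range")
      }
    }
  }
  structure(list(tm = tm, se = se, method = method, curve = cv),
            class = "pa_tm_fit")
}

#' @export
print.pa_tm_fit <- function(x, ...) {
  cat("<pa_tm_fit> Tm =", sprintf("%.1f", x$tm), "+/-",
      sprintf("%.1f", x$se), "deg C (", x$method, ")\n")
  invisible(x)
}

#' Tidy summary of a melting-temperature fit
#' @param x A `pa_tm_fit`.
#' @param ... Unused.
#' @return One-row tibble with the melting temperature and standard error.
#' @export
#' @exportS3Method generics::tidy
tidy.pa_tm_fit <- function(x, ...) {
  tibble::tibble(term = "tm", estimate = x$tm, std_error = x$se,
                 method = x$method)
}

#' Classify epistasis of a combined variant against its singles
#'
#' The null expectation for non-interacting substitutions is multiplicative
#' on fold-changes (additive improvements in log space): expected =
#' product of single folds, with first-order error propagation. The combo is
#' classified `negative` if it falls more than `k_sigma` propagated sigmas
#' below the expectation, `positive` if above, else `additive`.
#'
#' @param singles Data frame with columns `fold` and `sem` (>= 2 rows), or a
#'   list of length-2 vectors.
#' @param combo Length-2 vector `c(fold, sem)` or one-row data frame.
#' @param k_sigma Classification width in propagated sigmas.
#' @return List of class `pa_epistasis` with `class`, `expected`,
#'   `sigma_expected`, `combo`.
#' @export
classify_epistasis <- function(singles, combo, k_sigma = 2) {
  if (is.list(singles) && !is.data.frame(singles)) {
    singles <- do.call(rbind, lapply(singles, function(v)
      data.frame(fold = v[1], sem = v[2])))
  }
  singles <- tibble::as_tibble(singles)
  if (nrow(singles) < 2) stop("need at least two single-substitution folds")
  cb <- if (is.list(combo)) c(combo[["fold"]][1], combo[["sem"]][1])
        else unname(combo[1:2])
  if (any(singles$fold <= 0) || cb[1] <= 0) {
    stop("fold-changes must be positive")
  }
  expected <- prod(singles$fold)
  sigma <- expected * sqrt(sum((singles$sem / singles$fold)^2))
  cls <- if (cb[1] < expected - k_sigma * sigma) "negative"
         else if (cb[1] > expected + k_sigma * sigma) "positive"
         else "additive"
  structure(list(class = cls, expected = expected, sigma_expected = sigma,
                 combo = cb[1], combo_sem = cb[2], k_sigma = k_sigma),
            class = "pa_epistasis")
}

#' @export
print.pa_epistasis <- function(x, ...) {
  cat("<pa_epistasis>", x$class, ": combo ", round(x$combo, 2),
      " vs expected ", round(x$expected, 2), " +/- ",
      round(x$sigma_expected, 2), " (k =", x$k_sigma, ")\n")
  invisible(x)
}
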