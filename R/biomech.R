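#' Craniomandibular bite-force measurements
#'
#' The nine linear measurements (mm) entering the relative bite-force model:
#' `ZW` internal width across the zygomatic arches; `BW` braincase width;
#' `POW` postorbital constriction width; `TFL` temporal fossa length; `MAT`
#' temporalis inlever moment arm (mandibular cotyle to coronoid tip); `CFL`
#' coronoid fossa length; `MSW` masseteric scar width; `MSL` masseteric scar
#' length; `MAM` masseter inlever moment arm (cotyle to ventral mandibular
#' rim).
#'
#' @param ZW,BW,POW,TFL,MAT,CFL,MSW,MSL,MAM positive measurements in mm;
#'   `ZW` must be at least `(BW + POW)/2` (the effective temporalis origin
#'   width cannot be negative; equality gives zero temporalis output).
#' @return list of class `bite_force_measures`.
#' @export
bite_force_measures <- function(ZW, BW, POW, TFL, MAT, CFL, MSW, MSL, MAM) {
  vals <- c(ZW = ZW, BW = BW, POW = POW, TFL = TFL, MAT = MAT,
            CFL = CFL, MSW = MSW, MSL = MSL, MAM = MAM)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all nine measurements must be positive and finite")
  if (ZW < (BW + POW) / 2)
    stop("ZW must be at least (BW + POW)/2; the temporalis cross-section ",
         "term would be negative under the square root, which signals ",
         "inconsistent measurements")
  structure(as.list(vals), class = "bite_force_measures")
}

#' Relative bite-force estimate
#'
#' Relative (not absolute) force output of the two main mandibular adductors
#' from dry-skull measurements: temporalis output is
#' sqrt(((ZW - (BW + POW)/2)/2) * TFL) * MAT (cross-section proxy from the
#' temporal fossa times its inlever), masseter output is
#' sqrt(((CFL + MSW)/2) * MSL) * MAM. Their sum estimates one side of the
#' skull; the total doubles it for both sides. Outputs scale as length
#' squared (c-times larger skulls give c^2 the relative force).
#'
#' @param m a [bite_force_measures()] object (or list with the nine fields).
#' @return list with `temporalis`, `masseter`, `per_side`, `total`
#'   (dimension mm^2; relative units).
#' @examples
#' m <- bite_force_measures(ZW = 100, BW = 60, POW = 40, TFL = 80, MAT = 30,
#'                          CFL = 30, MSW = 20, MSL = 50, MAM = 25)
#' relative_bite_force(m)
#' @export
relative_bite_force <- function(m) {
  if (!inherits(m, "bite_force_measures"))
    m <- do.call(bite_force_measures, as.list(m)[c("ZW", "BW", "POW", "TFL",
                                                   "MAT", "CFL", "MSW", "MSL",
                                                   "MAM")])
  temporalis <- sqrt(((m$ZW - (m$BW + m$POW) / 2) / 2) * m$TFL) * m$MAT
  masseter <- sqrt(((m$CFL + m$MSW) / 2) * m$MSL) * m$MAM
  per_side <- temporalis + masseter
  list(temporalis = temporalis, masseter = masseter,
       per_side = per_side, total = 2 * per_side)
}

#' Predict body mass from condylobasal skull length
#'
#' Ordinary least squares of log10(body mass, kg) on log10(CBL, mm) over
#' species means (species means are computed on the arithmetic scale, then
#' log-transformed), back-transformed as 10^yhat without bias correction
#' (optionally with the smearing-free log-normal correction).
#'
#' @param cbl condylobasal length (mm) of the specimen(s) to predict.
#' @param training data frame with columns `species`, `cbl`, `mass`
#'   (per-specimen rows are averaged within species first).
#' @param bias_correction apply the log-normal back-transform correction
#'   10^(sigma^2 ln(10)/2) (default FALSE: direct prediction).
#' @return list of class `mass_prediction`: `mass` (kg), `slope`,
#'   `intercept`, `r_squared`, `n_species`.
#' @export
predict_body_mass <- function(cbl, training, bias_correction = FALSE) {
  stopifnot(all(c("species", "cbl", "mass") %in% names(training)))
  if (any(!is.finite(cbl)) || any(cbl <= 0)) stop("cbl must be positive")
  if (any(training$cbl <= 0) || any(training$mass <= 0))
    stop("training measurements must be positive")
  sp_cbl <- tapply(training$cbl, training$species, mean)
  sp_mass <- tapply(training$mass, training$species, mean)
  n_sp <- length(sp_cbl)
  if (n_sp < 2) stop("need at least 2 training species to fit a line")
  fit <- stats::lm(log10(sp_mass) ~ log10(sp_cbl))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  yhat <- intercept + slope * log10(cbl)
  corr <- if (bias_correction && n_sp > 2) {
    s2 <- sum(stats::residuals(fit)^2) / (n_sp - 2)
    10^(s2 * log(10) / 2)
  } else 1
  y <- log10(sp_mass)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(mass = corr * 10^yhat, slope = slope, intercept = intercept,
         r_squared = r2, n_species = n_sp),
    class = "mass_prediction")
}

#' @export
print.mass_prediction <- function(x, ...) {
  cat(sprintf(paste0("<mass_prediction> %.1f kg (log10 mass = %.3f + %.3f ",
                     "log10 CBL; r^2 = %.3f; %d species)\n"),
              x$mass[1], x$intercept, x$slope, x$r_squared, x$n_species))
  invisible(x)
}
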