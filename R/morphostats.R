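#' Round half away from zero
#'
#' Reporting-layer rounding: exact halves round up (away from zero), unlike
#' base R's round-half-even. Internal computations keep full precision.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Craniodental ratio
#'
#' Quotient of two positive linear measurements, optionally expressed as a
#' percentage and rounded half-up at the reporting layer (the conventional
#' precision is 3 decimals for ratios and 1 decimal for percentages).
#'
#' @param numerator,denominator positive measurements (mm).
#' @param decimals decimal places for reporting; `NULL` (default) returns
#'   full precision.
#' @param percent express as a percentage.
#' @return Dimensionless ratio (or percentage).
#' @examples
#' ratio(56.0, 236.3, decimals = 1, percent = TRUE)  # 23.7
#' @export
ratio <- function(numerator, denominator, decimals = NULL, percent = FALSE) {
  if (any(!is.finite(numerator)) || any(!is.finite(denominator)) ||
      any(numerator <= 0) || any(denominator <= 0))
    stop("ratio() requires positive finite measurements")
  r <- numerator / denominator
  if (percent) r <- 100 * r
  if (!is.null(decimals)) r <- round_half_up(r, decimals)
  r
}

#' Ratio profile of specimens in a measurement table
#'
#' Computes a named set of measurement ratios per specimen; rows with a
#' missing numerator or denominator get `NA`.
#'
#' @param table a [measurement_table()].
#' @param ratios named list; each element `c(numerator_var, denominator_var)`.
#' @param percent express as percentages.
#' @param decimals reporting rounding (half-up); `NULL` for full precision.
#' @return data frame with `specimen_id`, `group` and one column per ratio.
#' @export
ratio_profile <- function(table, ratios, percent = FALSE, decimals = NULL) {
  stopifnot(inherits(table, "measurement_table"), length(ratios) > 0)
  out <- table[, c("specimen_id", "group")]
  for (nm in names(ratios)) {
    pair <- ratios[[nm]]
    if (!all(pair %in% names(table)))
      stop("unknown variable(s) in ratio '", nm, "': ",
           paste(setdiff(pair, names(table)), collapse = ", "))
    num <- table[[pair[1]]]
    den <- table[[pair[2]]]
    val <- rep(NA_real_, nrow(table))
    ok <- !is.na(num) & !is.na(den)
    if (any(ok)) val[ok] <- ratio(num[ok], den[ok], decimals, percent)
    out[[nm]] <- val
  }
  out
}

#' Comparative range table
#'
#' Observed minimum and maximum of each ratio per comparison group.
#'
#' @param df data frame with columns `group`, `ratio`, `min`, `max`.
#' @return Validated data frame of class `range_table`.
#' @export
range_table <- function(df) {
  if (!all(c("group", "ratio", "min", "max") %in% names(df)))
    stop("range table needs columns group, ratio, min, max")
  if (any(df$min > df$max)) stop("range with min > max")
  class(df) <- c("range_table", "data.frame")
  df
}

#' Compare a ratio value against comparative ranges
#'
#' Verdict per group: `below`, `within` or `above` the group's observed
#' closed interval; values within but at or below the interval midpoint get
#' the qualifier `"lower half"`.
#'
#' @param value dimensionless ratio.
#' @param ranges a [range_table()].
#' @param ratio_name which ratio's ranges to use.
#' @return data frame with `group`, `min`, `max`, `verdict`, `qualifier`.
#' @examples
#' rt <- range_table(data.frame(group = "tiger", ratio = "nasal_cbl",
#'                              min = 0.333, max = 0.417))
#' range_compare(0.345, rt, "nasal_cbl")
#' @export
range_compare <- function(value, ranges, ratio_name) {
  stopifnot(inherits(ranges, "range_table"), length(value) == 1)
  sub <- ranges[ranges$ratio == ratio_name, , drop = FALSE]
  if (!nrow(sub)) stop("unknown ratio '", ratio_name, "' in range table")
  verdict <- ifelse(value < sub$min, "below",
                    ifelse(value > sub$max, "above", "within"))
  qualifier <- ifelse(verdict == "within" & value <= (sub$min + sub$max) / 2,
                      "lower half", "")
  data.frame(group = sub$group, min = sub$min, max = sub$max,
             verdict = verdict, qualifier = qualifier,
             stringsAsFactors = FALSE)
}

#' Size-adjusted principal components analysis
#'
#' Removes isometric size from a measurement table and runs a covariance PCA
#' on the adjusted variables. Adjustment `"ratio_cbl"` divides every other
#' variable by condylobasal length (the standard size denominator);
#' `"log_shape"` uses log-shape ratios: log(variable) minus the specimen's
#' mean log measurement. Rows with missing values are dropped (recorded in
#' the result).
#'
#' @param table a [measurement_table()] with >= 3 complete specimens and >= 2
#'   variables after adjustment.
#' @param adjustment `"ratio_cbl"` or `"log_shape"`.
#' @param cbl_var name of the condylobasal-length column (default `"CBL"`).
#' @return list of class `size_adjusted_pca`: `scores`, `loadings`,
#'   `eigenvalues`, `adjusted` (the adjusted data), `excluded`
#'   (specimen ids dropped for missingness), `adjustment`, `groups`.
#' @export
size_adjusted_pca <- function(table, adjustment = c("ratio_cbl", "log_shape"),
                              cbl_var = "CBL") {
  adjustment <- match.arg(adjustment)
  stopifnot(inherits(table, "measurement_table"))
  vars <- setdiff(names(table), c("specimen_id", "group"))
  X <- as.matrix(table[, vars, drop = FALSE])
  rownames(X) <- table$specimen_id
  complete <- stats::complete.cases(X)
  excluded <- table$specimen_id[!complete]
  X <- X[complete, , drop = FALSE]
  groups <- table$group[complete]
  if (nrow(X) < 3) stop("need >= 3 complete-case specimens")
  if (adjustment == "ratio_cbl") {
    if (!(cbl_var %in% colnames(X)))
      stop("variable '", cbl_var, "' absent: required for ratio_cbl adjustment")
    A <- X[, setdiff(colnames(X), cbl_var), drop = FALSE] / X[, cbl_var]
  } else {
    lg <- log(X)
    A <- lg - rowMeans(lg)
  }
  if (ncol(A) < 2) stop("need >= 2 variables after adjustment")
  pc <- stats::prcomp(A, center = TRUE, scale. = FALSE)
  structure(
    list(scores = pc$x, loadings = pc$rotation, eigenvalues = pc$sdev^2,
         adjusted = A, excluded = excluded, adjustment = adjustment,
         groups = groups),
    class = "size_adjusted_pca")
}

# pooled within-group covariance with optional shrinkage toward its diagonal
pooled_covariance <- function(X, groups, shrinkage = 0) {
  p <- ncol(X)
  S <- matrix(0, p, p)
  df <- 0
  for (g in unique(groups)) {
    Xi <- X[groups == g, , drop = FALSE]
    if (nrow(Xi) > 1) {
      S <- S + stats::cov(Xi) * (nrow(Xi) - 1)
      df <- df + nrow(Xi) - 1
    }
  }
  S <- S / df
  if (shrinkage > 0) S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), p)
  S
}

#' Linear discriminant classification with jackknifed accuracy
#'
#' Fits a linear discriminant on the training specimens (pooled within-group
#' covariance; classification by smallest Mahalanobis distance to the group
#' centroids), classifies an optional held-out specimen, and estimates
#' leave-one-out (jackknifed) accuracy by refitting the entire model with
#' each training specimen withheld in turn. When any group has fewer
#' specimens than variables + 2 the pooled covariance is shrunk toward its
#' diagonal (default intensity 0.2) for stability.
#'
#' @param x numeric matrix or data frame of variables or scores (rows named
#'   by specimen).
#' @param groups group label per row; >= 2 groups with >= 3 members each.
#' @param holdout_label optional specimen (row name) excluded from training
#'   and classified by the resulting model.
#' @param shrinkage shrinkage intensity in \[0, 1\]; `NULL` (default) selects
#'   0 when every group has >= variables + 2 members, else 0.2.
#' @return list of class `dfa_jackknife`: `holdout` (label, predicted group)
#'   or NULL, `loo_predicted`, `loo_accuracy`, `per_group_accuracy`,
#'   `confusion`, `shrinkage`.
#' @export
dfa_jackknife <- function(x, groups, holdout_label = NULL, shrinkage = NULL) {
  X <- as.matrix(x)
  if (is.null(rownames(X))) rownames(X) <- paste0("spec_", seq_len(nrow(X)))
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) stop("one group label per row required")
  hold <- NULL
  if (!is.null(holdout_label)) {
    hi <- match(holdout_label, rownames(X))
    if (is.na(hi)) stop("holdout specimen '", holdout_label, "' not found")
    hold <- list(x = X[hi, , drop = FALSE], label = holdout_label)
    X <- X[-hi, , drop = FALSE]
    groups <- groups[-hi]
  }
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 3))
    stop("need >= 2 groups with >= 3 members each in the training data")
  p <- ncol(X)
  if (is.null(shrinkage)) shrinkage <- if (min(tab) < p + 2) 0.2 else 0
  classify <- function(train_x, train_g, new_x) {
    S <- pooled_covariance(train_x, train_g, shrinkage)
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("singular pooled covariance; set a positive 'shrinkage'",
           call. = FALSE))
    cents <- do.call(rbind, lapply(sort(unique(train_g)), function(g)
      colMeans(train_x[train_g == g, , drop = FALSE])))
    rownames(cents) <- sort(unique(train_g))
    d2 <- apply(cents, 1, function(mu) {
      dv <- sweep(new_x, 2, mu)
      rowSums((dv %*% Sinv) * dv)
    })
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    rownames(cents)[apply(d2, 1, which.min)]
  }
  holdout_res <- NULL
  if (!is.null(hold))
    holdout_res <- list(label = hold$label,
                        predicted = classify(X, groups, hold$x))
  loo <- character(nrow(X))
  for (i in seq_len(nrow(X)))
    loo[i] <- classify(X[-i, , drop = FALSE], groups[-i],
                       X[i, , drop = FALSE])
  acc <- mean(loo == groups)
  per_group <- vapply(sort(unique(groups)), function(g)
    mean(loo[groups == g] == g), numeric(1))
  structure(
    list(holdout = holdout_res, loo_predicted = setNames(loo, rownames(X)),
         loo_accuracy = acc, per_group_accuracy = per_group,
         confusion = table(actual = groups, predicted = loo),
         shrinkage = shrinkage),
    class = "dfa_jackknife")
}

#' @export
print.dfa_jackknife <- function(x, ...) {
  cat("<dfa_jackknife> LOO accuracy", sprintf("%.1f%%", 100 * x$loo_accuracy))
  if (!is.null(x$holdout))
    cat("; holdout", x$holdout$label, "->", x$holdout$predicted)
  cat("\n")
  invisible(x)
}
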