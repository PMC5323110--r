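# Three-step (Baron-Kenny) mediation of the EF -> EM effect through
# connectivity strength:
#
#   (1) Y = c  X + e1          total effect
#   (2) M = a  X + e2          X -> mediator
#   (3) Y = c' X + b M + e3    direct + mediated
#
# all fit by OLS with intercepts. Without covariates the decomposition
# c = c' + a b holds exactly. Mediation is established when (1) c is
# significant, (2) a and b are significant, and (3) either c' is
# insignificant (full mediation) or |c'| < |c| (partial mediation). The
# mediated fraction is the indirect ratio (a b) / c, reported only when c
# is significant (it is unstable near c = 0). A Sobel z for a b is reported
# as a supplementary statistic.

coef_row <- function(fit, term) {
  s <- summary(fit)$coefficients
  c(estimate = s[term, 1], se = s[term, 2], p = s[term, 4])
}

#' Fit a three-step mediation model
#'
#' @param x independent variable (e.g. EF composite; per subject)
#' @param m mediator (e.g. extracted Fisher-z connectivity strength)
#' @param y outcome (e.g. EM composite)
#' @param alpha two-sided significance level for the path tests
#' @param covariates optional data frame of covariates entered in all three
#'   regressions
#' @param data optional data frame in which to look up `x`, `m`, `y` given
#'   as column names
#' @return a `mediation_fit` object with paths `a`, `b`, `c`, `c_prime`
#'   (each estimate/SE/p), `indirect`, `indirect_ratio`, `sobel`,
#'   `classification` (`"none"`, `"partial"` or `"full"`), `n`, `alpha`
#' @export
fit_mediation <- function(x, m, y, alpha = 0.05, covariates = NULL,
                          data = NULL) {
  if (!is.null(data)) {
    x <- data[[x]]; m <- data[[m]]; y <- data[[y]]
  }
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, n >= 10)
  if (!all(is.finite(c(x, m, y)))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(m) == 0)
    stop("zero-variance x or m")
  df <- data.frame(x = x, m = m, y = y)
  cv <- ""
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    cv <- paste("+", paste(names(covariates), collapse = " + "))
  }
  f1 <- stats::lm(stats::as.formula(paste("y ~ x", cv)), df)
  f2 <- stats::lm(stats::as.formula(paste("m ~ x", cv)), df)
  f3 <- stats::lm(stats::as.formula(paste("y ~ x + m", cv)), df)
  cc <- coef_row(f1, "x")
  aa <- coef_row(f2, "x")
  bb <- coef_row(f3, "m")
  cp <- coef_row(f3, "x")
  indirect <- aa["estimate"] * bb["estimate"]
  sobel_z <- unname(indirect / sqrt(aa["estimate"]^2 * bb["se"]^2 +
                                      bb["estimate"]^2 * aa["se"]^2))
  sig <- function(path) path["p"] < alpha
  classification <-
    if (!sig(cc) || !sig(aa) || !sig(bb)) "none"
    else if (!sig(cp)) "full"
    else if (abs(cp["estimate"]) < abs(cc["estimate"])) "partial"
    else "none"
  ratio <- if (sig(cc)) unname(indirect / cc["estimate"]) else NA_real_
  structure(
    list(a = aa, b = bb, c = cc, c_prime = cp,
         indirect = unname(indirect), indirect_ratio = ratio,
         sobel = c(z = sobel_z, p = 2 * stats::pnorm(-abs(sobel_z))),
         classification = classification, n = n, alpha = alpha,
         covariates = if (is.null(covariates)) character(0)
                      else names(covariates),
         fits = list(total = f1, mediator = f2, outcome = f3)),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, digits = 3, ...) {
  cat("Three-step mediation (OLS)\n")
  cat(sprintf("  n = %d, alpha = %g%s\n", x$n, x$alpha,
              if (length(x$covariates))
                paste0(", covariates: ", paste(x$covariates, collapse = ", "))
              else ""))
  paths <- rbind(a = x$a, b = x$b, c = x$c, `c'` = x$c_prime)
  print(round(paths, digits))
  cat(sprintf("  indirect a*b = %.*f", digits, x$indirect))
  if (is.na(x$indirect_ratio))
    cat("  (indirect ratio undefined: c not significant)\n")
  else
    cat(sprintf("  indirect ratio (a*b)/c = %.*f\n", digits,
                x$indirect_ratio))
  cat(sprintf("  classification: %s mediation\n", x$classification))
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  print(object, ...)
  cat(sprintf("  Sobel z = %.3f (p = %.4f) [supplementary]\n",
              object$sobel["z"], object$sobel["p"]))
  invisible(object)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(a = unname(object$a["estimate"]), b = unname(object$b["estimate"]),
    c = unname(object$c["estimate"]),
    c_prime = unname(object$c_prime["estimate"]))
}

#' Extract the mediator: mean connectivity over a cluster
#'
#' @param fc_maps list of per-subject 3D Fisher-z arrays
#' @param cluster integer voxel indices of the cluster
#' @return per-subject mean Fisher-z strength
#' @export
extract_mediator <- function(fc_maps, cluster) {
  cluster <- as.integer(cluster)
  if (!length(cluster)) stop("cluster is empty")
  vapply(fc_maps, function(m) mean(as.vector(m)[cluster]), numeric(1))
}
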