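# Binary subtype design-matrix model: which ring-neuron subtypes explain
# each driver's sleep change? Response = mean change rate of one sleep
# parameter per driver; predictors = 0/1 subtype membership of the driver.
# Ordinary least squares with intercept (identity link, normal errors),
# two-sided t tests per coefficient.

#' Canonical ring-neuron subtypes
#'
#' The 11 anatomically defined ellipsoid-body ring-neuron subtypes used as
#' design columns.
#' @export
RING_SUBTYPES <- c("R1", "R2", "R3a", "R3d", "R3m", "R3p", "R3w",
                   "R4d", "R4m", "R5", "R6")

#' Validate a driver x subtype 0/1 annotation matrix
#'
#' @param X Matrix or data.frame, rows = drivers (rownames), columns =
#'   subtypes, entries 0/1.
#' @param allow_all_zero Allow drivers labeling no listed subtype.
#' @return The validated numeric matrix.
#' @export
subtype_design <- function(X, allow_all_zero = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(rownames(X))) stop("design needs driver rownames", call. = FALSE)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("design needs unique subtype column names", call. = FALSE)
  }
  if (!all(X %in% c(0, 1))) stop("design entries must be 0/1", call. = FALSE)
  if (!allow_all_zero && any(rowSums(X) == 0)) {
    stop("driver(s) with all-zero subtype row: ",
         paste(rownames(X)[rowSums(X) == 0], collapse = ", "), call. = FALSE)
  }
  X
}

#' Fit the subtype contribution model for one response
#'
#' Least-squares fit of `y ~ 1 + X` where `X` is the binary driver x
#' subtype matrix. Exactly collinear columns (detected by pivoted QR) are
#' dropped, later columns first, and reported; a condition number above
#' `1e8` on the retained design triggers a warning only. P-values are
#' two-sided t tests on the coefficients with residual degrees of freedom.
#'
#' @param X Driver x subtype 0/1 matrix (see [subtype_design()]).
#' @param y Numeric response, one value per driver (mean change rate).
#' @param parameter,phase Optional labels carried into the result.
#' @return Object of class `subtype_glm_fit`: `coefficients` table
#'   (`term`, `weight`, `se`, `t`, `p`), `intercept` row included;
#'   `dropped_columns`, `df_residual`, `sigma`, `r_squared`,
#'   `parameter`, `phase`.
#' @export
fit_subtype_glm <- function(X, y, parameter = NA_character_,
                            phase = NA_character_) {
  X <- subtype_design(X, allow_all_zero = TRUE)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("y must be finite for every driver", call. = FALSE)
  }
  M <- cbind(`(Intercept)` = 1, X)
  qrM <- qr(M)
  retained <- qrM$pivot[seq_len(qrM$rank)]
  dropped <- colnames(M)[setdiff(seq_len(ncol(M)), retained)]
  keep <- sort(retained) # preserve original column order
  Mr <- M[, keep, drop = FALSE]
  if (length(dropped)) {
    warning("dropping collinear column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  df_res <- n - ncol(Mr)
  if (df_res < 1L) {
    stop("no residual degrees of freedom: ", n, " drivers for ",
         ncol(Mr), " retained coefficients", call. = FALSE)
  }
  kappa_val <- kappa(Mr, exact = TRUE)
  if (kappa_val > 1e8) {
    warning(sprintf("near-collinear design (condition number %.3g)", kappa_val),
            call. = FALSE)
  }
  fit <- lm.fit(Mr, y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(chol(crossprod(Mr)))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df_res)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = data.table(term = names(beta), weight = unname(beta),
                              se = unname(se), t = unname(tstat),
                              p = unname(pval)),
    dropped_columns = dropped,
    df_residual = df_res,
    sigma = sqrt(sigma2),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    condition_number = kappa_val,
    parameter = parameter, phase = phase
  ), class = "subtype_glm_fit")
}

#' Classify subtype effects by sign and significance
#'
#' A subtype is `"positive"` when its weight is > 0 with p below `alpha`,
#' `"negative"` when the weight is < 0 with p below `alpha`, `"none"`
#' otherwise (intercept excluded). By default p-values are used raw,
#' matching the screen's per-subtype reporting; `p_adjust = "BH"` applies
#' a Benjamini-Hochberg correction across the subtypes first.
#'
#' @param fit A [fit_subtype_glm()] result, or any table with `term`,
#'   `weight`, `p` columns.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Named character vector, one entry per subtype.
#' @export
classify_effects <- function(fit, alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  co <- if (inherits(fit, "subtype_glm_fit")) fit$coefficients else
    as.data.table(fit)
  co <- co[co$term != "(Intercept)", ]
  p <- if (p_adjust == "BH") stats::p.adjust(co$p, "BH") else co$p
  cls <- ifelse(p < alpha & co$weight > 0, "positive",
                ifelse(p < alpha & co$weight < 0, "negative", "none"))
  setNames(cls, co$term)
}

#' Subtype model across all sleep parameters and phases
#'
#' Fits one [fit_subtype_glm()] per (parameter, phase) combination present
#' in the change-rate table and stacks the coefficient tables, giving the
#' weight/p layout of the screen's subtype summary.
#'
#' @param X Driver x subtype 0/1 matrix.
#' @param rates Output of [driver_change_rates()].
#' @param alpha Level for effect classification.
#' @return `data.table`: `parameter`, `phase`, `term`, `weight`, `se`,
#'   `t`, `p`, `effect`.
#' @export
subtype_glm_table <- function(X, rates, alpha = 0.05) {
  rates <- as.data.table(rates)
  combos <- unique(rates[, .(parameter, phase)])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- rates[parameter == combos$parameter[i] & phase == combos$phase[i]]
    sub <- sub[match(rownames(X), driver)]
    if (anyNA(sub$value)) {
      stop("missing change rate for driver(s): ",
           paste(rownames(X)[is.na(sub$value)], collapse = ", "), call. = FALSE)
    }
    fit <- fit_subtype_glm(X, sub$value, parameter = combos$parameter[i],
                           phase = combos$phase[i])
    eff <- classify_effects(fit, alpha = alpha)
    co <- copy(fit$coefficients)
    co[, `:=`(parameter = combos$parameter[i], phase = combos$phase[i],
              effect = c("(Intercept)" = NA_character_, eff)[term])]
    out[[i]] <- co
  }
  res <- rbindlist(out)
  setcolorder(res, c("parameter", "phase", "term"))
  res[]
}
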