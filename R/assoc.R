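# Multivariable linear association models: one BP outcome regressed on one
# exposure (a species' CLR abundance or Shannon diversity) plus a covariate
# design, with BH FDR per outcome across the species screen.

#' Build a model covariate design
#'
#' Expands the named covariate columns of a data frame into a full-rank
#' numeric design (treatment coding, first factor level as reference;
#' country-of-birth should be supplied as a factor with Scandinavia first and
#' plate with the lexicographically first plate as its first level).
#'
#' @param data Data frame holding the covariates.
#' @param covariates Character vector of column names.
#' @return Numeric matrix without an intercept column.
#' @export
covariate_design <- function(data, covariates) {
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    stop_input("covariate column(s) absent: %s", paste(missing_cols, collapse = ", "))
  }
  X <- .design_matrix(covariates, data, intercept = FALSE)
  if (anyNA(X)) stop_input("covariate design contains missing values; apply complete-case selection first")
  constant <- apply(X, 2L, function(v) max(v) == min(v))
  if (any(constant)) {
    message("dropping constant design column(s): ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  X
}

#' Fit one exposure-outcome association model
#'
#' Ordinary least squares of `outcome ~ exposure + covariates`. Reports the
#' exposure coefficient (mmHg per exposure unit), its standard error, the
#' two-sided t-test p-value and the 95% CI from the t quantile at the
#' residual degrees of freedom.
#'
#' @param outcome Numeric response vector (mmHg).
#' @param exposure Numeric exposure vector (e.g. CLR abundance).
#' @param covariates Numeric covariate matrix (no intercept), or `NULL`.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row data frame: `beta`, `se`, `ci_low`, `ci_high`, `p`, `n`, `df`.
#' @export
fit_association <- function(outcome, exposure, covariates = NULL, conf_level = 0.95) {
  n <- length(outcome)
  if (stats::var(exposure) == 0) stop("design error: exposure has zero variance", call. = FALSE)
  X <- cbind("(Intercept)" = 1, exposure = exposure, covariates)
  if (n <= ncol(X) + 2L) stop_input("too few observations for the design (n = %d, p = %d)", n, ncol(X))
  qrx <- qr(X, tol = 1e-8)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1L, ncol(X))]]
    stop("design error: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, outcome)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv_piv <- chol2inv(qr.R(qrx))  # (X'X)^{-1} in pivot order
  XtX_inv_diag <- diag(XtX_inv_piv)[order(qrx$pivot)][2L]
  beta <- fit$coefficients[["exposure"]]
  se <- sqrt(sigma2 * XtX_inv_diag)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  data.frame(beta = beta, se = se,
             ci_low = beta - tq * se, ci_high = beta + tq * se,
             p = p, n = n, df = df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust] with `method = "BH"`),
#' with an explicit domain check.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Screen species and diversity against blood-pressure outcomes
#'
#' Fits one model per exposure x outcome. Species exposures form one BH
#' family per outcome; the Shannon-diversity exposure is tested separately
#' with its own BH family across outcomes (so a few diversity tests never
#' dilute or inflate the species FDR, and vice versa). Discoveries are flagged
#' at `q < fdr`.
#'
#' @param exposures Numeric matrix, samples x exposures (typically the CLR
#'   species matrix). Column names identify species.
#' @param diversity Optional numeric vector (Shannon index) tested as its own
#'   family; `NULL` to skip.
#' @param outcomes Named list or data frame of numeric outcome vectors (mmHg).
#' @param data Data frame with the model covariates.
#' @param covariates Character vector naming the model covariates (Model 1
#'   includes BMI; Model 2 excludes it).
#' @param model Label recorded in the results (1 or 2).
#' @param fdr Discovery threshold on q, default 0.05.
#' @return Object of class `bp_screen`: data frame with one row per fit,
#'   columns `exposure`, `exposure_type`, `outcome`, `model`, `n`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `p`, `q`, `discovery`.
#' @export
run_screen <- function(exposures, diversity = NULL, outcomes, data, covariates,
                       model = 1, fdr = 0.05) {
  exposures <- as.matrix(exposures)
  outcomes <- as.list(as.data.frame(outcomes))
  n <- nrow(exposures)
  if (any(vapply(outcomes, length, 0L) != n) || nrow(data) != n) {
    stop_input("exposures, outcomes and covariate data must align on samples")
  }
  X <- covariate_design(data, covariates)
  fit_block <- function(mat, type) {
    blocks <- lapply(names(outcomes), function(oc) {
      y <- outcomes[[oc]]
      rows <- lapply(colnames(mat), function(sp) {
        r <- fit_association(y, mat[, sp], X)
        cbind(exposure = sp, exposure_type = type, outcome = oc, model = model, r)
      })
      out <- do.call(rbind, rows)
      out$q <- bh_fdr(out$p)
      out
    })
    do.call(rbind, blocks)
  }
  res <- fit_block(exposures, "species")
  if (!is.null(diversity)) {
    div <- matrix(diversity, ncol = 1L, dimnames = list(NULL, "shannon"))
    dres <- do.call(rbind, lapply(names(outcomes), function(oc) {
      r <- fit_association(outcomes[[oc]], div[, 1L], X)
      cbind(exposure = "shannon", exposure_type = "diversity", outcome = oc,
            model = model, r)
    }))
    dres$q <- bh_fdr(dres$p)
    res <- rbind(res, dres)
  }
  res$discovery <- res$q < fdr
  rownames(res) <- NULL
  structure(res, fdr = fdr, class = c("bp_screen", "data.frame"))
}

#' @export
print.bp_screen <- function(x, ...) {
  df <- as.data.frame(x)
  n_disc <- sum(df$discovery)
  cat(sprintf("Association screen: %d fits (%d exposures x %d outcomes), model %s\n",
              nrow(df), length(unique(df$exposure)), length(unique(df$outcome)),
              paste(unique(df$model), collapse = "/")))
  cat(sprintf("Discoveries at q < %g: %d\n", attr(x, "fdr"), n_disc))
  if (n_disc) {
    print(df[df$discovery, c("exposure", "outcome", "beta", "ci_low", "ci_high", "p", "q")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Compare Model 1 and Model 2 estimates
#'
#' Side-by-side table of per-exposure estimates with and without BMI
#' adjustment, for attenuation assessment.
#'
#' @param screen1,screen2 [run_screen] results for Model 1 and Model 2.
#' @return Data frame keyed by exposure and outcome with `beta_model1`,
#'   `beta_model2`, `attenuation` (1 - beta1/beta2 where beta2 != 0).
#' @export
compare_models <- function(screen1, screen2) {
  k <- c("exposure", "outcome")
  m <- merge(as.data.frame(screen1)[, c(k, "beta", "p")],
             as.data.frame(screen2)[, c(k, "beta", "p")],
             by = k, suffixes = c("_model1", "_model2"))
  m$attenuation <- ifelse(m$beta_model2 != 0, 1 - m$beta_model1 / m$beta_model2, NA_real_)
  m
}
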