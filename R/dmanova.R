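# Distance-based multivariate analysis of variance on a dissimilarity matrix:
# Gower double-centring, trace pseudo-R^2, incremental pseudo-F with a
# Freedman-Lane permutation test, and nested model sequences.

#' Gower double-centring of a dissimilarity matrix
#'
#' `G = -1/2 * C (D o D) C` with `C = I - 11'/n` and `o` the elementwise
#' square. `G` plays the role of an (outer-product) Gram matrix of the
#' implicit sample configuration; its trace is the total "variance" that
#' designs partition.
#'
#' @param D Square symmetric dissimilarity matrix with zero diagonal.
#' @return Object of class `gower_matrix` (a double-centred matrix).
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-10) {
    stop_input("D must be square and symmetric")
  }
  if (max(abs(diag(D))) > 1e-12) stop_input("D must have a zero diagonal")
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  structure(G, class = c("gower_matrix", "matrix", "array"))
}

# Hat matrix of a design, with rank from a pivoted QR at tolerance
# 1e-8 * largest diagonal magnitude.
.hat_matrix <- function(X) {
  qrx <- qr(X, tol = 1e-8)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = qrx$rank)
}

# Expand a model frame (data.frame or matrix) to a numeric design matrix with
# treatment coding, first level as reference, no intercept column added here.
.design_matrix <- function(spec, data, intercept = TRUE) {
  if (is.null(spec) || !length(spec)) {
    return(matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)")))
  }
  f <- stats::as.formula(paste("~", paste(spec, collapse = " + ")))
  mm <- stats::model.matrix(f, data = data)
  if (!intercept) mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  mm
}

#' Incremental pseudo-F test on a Gower-centred matrix
#'
#' Tests whether columns `Z` add explained dissimilarity variance beyond a
#' reduced design `X0`. With `H_X` the hat matrix of a design,
#' `pseudoR2(X) = tr(H_X G H_X) / tr(G)` and
#' `F = ((tr(Hf G Hf) - tr(H0 G H0)) / q) / (tr((I-Hf) G (I-Hf)) / (n - p))`
#' with `q` the rank gain and `p` the full-design rank. The p-value comes from
#' a Freedman-Lane permutation scheme: `G` is residualised on the reduced
#' model, rows and columns are permuted jointly, and `F` recomputed; the
#' observed statistic is evaluated on the same residualised matrix so the
#' identity permutation is a draw from the null ensemble, and
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' A saturated increment (zero residual trace) reports `F = Inf`.
#'
#' @param G A [gower_center] result (or any double-centred matrix).
#' @param X0 Reduced design matrix (including the intercept).
#' @param Z Matrix of added columns.
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed Integer seed.
#' @return List: `pseudo_r2_reduced`, `pseudo_r2_full`, `F`, `p`, `q`, `rank_full`,
#'   `n_perm`.
#' @export
dmanova_increment <- function(G, X0, Z, n_perm = 999L, seed = 1L) {
  G <- unclass(G)
  n <- nrow(G)
  trG <- sum(diag(G))
  if (abs(trG) < 1e-12) stop("degenerate-distance error: tr(G) = 0", call. = FALSE)
  X0 <- as.matrix(X0); Z <- as.matrix(Z)
  h0 <- .hat_matrix(X0)
  hf <- .hat_matrix(cbind(X0, Z))
  q <- hf$rank - h0$rank
  if (q <= 0L) stop("design error: added columns give no rank gain", call. = FALSE)
  p_full <- hf$rank
  if (n <= p_full) stop("design error: n must exceed the full-design rank", call. = FALSE)

  # tr(H G H) = tr(G H) for idempotent symmetric H
  r2_red <- sum(h0$H * G) / trG
  r2_full <- sum(hf$H * G) / trG

  R0 <- diag(n) - h0$H
  Gres <- R0 %*% G %*% R0
  f_stat_on <- function(M) {
    num <- (sum(hf$H * M) - sum(h0$H * M)) / q
    den <- (sum(diag(M)) - sum(hf$H * M)) / (n - p_full)
    if (abs(den) < 1e-12) return(Inf)
    num / den
  }
  F_obs <- f_stat_on(Gres)
  # tolerance so permutations tied with F_obs (e.g. group relabelings) count
  # as exceedances despite floating-point noise
  eps <- if (is.finite(F_obs)) 1e-8 * max(1, abs(F_obs)) else 0
  exceed <- with_local_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      if (f_stat_on(Gres[idx, idx]) >= F_obs - eps) count <- count + 1L
    }
    count
  })
  list(pseudo_r2_reduced = r2_red, pseudo_r2_full = r2_full,
       F = F_obs, p = (1 + exceed) / (n_perm + 1),
       q = q, rank_full = p_full, n_perm = n_perm)
}

#' Run a nested D-MANOVA model sequence
#'
#' Evaluates the pseudo-R^2 of each design in a strictly nested covariate
#' sequence (e.g. baseline, baseline + office BP, baseline + office + 24-h BP)
#' and the incremental pseudo-F and permutation p-value for each step.
#'
#' @param G A [gower_center] result.
#' @param model_specs Named list of character vectors of covariate names; each
#'   must extend the previous one.
#' @param data Data frame providing the covariates (factors expanded with the
#'   first level as reference).
#' @param n_perm Permutations per increment.
#' @param seed Integer seed.
#' @return Object of class `dmanova_result`: data frame of models with
#'   `pseudo_r2`, `f_increment`, `p_increment`, plus attributes `n_perm`, `seed`.
#' @export
run_dmanova_sequence <- function(G, model_specs, data, n_perm = 999L, seed = 1L) {
  if (length(model_specs) < 1L) stop_config("need at least one model spec")
  labels <- names(model_specs) %||% paste0("model", seq_along(model_specs))
  for (i in seq_along(model_specs)[-1L]) {
    if (!all(model_specs[[i - 1L]] %in% model_specs[[i]])) {
      stop_config("model specs must be strictly nested ('%s' does not extend '%s')",
                  labels[i], labels[i - 1L])
    }
    if (length(model_specs[[i]]) <= length(model_specs[[i - 1L]])) {
      stop_config("model '%s' adds no covariates", labels[i])
    }
  }
  res <- data.frame(model = labels, pseudo_r2 = NA_real_,
                    f_increment = NA_real_, p_increment = NA_real_)
  X_prev <- .design_matrix(model_specs[[1L]], data)
  h <- .hat_matrix(X_prev)
  trG <- sum(diag(unclass(G)))
  res$pseudo_r2[1L] <- sum(h$H * unclass(G)) / trG
  for (i in seq_along(model_specs)[-1L]) {
    X_full <- .design_matrix(model_specs[[i]], data)
    added <- setdiff(colnames(X_full), colnames(X_prev))
    inc <- dmanova_increment(G, X_prev, X_full[, added, drop = FALSE],
                             n_perm = n_perm, seed = child_seed(seed, i))
    res$pseudo_r2[i] <- inc$pseudo_r2_full
    res$f_increment[i] <- inc$F
    res$p_increment[i] <- inc$p
    X_prev <- X_full
  }
  structure(res, n_perm = n_perm, seed = seed, class = c("dmanova_result", "data.frame"))
}

#' @export
print.dmanova_result <- function(x, digits = 4, ...) {
  cat("D-MANOVA nested model sequence (", attr(x, "n_perm"),
      " permutations per increment)\n", sep = "")
  df <- as.data.frame(x)
  df$pseudo_r2 <- sprintf(paste0("%.", digits, "f"), df$pseudo_r2)
  print(df, row.names = FALSE)
  invisible(x)
}
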