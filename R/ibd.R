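#' Mantel test between two distance matrices
#'
#' Pearson correlation `r` over the `n(n-1)/2` unordered pairs, with
#' significance from joint row/column permutations of the second matrix.
#' The one-sided (positive association) p-value is
#' `(1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`. With `exhaustive = TRUE`
#' all `n!` relabellings are enumerated instead (small `n` only) and the
#' p-value is the exact fraction of relabellings, the identity included,
#' with `r >= r_obs`.
#'
#' @param dgeo,dgen conformable square distance matrices in the same
#'   sample order.
#' @param n_perm number of random permutations (default 999).
#' @param seed optional integer seed.
#' @param exhaustive enumerate all permutations (requires `n <= 8`).
#' @return one-row tibble: `statistic` (Mantel r), `r_squared`,
#'   `p_value`, `n_perm`, `n`.
#' @export
mantel_test <- function(dgeo, dgen, n_perm = 999, seed = NULL,
                        exhaustive = FALSE) {
  if (!all(dim(dgeo) == dim(dgen))) abort("matrices are not conformable")
  n <- nrow(dgeo)
  up <- upper_pairs(n)
  iu <- cbind(up$i, up$j)
  x <- dgeo[iu]
  y <- dgen[iu]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant distance matrix: Mantel r undefined")
    return(tibble(statistic = NA_real_, r_squared = NA_real_,
                  p_value = NA_real_, n_perm = 0L, n = n))
  }
  r_obs <- cor(x, y)
  if (exhaustive) {
    if (n > 8) abort("exhaustive enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    r_all <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      cor(x, dgen[p, p][iu])
    }, 0)
    p_val <- mean(r_all >= r_obs - 1e-12)
    n_perm <- nrow(perms) - 1L
  } else {
    if (n_perm < 1) abort("n_perm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      cor(x, dgen[p, p][iu])
    }, 0)
    p_val <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  }
  tibble(statistic = r_obs, r_squared = r_obs^2, p_value = p_val,
         n_perm = as.integer(n_perm), n = n)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.integer(blk)
    r <- r + nrow(sub)
  }
  out
}

#' Build the pair table of geographic and genetic distances
#'
#' One row per unordered sample pair with geographic distance, genetic
#' distance and the pair midpoint (coordinate mean) — the table the IBD
#' fit and the residual-surface analysis operate on. Pairs with `NA`
#' genetic distance are dropped (a message reports how many).
#'
#' @param geo a [sample_geo()] tibble.
#' @param dgen genetic `dist_matrix` covering the same samples.
#' @param ibd_model optional fitted [fit_ibd()] model; when supplied, a
#'   `residual = gen - predicted(geo_km)` column is added.
#' @return tibble `id_1`, `id_2`, `geo_km`, `gen`, `mid_x`, `mid_y`,
#'   `bearing` (pair axis orientation, degrees mod 180; plotting metadata
#'   only) and, with a model, `residual`.
#' @export
build_pairs <- function(geo, dgen, ibd_model = NULL) {
  ids <- rownames(dgen) %||% geo$sample_id
  miss <- setdiff(ids, geo$sample_id)
  if (length(miss) > 0) {
    abort(paste0("no coordinates for sample '", miss[1], "'"))
  }
  geo <- geo[match(ids, geo$sample_id), ]
  n <- length(ids)
  up <- upper_pairs(n)
  pairs <- tibble(
    id_1 = ids[up$i], id_2 = ids[up$j],
    geo_km = sqrt((geo$x[up$i] - geo$x[up$j])^2 +
                  (geo$y[up$i] - geo$y[up$j])^2),
    gen = dgen[cbind(up$i, up$j)],
    mid_x = (geo$x[up$i] + geo$x[up$j]) / 2,
    mid_y = (geo$y[up$i] + geo$y[up$j]) / 2,
    # pair axis orientation in degrees mod 180, plotting metadata only
    bearing = (atan2(geo$y[up$j] - geo$y[up$i],
                     geo$x[up$j] - geo$x[up$i]) * 180 / pi) %% 180
  )
  n_na <- sum(is.na(pairs$gen))
  if (n_na == nrow(pairs)) abort("all genetic distances are NA")
  if (n_na > 0) {
    message(n_na, " pair(s) with NA genetic distance dropped")
    pairs <- pairs %>% filter(!is.na(.data$gen))
  }
  if (!is.null(ibd_model)) {
    pairs$residual <- pairs$gen - predict(ibd_model, pairs$geo_km)
  }
  pairs
}

#' Fit the isolation-by-distance trend
#'
#' Least-squares fit of genetic distance against geographic distance over
#' all pairs. The default `asymptotic_exp` model is the reverse
#' exponential asymptotic curve `y(d) = a - b exp(-c d)` with `b, c >= 0`
#' (monotone non-decreasing, saturating — the expected shape of IBD at a
#' regional scale); `linear` fits `y = intercept + slope d`. If the
#' nonlinear fit fails to converge the function falls back to the linear
#' model with a warning. Residuals `gen - y(d)` are the input to the
#' residual-surface (DResD) analysis.
#'
#' @param pairs tibble with `geo_km` and `gen` columns ([build_pairs()]).
#' @param model `"asymptotic_exp"` (default) or `"linear"`.
#' @return an `ibd_model` object with `predict()`, `residuals()`,
#'   `tidy()` and `glance()` methods.
#' @export
fit_ibd <- function(pairs, model = c("asymptotic_exp", "linear")) {
  model <- match.arg(model)
  d <- pairs$geo_km
  y <- pairs$gen
  keep <- is.finite(d) & is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (length(unique(d)) < 2) abort("all geographic distances are equal")
  if (model == "linear" && length(d) < 3) abort("need >= 3 pairs")
  if (model == "asymptotic_exp" && length(d) < 4) abort("need >= 4 pairs")

  if (model == "asymptotic_exp") {
    bins <- cut(rank(d, ties.method = "first"),
                breaks = min(10, max(2, floor(length(d) / 2))))
    bin_means <- tapply(y, bins, mean)
    a0 <- max(bin_means)
    b0 <- max(a0 - min(bin_means), 1e-6)
    c0 <- 1 / max(median(d), 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a - b * exp(-cc * d),
                        start = list(a = a0, b = b0, cc = c0),
                        lower = c(a = -Inf, b = 0, cc = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warn("asymptotic_exp fit did not converge; falling back to linear")
      return(fit_ibd(pairs, model = "linear"))
    }
    cf <- coef(fit)
    params <- c(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["cc"]))
    fitted_y <- params["a"] - params["b"] * exp(-params["c"] * d)
  } else {
    fit <- lm(y ~ d)
    cf <- coef(fit)
    params <- c(intercept = unname(cf[1]), slope = unname(cf[2]))
    fitted_y <- unname(cf[1] + cf[2] * d)
  }
  r2 <- 1 - sum((y - fitted_y)^2) / sum((y - mean(y))^2)
  structure(
    list(model = model, parameters = params, r_squared = r2,
         n_pairs = length(d), mantel = NULL),
    class = "ibd_model"
  )
}

#' Predicted genetic distance at given geographic distances
#' @param object an `ibd_model`.
#' @param newdata numeric vector of distances (km) or a data frame with a
#'   `geo_km` column.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ibd_model <- function(object, newdata, ...) {
  d <- if (is.data.frame(newdata)) newdata$geo_km else newdata
  p <- object$parameters
  if (object$model == "asymptotic_exp") {
    p["a"] - p["b"] * exp(-p["c"] * d)
  } else {
    p["intercept"] + p["slope"] * d
  }
}

#' Attach Mantel results to an IBD model
#'
#' Convenience: stores a [mantel_test()] row inside the model so
#' `glance()` reports curve fit and matrix correlation together.
#'
#' @param object an `ibd_model`.
#' @param mantel one-row tibble from [mantel_test()].
#' @return the updated `ibd_model`.
#' @export
set_mantel <- function(object, mantel) {
  stopifnot(inherits(object, "ibd_model"))
  object$mantel <- mantel
  object
}

#' @export
print.ibd_model <- function(x, ...) {
  cat("<ibd_model> ", x$model, ", ", x$n_pairs, " pairs, R^2 = ",
      signif(x$r_squared, 3), "\n  parameters: ",
      paste(names(x$parameters), signif(x$parameters, 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  if (!is.null(x$mantel)) {
    cat(sprintf("  Mantel r = %.3f (r^2 = %.3f), p = %.4g [%d permutations]\n",
                x$mantel$statistic, x$mantel$r_squared, x$mantel$p_value,
                x$mantel$n_perm))
  }
  invisible(x)
}

#' Parameters of a fitted IBD model
#' @param x an `ibd_model`.
#' @param ... unused.
#' @return tibble `term`, `estimate`.
#' @export
tidy.ibd_model <- function(x, ...) {
  tibble(term = names(x$parameters), estimate = unname(x$parameters))
}

#' One-row IBD model summary
#' @param x an `ibd_model`.
#' @param ... unused.
#' @return tibble with model tag, fit R^2, pair count and, when attached,
#'   Mantel statistics.
#' @export
glance.ibd_model <- function(x, ...) {
  out <- tibble(model = x$model, r_squared = x$r_squared,
                n_pairs = x$n_pairs)
  if (!is.null(x$mantel)) {
    out$mantel_r <- x$mantel$statistic
    out$mantel_r_squared <- x$mantel$r_squared
    out$mantel_p <- x$mantel$p_value
  }
  out
}

#' Scatter of genetic vs geographic distance with the fitted IBD curve
#'
#' @param object an `ibd_model`.
#' @param pairs the pair table the model was fitted on.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ibd_model <- function(object, pairs, ...) {
  grid_d <- seq(0, max(pairs$geo_km), length.out = 200)
  curve <- tibble(geo_km = grid_d, gen = predict(object, grid_d))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$geo_km, y = .data$gen)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick", linewidth = 0.9) +
    ggplot2::labs(x = "geographic distance (km)", y = "genetic distance",
                  title = paste0("isolation by distance (", object$model,
                                 ", R² = ", signif(object$r_squared, 2), ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
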