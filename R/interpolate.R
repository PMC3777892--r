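# Normalised inverse-distance weights from grid points to data points.
# w = 1/d with power 1; a grid point within eps of any data point takes
# the plain mean of the coincident points instead (the IDW limit).
idw_weights <- function(gx, gy, px, py, eps = 1e-6) {
  if (length(px) == 0) abort("empty point set")
  if (eps <= 0) abort("eps must be > 0")
  d <- sqrt(outer(gx, px, "-")^2 + outer(gy, py, "-")^2)
  w <- 1 / d
  hit <- d < eps
  coincident <- rowSums(hit) > 0
  if (any(coincident)) {
    w[coincident, ] <- hit[coincident, , drop = FALSE] /
      rowSums(hit)[coincident]
  }
  w[!coincident, ] <- w[!coincident, , drop = FALSE] /
    rowSums(w[!coincident, , drop = FALSE])
  w
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Interpolates scattered values to every grid point as the
#' inverse-distance-weighted average over *all* data points,
#' `v(g) = sum_i v_i / d(g,i) / sum_i 1 / d(g,i)` (weight power fixed at
#' 1). A grid point closer than `eps` to one or more data points takes
#' the mean of those coincident values.
#'
#' @param points data frame with `x`, `y` and one or more numeric value
#'   columns (every column other than `x`/`y` is interpolated).
#' @param grid a [grid_spec()].
#' @param eps coincidence tolerance in km (default `1e-6`).
#' @return tibble `point_id`, `x`, `y` plus one interpolated column per
#'   input value column.
#' @export
idw_interpolate <- function(points, grid, eps = 1e-6) {
  vcols <- setdiff(names(points), c("x", "y"))
  if (length(vcols) == 0) abort("points needs at least one value column")
  g <- grid_points(grid)
  w <- idw_weights(g$x, g$y, points$x, points$y, eps = eps)
  vals <- w %*% as.matrix(points[vcols])
  dplyr::bind_cols(g, as_tibble(as.data.frame(vals)))
}

#' Classify grid points into core / probable / outside range per group
#'
#' The admixture-surface significance method: each cluster's membership
#' coefficients are interpolated from the sample locations onto the grid
#' by inverse-distance weighting; a resampling null re-assigns the
#' membership rows to the *fixed* sample locations `n_boot` times
#' (permuted without replacement by default, or drawn with replacement);
#' and every grid point is classified per group against the empirical
#' `alpha/2` and `1 - alpha/2` percentiles of its null distribution:
#'
#' * `core`     — observed value above the upper percentile (the group's
#'   statistically supported core area),
#' * `outside`  — observed below the lower percentile (evidently out of
#'   the group's range),
#' * `probable` — between the bounds (indistinguishable from spatially
#'   random structure); observed values exactly on a bound fall here.
#'
#' Inference is pointwise: no correction is applied across grid points.
#'
#' @param q a [membership_matrix()].
#' @param geo a [sample_geo()] tibble covering the same samples.
#' @param grid a [grid_spec()]; default: 5-km grid over the samples'
#'   bounding box padded by one spacing ([grid_from_samples()]).
#' @param n_boot null replicates (default 1000; must be `>= 40` for the
#'   percentile bounds to be meaningful).
#' @param alpha pointwise significance level (default 0.05).
#' @param resample `"permute"` (rows reshuffled without replacement, the
#'   default: the observed field is then exchangeable with the null
#'   replicates, so the classification is exactly calibrated pointwise)
#'   or `"bootstrap"` (rows drawn with replacement: a markedly
#'   over-dispersed, hence conservative, null).
#' @param seed optional integer seed; results are bit-reproducible.
#' @param eps IDW coincidence tolerance (km).
#' @return a `range_classification` object: `$field` (per point x group:
#'   `value`, `lower`, `upper`, `class`), `$report` (per group class
#'   coverage fractions over retained grid points and the number of
#'   connected core components), `$grid`, `$params`. See
#'   [tidy.range_classification()], [glance.range_classification()],
#'   [autoplot.range_classification()].
#' @export
classify_ranges <- function(q, geo, grid = NULL, n_boot = 1000,
                            alpha = 0.05, resample = c("permute", "bootstrap"),
                            seed = NULL, eps = 1e-6) {
  resample <- match.arg(resample)
  if (n_boot < 40) abort("n_boot must be >= 40 for percentile bounds")
  ids <- q$sample_id
  miss <- setdiff(ids, geo$sample_id)
  if (length(miss) > 0) abort(paste0("no coordinates for sample '", miss[1], "'"))
  geo <- geo[match(ids, geo$sample_id), ]
  grid <- grid %||% grid_from_samples(geo)
  qm <- q_matrix(q)
  K <- ncol(qm)
  if (K < 2) abort("need K >= 2 clusters")
  n <- nrow(qm)
  g <- grid_points(grid)
  w <- idw_weights(g$x, g$y, geo$x, geo$y, eps = eps)
  observed <- w %*% qm

  degenerate <- max(apply(qm, 2, function(col) diff(range(col)))) < 1e-12
  if (degenerate) {
    warn("all membership rows identical: degenerate null, everything 'probable'")
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(K), function(k) matrix(0, nrow(g), n_boot))
  for (b in seq_len(n_boot)) {
    idx <- if (resample == "bootstrap") {
      sample.int(n, n, replace = TRUE)
    } else {
      sample.int(n)
    }
    fb <- w %*% qm[idx, , drop = FALSE]
    for (k in seq_len(K)) reps[[k]][, b] <- fb[, k]
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  field <- purrr::map_dfr(seq_len(K), function(k) {
    qs <- row_quantiles(reps[[k]], probs)
    lower <- qs[1, ]
    upper <- qs[2, ]
    obs <- observed[, k]
    cls <- ifelse(obs > upper, "core",
                  ifelse(obs < lower, "outside", "probable"))
    if (degenerate) cls <- rep("probable", length(obs))
    tibble(group = colnames(qm)[k], point_id = g$point_id,
           x = g$x, y = g$y, value = obs,
           lower = lower, upper = upper, class = cls)
  })
  field$class <- factor(field$class, levels = c("core", "probable", "outside"))
  report <- field %>%
    count(.data$group, .data$class, .drop = FALSE) %>%
    group_by(.data$group) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select("group", "class", "fraction") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "fraction") %>%
    left_join(
      field %>%
        filter(.data$class == "core") %>%
        group_by(.data$group) %>%
        summarise(n_core_components = n_components(.data$point_id, grid),
                  .groups = "drop"),
      by = "group"
    ) %>%
    mutate(n_core_components = tidyr::replace_na(.data$n_core_components, 0L))

  structure(
    list(field = field, report = report, grid = grid,
         params = list(n_boot = n_boot, alpha = alpha, resample = resample,
                       seed = seed, eps = eps)),
    class = "range_classification"
  )
}

# Connected components (4-neighbour adjacency) of a set of grid point ids.
n_components <- function(point_ids, grid) {
  m <- length(point_ids)
  if (m == 0) return(0L)
  nx <- grid$nx
  i <- (point_ids - 1L) %% nx
  j <- (point_ids - 1L) %/% nx
  keys <- paste(i, j)
  alive <- rep(TRUE, m)
  comp <- 0L
  for (s in seq_len(m)) {
    if (!alive[s]) next
    comp <- comp + 1L
    stack <- s
    alive[s] <- FALSE
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- match(c(paste(i[cur] + 1L, j[cur]), paste(i[cur] - 1L, j[cur]),
                    paste(i[cur], j[cur] + 1L), paste(i[cur], j[cur] - 1L)),
                  keys)
      nb <- nb[!is.na(nb)]
      nb <- nb[alive[nb]]
      alive[nb] <- FALSE
      stack <- c(stack, nb)
    }
  }
  comp
}

#' @export
print.range_classification <- function(x, ...) {
  cat("<range_classification> ", length(unique(x$field$group)), " groups x ",
      length(unique(x$field$point_id)), " grid points; n_boot = ",
      x$params$n_boot, ", alpha = ", x$params$alpha,
      " (", x$params$resample, ")\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Per-point classification field as a tibble
#' @param x a `range_classification`.
#' @param ... unused.
#' @return tibble `group`, `point_id`, `x`, `y`, `value`, `lower`,
#'   `upper`, `class`.
#' @export
tidy.range_classification <- function(x, ...) x$field

#' Per-group coverage report
#' @param x a `range_classification`.
#' @param ... unused.
#' @return tibble per group: `core`, `probable`, `outside` coverage
#'   fractions (summing to 1) and `n_core_components`.
#' @export
glance.range_classification <- function(x, ...) x$report

#' Map the classified ranges
#'
#' One facet per genetic group; tiles coloured by class, sample locations
#' overplotted.
#'
#' @param object a `range_classification`.
#' @param geo optional [sample_geo()] tibble to overlay sample points.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.range_classification <- function(object, geo = NULL, ...) {
  p <- ggplot2::ggplot(object$field,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$class)) +
    ggplot2::geom_tile(width = object$grid$spacing,
                       height = object$grid$spacing) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_manual(values = c(core = "#1b7837",
                                          probable = "#d9f0d3",
                                          outside = "white")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(geo)) {
    p <- p + ggplot2::geom_point(data = geo, inherit.aes = FALSE,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 size = 0.5, alpha = 0.6)
  }
  p
}
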