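#' Split a cell mask into periphery and interior
#'
#' Automated stand-in for manually drawn region masks: the periphery is the
#' cell mask minus its morphological erosion by `depth` (disc structuring
#' element, holes filled first), the interior is the erosion itself.
#'
#' @param cell_mask logical matrix.
#' @param depth erosion depth in pixels (>= 1).
#' @return a `region_masks` object (logical matrices `periphery`,
#'   `interior`).
#' @export
split_periphery_interior <- function(cell_mask, depth = 2L) {
  stopifnot(is.logical(cell_mask), depth >= 1)
  # holes (e.g. the nucleus) are filled first: the periphery is the band
  # inside the cell outline, not a rim around internal holes
  filled <- EBImage::fillHull(cell_mask * 1) > 0.5
  er <- erode_mask(filled, depth)
  if (!any(er & cell_mask))
    stop("erosion emptied the interior; use a smaller depth")
  region_masks(interior = er & cell_mask, periphery = cell_mask & !er)
}

# binary erosion by a disc-shaped structuring element of the given radius
erode_mask <- function(mask, depth) {
  EBImage::erode(mask * 1,
                 EBImage::makeBrush(2L * as.integer(depth) + 1L,
                                    shape = "disc")) > 0.5
}

#' Region masks (periphery/interior)
#'
#' Validates user-supplied (e.g. manually drawn) region masks: the two
#' regions must be disjoint and together form the analyzed cell area.
#'
#' @param interior,periphery logical matrices of equal shape.
#' @return a `region_masks` object.
#' @export
region_masks <- function(interior, periphery) {
  stopifnot(is.logical(interior), is.logical(periphery),
            all(dim(interior) == dim(periphery)))
  if (any(interior & periphery))
    stop("interior and periphery masks overlap")
  structure(list(interior = interior, periphery = periphery),
            class = "region_masks")
}

#' Periphery vs interior pooled lifetimes
#'
#' Pools the photons of each region and fits a mono-exponential decay to
#' each, giving the paired `(tau_P, tau_I)` readout used to localize donor
#' quenching.
#'
#' @param cube a [tcspc_cube()].
#' @param masks a [region_masks()].
#' @param irf `irf_model`.
#' @param options [fit_options()].
#' @return named numeric vector `c(tau_P, tau_I)` (ns).
#' @export
region_lifetime_pair <- function(cube, masks, irf,
                                 options = fit_options()) {
  stopifnot(inherits(masks, "region_masks"))
  if (!any(masks$periphery) || !any(masks$interior))
    stop("both regions must contain pixels")
  hp <- pool_pixels(cube, masks$periphery)
  hi <- pool_pixels(cube, masks$interior)
  if (hp$n_photons == 0 || hi$n_photons == 0)
    stop("a region contains no photons")
  c(tau_P = fit_mono(hp, irf, options)$apparent_lifetime,
    tau_I = fit_mono(hi, irf, options)$apparent_lifetime)
}

#' Ordinary least-squares regression
#'
#' Slope, intercept and R-squared of `y` on `x` (e.g. apparent lifetime on
#' acceptor expression level, or on %FRET).
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list with `slope`, `intercept`, `r_squared`, `n`, class
#'   `regression_result`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0) stop("x has zero variance")
  if (sd(y) == 0)   # flat response: zero slope, nothing explained
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          n = length(x)), class = "regression_result"))
  fit <- lm(y ~ x)
  # summary() warns on exact fits; an R^2 of 1 is a legitimate result here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> beta = %.4g, intercept = %.4g, R2 = %.3f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Group comparisons (one-way ANOVA + Bonferroni, or paired t-tests)
#'
#' For an independent design: one-way ANOVA across groups plus two-sided
#' pairwise t-tests on the pre-declared relevant pairs, Bonferroni-adjusted
#' over those pairs. For a paired design: paired two-sided t-tests per pair
#' (observations matched by order within group).
#'
#' @param values numeric response (e.g. apparent lifetime per cell).
#' @param groups factor or character group labels.
#' @param design `"independent"` or `"paired"`.
#' @param pairs list of length-2 character vectors naming the relevant
#'   pairs; defaults to all pairs.
#' @return list with `group_stats` (mean, SEM, n per group), `anova`
#'   (F statistic and p, independent design), and `pairwise` (data.frame:
#'   pair, statistic, p_value, p_adjusted, correction).
#' @export
compare_groups <- function(values, groups,
                           design = c("independent", "paired"),
                           pairs = NULL) {
  design <- match.arg(design)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lv <- unique(groups)
  if (length(lv) < 2) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  gs <- data.frame(
    group = lv,
    mean = vapply(lv, function(g) mean(values[groups == g]), 0),
    sem = vapply(lv, function(g)
      sd(values[groups == g]) / sqrt(sum(groups == g)), 0),
    n = as.integer(ns[lv]))
  if (is.null(pairs))
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  an <- NULL
  if (design == "independent") {
    a <- summary(aov(values ~ factor(groups)))[[1]]
    an <- list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
  }
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    va <- values[groups == pr[1]]
    vb <- values[groups == pr[2]]
    if (design == "paired") {
      if (length(va) != length(vb))
        stop("paired design requires complete pairs for ",
             pr[1], " vs ", pr[2])
      tt <- degenerate_safe_t(va - vb, function() t.test(va, vb,
                                                         paired = TRUE))
    } else {
      tt <- degenerate_safe_t(c(va - mean(vb), vb - mean(vb)),
                              function() t.test(va, vb))
    }
    data.frame(pair = paste(pr[1], "vs", pr[2]),
               statistic = unname(tt$statistic),
               p_value = tt$p.value,
               p_adjusted = min(tt$p.value * m, 1),
               correction = "bonferroni")
  }))
  list(group_stats = gs, anova = an, pairwise = pw)
}

#' Pearson colocalization coefficient
#'
#' Standard Pearson correlation of two channel intensities over the masked
#' pixels, the conventional whole-cell colocalization readout.
#'
#' @param image_a,image_b 2-D intensity grids of equal shape.
#' @param mask logical matrix; defaults to all pixels.
#' @return Pearson r.
#' @export
pearson_colocalization <- function(image_a, image_b, mask = NULL) {
  stopifnot(all(dim(image_a) == dim(image_b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image_a), ncol(image_a))
  stopifnot(all(dim(mask) == dim(image_a)))
  a <- image_a[mask]; b <- image_b[mask]
  if (length(a) < 2) stop("need at least 2 masked pixels")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in a channel over the mask")
  cor(a, b)
}

# t.test is undefined when the relevant spread is exactly zero: identical
# samples get p = 1, perfectly separated constant differences p = 0
degenerate_safe_t <- function(spread, test_fn) {
  if (sd(spread) > 0) return(test_fn())
  if (isTRUE(all.equal(mean(spread), 0)))
    list(statistic = c(t = 0), p.value = 1)
  else
    list(statistic = c(t = sign(mean(spread)) * Inf), p.value = 0)
}
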