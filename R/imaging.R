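#' ROI signal density
#'
#' Mean pixel intensity of a region of interest (signal density: total
#' intensity normalized to ROI area), optionally normalized to a reference
#' ROI on the same image (e.g. the contralateral fissure).
#'
#' @param image 2D numeric matrix (single channel; extract the red channel
#'   at the I/O boundary for RGB data).
#' @param mask Logical matrix of the same shape, or a rectangle spec
#'   `list(rows = c(r1, r2), cols = c(c1, c2))`.
#' @param reference_mask Optional reference ROI (same forms as `mask`).
#' @param roi_id Identifier carried into the result.
#' @return List of class `roi_quant`: `roi_id`, `area` (pixels),
#'   `mean_intensity`, `density` (= total/area), `normalized` (vs reference,
#'   or `NA`).
#' @export
roi_density <- function(image, mask, reference_mask = NULL, roi_id = "roi") {
  m <- as_mask(mask, dim(image))
  area <- sum(m)
  if (area == 0) stop("empty ROI mask")
  dens <- sum(image[m]) / area
  normalized <- NA_real_
  if (!is.null(reference_mask)) {
    rm <- as_mask(reference_mask, dim(image))
    if (sum(rm) == 0) stop("empty reference mask")
    ref <- sum(image[rm]) / sum(rm)
    if (ref == 0) stop("zero-intensity reference ROI")
    normalized <- dens / ref
  }
  structure(list(roi_id = roi_id, area = area, mean_intensity = dens,
                 density = dens, normalized = normalized),
            class = "roi_quant")
}

as_mask <- function(mask, dims) {
  if (is.matrix(mask) && is.logical(mask)) {
    if (!all(dim(mask) == dims)) stop("mask shape does not match image")
    return(mask)
  }
  if (is.list(mask) && !is.null(mask$rows) && !is.null(mask$cols)) {
    m <- matrix(FALSE, dims[1], dims[2])
    m[mask$rows[1]:mask$rows[2], mask$cols[1]:mask$cols[2]] <- TRUE
    return(m)
  }
  stop("mask must be a logical matrix or list(rows=, cols=)")
}

#' Columnar line profile normalized to a reference intensity
#'
#' Averages the image across the width of a column ROI (e.g. hilus to
#' fissure) and normalizes the resulting 1D profile to the mean intensity
#' of a reference ROI.
#'
#' @param image 2D numeric matrix.
#' @param cols Column indices of the columnar ROI.
#' @param reference_mask Reference ROI (mask or rectangle spec) whose mean
#'   intensity normalizes the profile; zero reference errors.
#' @return Numeric vector, one value per row of the image.
#' @export
line_profile <- function(image, cols, reference_mask) {
  prof <- rowMeans(image[, cols, drop = FALSE])
  rm <- as_mask(reference_mask, dim(image))
  if (sum(rm) == 0) stop("empty reference mask")
  ref <- mean(image[rm])
  if (ref == 0) stop("normalization by zero-intensity reference")
  prof / ref
}

#' Compare ROI signal densities across conditions
#'
#' Per-condition mean density normalized to a named reference condition,
#' with a homogeneity check on ROI areas (compared groups should not differ
#' in ROI size).
#'
#' @param quants data.frame with columns `condition`, `density`, `area`
#'   (one row per ROI), or a list of `roi_quant` objects plus `conditions`.
#' @param reference Condition whose mean density is set to 1.
#' @param area_alpha Significance level of the area-homogeneity check.
#' @return List with `table` (condition, n, mean_density, rel_density),
#'   `area_p` (one-way ANOVA on areas) and `area_flagged`.
#' @export
compare_roi_groups <- function(quants, reference, area_alpha = 0.05) {
  stopifnot(is.data.frame(quants),
            all(c("condition", "density", "area") %in% names(quants)))
  if (!reference %in% quants$condition)
    stop("reference condition '", reference, "' absent")
  tab <- do.call(rbind, lapply(split(quants, quants$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               mean_density = mean(d$density))))
  ref_mean <- tab$mean_density[tab$condition == reference]
  tab$rel_density <- tab$mean_density / ref_mean
  rownames(tab) <- NULL
  area_p <- if (length(unique(quants$condition)) > 1 &&
                var(quants$area) > 0) {
    summary(stats::aov(area ~ condition, data = quants))[[1]][
      "condition", "Pr(>F)"]
  } else 1
  list(table = tab, area_p = area_p,
       area_flagged = is.finite(area_p) && area_p < area_alpha)
}
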