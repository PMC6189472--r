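# Automated immunological-synapse scoring: cSMAC detection per cell and
# the synapse-forming fraction per condition.

#' Detect a central supramolecular activation cluster (cSMAC) in one cell
#'
#' Automates the visual synapse call with two explicit criteria: the largest
#' above-threshold cluster in the TCR/CD3 channel inside the cell must
#' (1) cover at least `min_area_um2` and (2) have its centroid within
#' `centrality_max_frac` of the cell's equivalent radius from the cell
#' centroid. Peripheral clusters — the hallmark of blocked centripetal
#' transport — therefore do not count as a synapse. Absence of signal is a
#' negative call, not an error.
#'
#' @param cd3_channel 2-D numeric matrix (TCR/CD3 cluster channel).
#' @param cell_mask Logical matrix: the cell footprint (non-empty).
#' @param pixel_size_um Pixel size, um/px.
#' @param min_area_um2 Minimum cluster area (default 3 um^2).
#' @param centrality_max_frac Maximum centroid offset as a fraction of the
#'   cell equivalent radius (default 0.4).
#' @return A one-row tibble: `has_csmac`, `csmac_area_um2`,
#'   `centroid_offset_um`, `area_pass`, `centrality_pass`.
#' @export
detect_csmac <- function(cd3_channel, cell_mask, pixel_size_um = 1,
                         min_area_um2 = 3, centrality_max_frac = 0.4) {
  stopifnot(all(dim(cd3_channel) == dim(cell_mask)))
  if (!any(cell_mask)) abort("`cell_mask` is empty.")
  negative <- tibble(has_csmac = FALSE, csmac_area_um2 = 0,
                     centroid_offset_um = NA_real_,
                     area_pass = FALSE, centrality_pass = FALSE)
  vals <- cd3_channel[cell_mask]
  thr <- tryCatch(otsu_threshold(vals), error = function(e) NULL)
  if (is.null(thr)) return(negative)
  cluster_mask <- cd3_channel >= thr & cell_mask
  if (!any(cluster_mask)) return(negative)
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(cluster_mask * 1))),
                nrow(cd3_channel))
  sizes <- table(lab[lab > 0])
  biggest <- as.integer(names(sizes)[which.max(sizes)])
  cl <- lab == biggest
  area_um2 <- sum(cl) * pixel_size_um^2

  g <- pixel_grid(dim(cd3_channel))
  cell_cx <- mean(g$x[cell_mask]); cell_cy <- mean(g$y[cell_mask])
  cl_cx <- mean(g$x[cl]); cl_cy <- mean(g$y[cl])
  offset_um <- sqrt((cl_cx - cell_cx)^2 + (cl_cy - cell_cy)^2) * pixel_size_um
  r_equiv_um <- sqrt(sum(cell_mask) / pi) * pixel_size_um

  area_pass <- area_um2 >= min_area_um2
  centrality_pass <- offset_um <= centrality_max_frac * r_equiv_um
  tibble(has_csmac = area_pass && centrality_pass,
         csmac_area_um2 = area_um2,
         centroid_offset_um = offset_um,
         area_pass = area_pass, centrality_pass = centrality_pass)
}

#' Score synapse formation for a condition
#'
#' Segments cells (from the brightfield/DIC channel, unless a labeled cell
#' mask is supplied), restricts to cells lying on the bilayer (at least 80%
#' of the cell footprint inside the thresholded DiI-positive area, when a
#' DiI channel is given), runs [detect_csmac()] per eligible cell, and
#' reports the synapse-forming fraction with a Wilson 95% confidence
#' interval.
#'
#' @param stack A single-frame [image_stack()] with the required channels.
#' @param channels Named list/vector mapping roles to channel labels or
#'   indices; `cd3` is required, `bf` (brightfield/DIC, for segmentation)
#'   and `dil` (bilayer tracer, for eligibility) are optional.
#' @param cells Optional labeled cell mask overriding brightfield
#'   segmentation.
#' @param min_area_um2,centrality_max_frac cSMAC criteria, see
#'   [detect_csmac()].
#' @param min_cell_area_px Size filter for cell segmentation.
#' @param dil_coverage Minimum fraction of the cell footprint on the
#'   DiI-positive area for eligibility.
#' @return A `synapse_score` object; `tidy()` returns the per-cell table,
#'   `glance()` the fraction with its confidence interval.
#' @export
score_condition <- function(stack, channels = list(cd3 = "cd3", bf = "bf", dil = "dil"),
                            cells = NULL, min_area_um2 = 3,
                            centrality_max_frac = 0.4,
                            min_cell_area_px = 200L, dil_coverage = 0.8) {
  channels <- as.list(channels)
  if (is.null(channels$cd3)) abort("`channels$cd3` is required.")
  cd3 <- get_frame(stack, 1L, channels$cd3)
  if (is.null(cells)) {
    if (is.null(channels$bf)) abort("Provide `cells` or a brightfield channel for segmentation.")
    cells <- segment_cells(get_frame(stack, 1L, channels$bf),
                           min_area_px = min_cell_area_px)
  }
  ids <- setdiff(sort(unique(as.vector(cells))), 0L)
  if (!length(ids)) abort("No cells segmented; cannot score the condition.")

  dil_mask <- NULL
  if (!is.null(channels$dil)) {
    dil <- get_frame(stack, 1L, channels$dil)
    thr <- tryCatch(otsu_threshold(dil), error = function(e) NULL)
    # A constant DiI channel means uniform bilayer coverage: all eligible.
    if (!is.null(thr)) dil_mask <- dil >= thr
  }

  rows <- lapply(ids, function(id) {
    cm <- cells == id
    eligible <- TRUE
    if (!is.null(dil_mask)) eligible <- mean(dil_mask[cm]) >= dil_coverage
    call <- detect_csmac(cd3, cm, pixel_size_um = stack$pixel_size_um,
                         min_area_um2 = min_area_um2,
                         centrality_max_frac = centrality_max_frac)
    mutate(call, cell_id = id, eligible = eligible, .before = 1)
  })
  tab <- bind_rows(rows)
  elig <- tab[tab$eligible, ]
  if (!nrow(elig)) abort("No eligible cells (none on the DiI-positive area).")
  k <- sum(elig$has_csmac); n <- nrow(elig)
  ci <- wilson_ci(k, n)
  structure(list(cells = tab, fraction = k / n, n_positive = k, n_eligible = n,
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]]),
            class = "synapse_score")
}

#' @export
print.synapse_score <- function(x, ...) {
  cat(sprintf("<synapse_score> %d / %d eligible cells synapse-positive (%.1f%%), 95%% CI [%.1f%%, %.1f%%]\n",
              x$n_positive, x$n_eligible, 100 * x$fraction,
              100 * x$ci_lower, 100 * x$ci_upper))
  invisible(x)
}

#' Tidy a synapse score
#' @param x A `synapse_score`.
#' @param ... Unused.
#' @return `tidy()`: the per-cell call table; `glance()`: a one-row summary
#'   (`fraction`, `n_positive`, `n_eligible`, `ci_lower`, `ci_upper`).
#' @exportS3Method generics::tidy
tidy.synapse_score <- function(x, ...) x$cells

#' @rdname tidy.synapse_score
#' @exportS3Method generics::glance
glance.synapse_score <- function(x, ...) {
  tibble(fraction = x$fraction, n_positive = x$n_positive,
         n_eligible = x$n_eligible, ci_lower = x$ci_lower,
         ci_upper = x$ci_upper)
}
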