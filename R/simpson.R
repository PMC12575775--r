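# Simpson biplane (method of discs) left-ventricular volumes and EF.
#
# The LV volume is approximated by a stack of n elliptical discs along the
# long axis; each disc's two diameters come from the two orthogonal apical
# views (A2C, A4C): V = (pi/4) (L/n) sum a_i b_i.

#' Disc stack for the Simpson biplane method
#'
#' Extracts the long axis and per-disc diameters of the LV label from two
#' orthogonal view masks. Per view, the long axis is the principal axis of
#' the LV pixel set (in mm coordinates), apex and base are the extreme
#' projections, and the common length L is the mean of the two view
#' lengths. Each view is partitioned into `n_discs` equal slabs along its
#' axis; the diameter at each slab is the perpendicular extent (max - min
#' perpendicular projection) of the LV pixels in the slab. Discs are
#' ordered from the wider (basal) end.
#'
#' @param mask_view1,mask_view2 label masks of the two views.
#' @param spacing1,spacing2 per-view (row, col) spacing in mm/px.
#' @param n_discs number of discs (default 20).
#' @param label LV label value (default 1).
#' @return object of class `disc_stack`: list with `L` (mm), `n_discs`,
#'   `a`, `b` (per-disc diameters in mm).
#' @export
extract_disc_stack <- function(mask_view1, mask_view2,
                               spacing1 = c(1, 1), spacing2 = c(1, 1),
                               n_discs = 20L, label = 1L) {
  v1 <- view_discs(mask_view1, spacing1, n_discs, label)
  v2 <- view_discs(mask_view2, spacing2, n_discs, label)
  structure(list(L = (v1$L + v2$L) / 2, n_discs = as.integer(n_discs),
                 a = v1$diameters, b = v2$diameters),
            class = "disc_stack")
}

view_discs <- function(mask, spacing, n_discs, label) {
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) == 0)
    abort_invalid("LV label absent from view",
                  class = "echosynth_undefined_metric")
  xy <- sweep(idx, 2, spacing, "*")
  ctr <- colMeans(xy)
  dev <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(dev) / nrow(dev), symmetric = TRUE)
  u <- ev$vectors[, 1]                      # long axis
  v <- ev$vectors[, 2]
  proj <- dev %*% u
  perp <- dev %*% v
  L <- max(proj) - min(proj)
  edges <- seq(min(proj), max(proj), length.out = n_discs + 1L)
  slab <- pmin(pmax(findInterval(proj, edges, rightmost.closed = TRUE), 1L), n_discs)
  diam <- vapply(seq_len(n_discs), function(kk) {
    p <- perp[slab == kk]
    if (length(p) == 0) 0 else max(p) - min(p)
  }, 0)
  half <- seq_len(floor(n_discs / 2))
  if (mean(diam[half]) < mean(diam[n_discs + 1L - half]))
    diam <- rev(diam)                        # base (wider end) first
  list(L = L, diameters = diam)
}

#' Simpson biplane volume of a disc stack
#'
#' V = (pi/4) (L/n) sum a_i b_i, converted from mm^3 to ml.
#'
#' @param stack a [extract_disc_stack()] result.
#' @return volume in ml.
#' @export
simpson_biplane_volume <- function(stack) {
  pi / 4 * (stack$L / stack$n_discs) * sum(stack$a * stack$b) / 1000
}

#' Ejection fraction
#'
#' EF = (EDV - ESV) / EDV.
#'
#' @param edv end-diastolic volume (> 0).
#' @param esv end-systolic volume in \[0, edv\].
#' @return fraction in \[0, 1\].
#' @export
ef <- function(edv, esv) {
  if (edv <= 0) abort_invalid("`edv` must be > 0")
  if (esv < 0 || esv > edv) abort_invalid("`esv` must lie in [0, edv]")
  (edv - esv) / edv
}

#' Biplane EF from per-cycle ED/ES masks
#'
#' Every A2C cycle is combined with every A4C cycle: per pair, EDV and ESV
#' come from [extract_disc_stack()] + [simpson_biplane_volume()] on the ED
#' and ES masks, then EF; the final estimate is the mean over all pairs.
#' Pairs in which a view lacks the LV label are skipped; if every pair
#' fails the exam yields a pipeline-failure error (mirroring feasibility
#' handling in clinical pipelines, where such exams are excluded).
#'
#' @param a2c_cycles,a4c_cycles lists of cycles; each cycle is a list with
#'   elements `ed` and `es` (label masks).
#' @param spacing_a2c,spacing_a4c per-view (row, col) spacing in mm/px.
#' @param n_discs number of Simpson discs.
#' @return list with `ef` (mean over pairs), `per_pair` (data.frame of
#'   pairwise EDV, ESV, EF) and `n_pairs`.
#' @export
biplane_ef_from_masks <- function(a2c_cycles, a4c_cycles,
                                  spacing_a2c = c(1, 1), spacing_a4c = c(1, 1),
                                  n_discs = 20L) {
  if (length(a2c_cycles) < 1 || length(a4c_cycles) < 1)
    abort_invalid("need at least one cycle per view")
  rows <- list()
  for (i in seq_along(a2c_cycles)) for (j in seq_along(a4c_cycles)) {
    res <- tryCatch({
      edv <- simpson_biplane_volume(extract_disc_stack(
        a2c_cycles[[i]]$ed, a4c_cycles[[j]]$ed, spacing_a2c, spacing_a4c, n_discs))
      esv <- simpson_biplane_volume(extract_disc_stack(
        a2c_cycles[[i]]$es, a4c_cycles[[j]]$es, spacing_a2c, spacing_a4c, n_discs))
      data.frame(a2c = i, a4c = j, edv = edv, esv = esv, ef = ef(edv, esv))
    }, echosynth_undefined_metric = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0)
    stop(structure(class = c("echosynth_pipeline_failure", "error", "condition"),
                   list(message = "EF undefined for all cycle pairs", call = NULL)))
  per_pair <- do.call(rbind, rows)
  list(ef = mean(per_pair$ef), per_pair = per_pair, n_pairs = nrow(per_pair))
}
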