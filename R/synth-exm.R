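#' Generate a matched pre-/post-expansion image pair
#'
#' Draws one engulfment scene and renders it twice: once at the
#' pre-expansion confocal sampling, and once with every physical
#' coordinate and object size multiplied by the linear expansion factor,
#' sampled at the post-expansion pixel size (0.155 um/px by default).
#' The optical PSF (in um) is unchanged — expansion magnifies the
#' specimen, not the microscope — which is exactly why ExM resolves
#' sub-diffraction structure.
#'
#' @param expansion_factor linear scale, >= 1.
#' @param scene an [engulfment_scene_params()]; the default is a
#'   small ExM field (70 x 70 um, 2 microglia) rather than the full
#'   transfected-region ROI, matching how expanded microglia are imaged
#'   a cell or two at a time.
#' @param pixel_size_post_um post-expansion sampling (default 0.155).
#' @param seed RNG seed.
#' @return list with `pre`, `post` (each `list(stack, truth)`) and
#'   `truth`: per-cell pre/post soma axes (um) and the true factor.
#' @export
generate_exm_pair <- function(expansion_factor,
                              scene = engulfment_scene_params(
                                roi_size_um = c(70, 70), n_microglia = 2L,
                                free_puncta_density = 0.05),
                              pixel_size_post_um = 0.155,
                              seed = NULL) {
  if (expansion_factor < 1) stop("`expansion_factor` must be >= 1")
  stopifnot(inherits(scene, "EngulfmentSceneParams"))
  with_seed(if (is.null(seed)) scene$seed else seed, {
    drawn <- .draw_engulfment_scene(scene)
    pre <- .render_engulfment_scene(drawn, scene)
    post_params <- scene
    post_params$roi_size_um <- scene$roi_size_um * expansion_factor
    post_params$pixel_size_um <- pixel_size_post_um
    post <- .render_engulfment_scene(.scale_scene(drawn, expansion_factor),
                                     post_params)
    axes <- do.call(rbind, lapply(seq_along(pre$truth$cells), function(i) {
      a <- pre$truth$cells[[i]]$soma_axes_um
      data.frame(cell_id = i,
                 pre_long_um = a[["long"]], pre_short_um = a[["short"]],
                 post_long_um = a[["long"]] * expansion_factor,
                 post_short_um = a[["short"]] * expansion_factor)
    }))
    list(pre = pre, post = post,
         truth = list(expansion_factor = expansion_factor,
                      soma_axes = axes))
  })
}
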